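#' Write a raster as an ESRI ASCII grid
#'
#' @param raster a [PopulationRaster-class].
#' @param path output file.
#' @param what `"values"` or `"mask"`.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(raster, path, what = c("values", "mask")) {
  what <- match.arg(what)
  z <- if (what == "values") raster@values else raster@landMask * 1
  z[!raster@landMask] <- -9999
  d <- dim(z)
  hdr <- c(
    sprintf("ncols %d", d[1]),
    sprintf("nrows %d", d[2]),
    sprintf("xllcorner %.10g", raster@origin[1]),
    sprintf("yllcorner %.10g", raster@origin[2]),
    sprintf("cellsize %.10g", raster@cellSize),
    "NODATA_value -9999")
  ## ESRI rows run north to south: row r of the file is y index ny - r + 1
  rows <- vapply(rev(seq_len(d[2])), function(j)
    paste(format(z[, j], trim = TRUE, scientific = FALSE), collapse = " "),
    character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as a population raster
#'
#' Cells equal to the NODATA value become off-land.
#'
#' @param path input file.
#' @param boundary boundary mode for the resulting raster.
#' @return A [PopulationRaster-class].
#' @export
readAsciiGrid <- function(path, boundary = "closed") {
  ln <- readLines(path)
  hv <- function(key) {
    row <- grep(paste0("^", key, "\\b"), ln, ignore.case = TRUE, value = TRUE)
    as.numeric(strsplit(trimws(row[1]), "\\s+")[[1]][2])
  }
  ncols <- hv("ncols"); nrows <- hv("nrows")
  xll <- hv("xllcorner"); yll <- hv("yllcorner")
  cs <- hv("cellsize"); nod <- hv("NODATA_value")
  dataLines <- ln[!grepl("^[A-Za-z]", ln)]
  vals <- as.numeric(unlist(strsplit(trimws(dataLines), "\\s+")))
  z <- matrix(NA_real_, ncols, nrows)
  for (r in seq_len(nrows)) {
    z[, nrows - r + 1] <- vals[((r - 1) * ncols + 1):(r * ncols)]
  }
  mask <- z != nod
  z[!mask] <- 0
  populationRaster(z, cs, mask, boundary, c(xll, yll))
}

#' Raster to and from x, y, value tables
#'
#' Compact plain-text representation for small fixtures: one row per land
#' cell with physical cell-centre coordinates.
#'
#' @param raster a [PopulationRaster-class].
#' @return `rasterToTable`: data frame with `x`, `y`, `value`.
#' @export
rasterToTable <- function(raster) {
  cells <- which(raster@landMask, arr.ind = TRUE)
  cc <- cellCenters(raster)
  data.frame(x = cc$x[cells[, 1]], y = cc$y[cells[, 2]],
             value = raster@values[cells])
}

#' Read model parameters and landscape from a structured config file
#'
#' YAML with keys `sigma`, `gamma`, `beta`, `alpha`, `cell_size`,
#' `boundary_mode`, `rho0`, `metropolitan: {c: ...}` and a `cities` list
#' (entries with `center`, `omega`, `radius`, optional
#' `background_radius`).
#'
#' @param path YAML file.
#' @return List with `params` ([ModelParams-class]), `cities` (list of
#'   [CitySpec-class]), `cellSize`, `boundary`, `rho0`, `coreFactor`.
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  grab <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  params <- modelParams(sigma = grab("sigma", 5), gamma = grab("gamma", 25),
                        beta = grab("beta", 1.1), alpha = grab("alpha", 1))
  cities <- lapply(cfg$cities, function(ct)
    citySpec(unlist(ct$center), ct$omega, ct$radius,
             if (is.null(ct$background_radius)) NA_real_
             else ct$background_radius))
  list(params = params, cities = cities,
       cellSize = grab("cell_size", 1),
       boundary = grab("boundary_mode", "closed"),
       rho0 = grab("rho0", 0),
       coreFactor = if (is.null(cfg$metropolitan$c)) 1 else cfg$metropolitan$c)
}

#' Write a model configuration file
#'
#' Inverse of [readModelConfig()].
#'
#' @param params a [ModelParams-class].
#' @param cities list of [CitySpec-class].
#' @param path output YAML file.
#' @param cellSize,boundary,rho0,coreFactor remaining config entries.
#' @return `path`, invisibly.
#' @export
writeModelConfig <- function(params, cities, path, cellSize = 1,
                             boundary = "closed", rho0 = 0, coreFactor = 1) {
  cfg <- list(
    sigma = params@sigma, gamma = params@gamma, beta = params@beta,
    alpha = params@alpha, cell_size = cellSize, boundary_mode = boundary,
    rho0 = rho0, metropolitan = list(c = coreFactor),
    cities = lapply(cities, function(ct) {
      out <- list(center = as.numeric(ct@center), omega = ct@omega,
                  radius = ct@radius)
      if (!is.na(ct@backgroundRadius))
        out$background_radius <- ct@backgroundRadius
      out
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
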