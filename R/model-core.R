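#' Create a set of model parameters
#'
#' @param sigma short-range interaction length scale (length units, > 0).
#' @param gamma metropolitan interaction length scale (length units, > 0).
#' @param beta conformity number (dimensionless, >= 1).
#' @param alpha inherent bias (dimensionless, > 0; 1 = unbiased).
#' @param tau memory timescale; time is measured in units of `tau`.
#' @return A [ModelParams-class] object.
#' @examples
#' modelParams(sigma = 5, beta = 1.1)
#' @export
modelParams <- function(sigma = 5, gamma = 25, beta = 1.1, alpha = 1, tau = 1) {
  new("ModelParams", sigma = sigma, gamma = gamma, beta = beta,
      alpha = alpha, tau = tau)
}

#' Create a city specification
#'
#' @param center length-2 numeric position of the city centre.
#' @param omega peak core density (> 0).
#' @param radius Gaussian core scale R (> 0).
#' @param backgroundRadius hinterland scale B (> radius), or `NA` for none.
#' @return A [CitySpec-class] object.
#' @export
citySpec <- function(center, omega, radius, backgroundRadius = NA_real_) {
  new("CitySpec", center = as.numeric(center), omega = omega, radius = radius,
      backgroundRadius = as.numeric(backgroundRadius))
}

setMethod("show", "ModelParams", function(object) {
  cat(sprintf(
    "ModelParams: sigma=%g gamma=%g beta=%g alpha=%g tau=%g\n",
    object@sigma, object@gamma, object@beta, object@alpha, object@tau))
})

setMethod("show", "CitySpec", function(object) {
  cat(sprintf("CitySpec at (%g, %g): omega=%g R=%g B=%s\n",
              object@center[1], object@center[2], object@omega, object@radius,
              ifelse(is.na(object@backgroundRadius), "none",
                     format(object@backgroundRadius))))
})

setMethod("show", "PopulationRaster", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "PopulationRaster: %d x %d cells (cell %g), %d land cells, %s boundary\n",
    d[1], d[2], object@cellSize, sum(object@landMask), object@boundary))
})

setMethod("show", "FieldState", function(object) {
  v <- object@m[is.finite(object@m)]
  cat(sprintf("FieldState at t=%g: mean m=%.4f, range [%.4f, %.4f]\n",
              object@t, mean(v), min(v), max(v)))
})

#' Conformity map from memory to usage frequency
#'
#' The sigmoidal map `p(m) = m^(alpha beta) / (m^(alpha beta) +
#' (1 - m^alpha)^beta)` converting a speaker's remembered frequency of
#' variant A into their current usage frequency. `beta > 1` pushes usage
#' toward the remembered local majority (conformity); `alpha != 1` biases
#' usage toward one variant independently of the majority. At
#' `alpha = beta = 1` the map is the identity. Endpoints are pinned to
#' `p(0) = 0`, `p(1) = 1`.
#'
#' @param m memory value(s) in `[0, 1]` (vector or matrix).
#' @param params a [ModelParams-class], or `NULL` when `alpha`/`beta` are
#'   given directly.
#' @param alpha,beta scalars overriding `params`.
#' @return Usage frequency with the shape of `m`.
#' @examples
#' conformityMap(0.6, alpha = 1, beta = 2)  # 0.36 / 0.52
#' @export
conformityMap <- function(m, params = NULL, alpha = NULL, beta = NULL) {
  if (!is.null(params)) {
    if (is.null(alpha)) alpha <- params@alpha
    if (is.null(beta)) beta <- params@beta
  }
  if (is.null(alpha) || is.null(beta))
    stop("supply either params or both alpha and beta")
  bad <- is.finite(m) & (m < 0 | m > 1)
  if (any(bad)) stop("memory values must lie in [0, 1]")
  ma <- m^alpha
  num <- ma^beta
  out <- num / (num + (1 - ma)^beta)
  # 0^0-type corners: the limits along m in (0,1) are 0 and 1
  out[is.finite(m) & m == 0] <- 0
  out[is.finite(m) & m == 1] <- 1
  out
}

#' Build a population raster from Gaussian cities
#'
#' Three density conventions are supported. `"with_hinterland"` sums, per
#' city, a Gaussian core `omega_i * exp(-|r - r_i|^2 / R_i^2)` plus a
#' unit-amplitude hinterland `exp(-|r - r_i|^2 / B_i^2)` (so density tends
#' to 0 far from all cities). `"bare_gaussian"` uses only the cores, plus
#' an optional constant background level `background`. `"capped"` produces
#' an occupation probability `min{(1 - rho0) * sum_i exp(-|r - r_i|^2 /
#' R_i^2) + rho0, 1}` suitable for sampling an agent lattice.
#'
#' @param cities list of [CitySpec-class] objects.
#' @param nx,ny grid dimensions in cells.
#' @param cellSize physical cell edge length.
#' @param mode one of `"with_hinterland"`, `"bare_gaussian"`, `"capped"`.
#' @param background constant background density level rho0 (`bare_gaussian`
#'   adds it; `capped` requires it in `[0, 1]`; ignored with a warning
#'   otherwise when 0).
#' @param landMask optional logical matrix; defaults to all land.
#' @param boundary `"closed"` or `"periodic"`.
#' @param origin physical coordinates of the grid corner.
#' @return A [PopulationRaster-class].
#' @examples
#' r <- buildCityDensity(list(citySpec(c(50, 50), 10, 10, 50)),
#'                       nx = 100, ny = 100, cellSize = 1)
#' @export
buildCityDensity <- function(cities, nx, ny, cellSize = 1,
                             mode = c("with_hinterland", "bare_gaussian", "capped"),
                             background = 0, landMask = NULL,
                             boundary = "closed", origin = c(0, 0)) {
  mode <- match.arg(mode)
  if (length(cities) < 1) stop("at least one city required")
  if (mode == "with_hinterland" &&
      any(vapply(cities, function(ct) is.na(ct@backgroundRadius), logical(1))))
    stop("with_hinterland mode requires backgroundRadius for every city")
  if (mode == "capped" && (background < 0 || background > 1))
    stop("capped mode requires background rho0 in [0, 1]")
  xs <- origin[1] + (seq_len(nx) - 0.5) * cellSize
  ys <- origin[2] + (seq_len(ny) - 0.5) * cellSize
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  core <- matrix(0, nx, ny)
  hint <- matrix(0, nx, ny)
  for (ct in cities) {
    d2 <- (X - ct@center[1])^2 + (Y - ct@center[2])^2
    core <- core + switch(mode,
      capped = exp(-d2 / ct@radius^2),
      ct@omega * exp(-d2 / ct@radius^2))
    if (mode == "with_hinterland")
      hint <- hint + exp(-d2 / ct@backgroundRadius^2)
  }
  vals <- switch(mode,
    with_hinterland = core + hint + background,
    bare_gaussian = core + background,
    capped = pmin((1 - background) * core + background, 1))
  if (is.null(landMask)) landMask <- matrix(TRUE, nx, ny)
  vals[!landMask] <- 0
  new("PopulationRaster", values = vals, cellSize = cellSize,
      landMask = landMask, boundary = boundary, origin = as.numeric(origin))
}

#' Construct a population raster from raw matrices
#'
#' @param values numeric density matrix (x along rows).
#' @param cellSize physical cell edge length.
#' @param landMask logical matrix (defaults to all land).
#' @param boundary `"closed"` or `"periodic"`.
#' @param origin grid corner coordinates.
#' @return A [PopulationRaster-class].
#' @export
populationRaster <- function(values, cellSize = 1, landMask = NULL,
                             boundary = "closed", origin = c(0, 0)) {
  if (is.null(landMask)) landMask <- matrix(TRUE, nrow(values), ncol(values))
  values[!landMask] <- 0
  new("PopulationRaster", values = values, cellSize = cellSize,
      landMask = landMask, boundary = boundary, origin = as.numeric(origin))
}

#' Metropolitan-fraction field from city cores
#'
#' The default convention: every speaker within distance `coreFactor * R_i`
#' of a city centre behaves entirely as a metropolitan (`M = 1`); everyone
#' else is non-metropolitan (`M = 0`).
#'
#' @param raster a [PopulationRaster-class].
#' @param cities list of [CitySpec-class]; `NULL` gives `M = 0` everywhere.
#' @param coreFactor multiplier c applied to each city radius.
#' @param values optional explicit matrix of metropolitan fractions,
#'   overriding the indicator construction.
#' @return A [MetropolitanField-class].
#' @export
metropolitanField <- function(raster, cities = NULL, coreFactor = 1,
                              values = NULL) {
  d <- dim(raster@values)
  if (!is.null(values)) {
    stopifnot(identical(dim(values), d))
    return(new("MetropolitanField", values = values))
  }
  M <- matrix(0, d[1], d[2])
  if (!is.null(cities) && length(cities)) {
    xs <- raster@origin[1] + (seq_len(d[1]) - 0.5) * raster@cellSize
    ys <- raster@origin[2] + (seq_len(d[2]) - 0.5) * raster@cellSize
    X <- matrix(xs, d[1], d[2])
    Y <- matrix(ys, d[1], d[2], byrow = TRUE)
    for (ct in cities) {
      d2 <- (X - ct@center[1])^2 + (Y - ct@center[2])^2
      M[d2 <= (coreFactor * ct@radius)^2] <- 1
    }
  }
  M[!raster@landMask] <- 0
  new("MetropolitanField", values = M)
}

## ---- accessors ----

#' Raster accessors
#'
#' Small accessors for [PopulationRaster-class] geometry: the density
#' matrix, land mask, cell size, boundary mode, and physical cell-centre
#' coordinate vectors.
#'
#' @param x a [PopulationRaster-class].
#' @return `rasterValues`: numeric matrix; `landMask`: logical matrix;
#'   `cellSize`, `boundaryMode`: scalars; `cellCenters`: list with `x`, `y`.
#' @name raster-accessors
NULL

#' @rdname raster-accessors
#' @export
rasterValues <- function(x) x@values

#' @rdname raster-accessors
#' @export
landMask <- function(x) x@landMask

#' @rdname raster-accessors
#' @export
cellSize <- function(x) x@cellSize

#' @rdname raster-accessors
#' @export
boundaryMode <- function(x) x@boundary

#' @rdname raster-accessors
#' @export
cellCenters <- function(x) {
  d <- dim(x@values)
  list(x = x@origin[1] + (seq_len(d[1]) - 0.5) * x@cellSize,
       y = x@origin[2] + (seq_len(d[2]) - 0.5) * x@cellSize)
}
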