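#' Ensemble of equilibrium modal-variant maps
#'
#' @slot modal list of logical matrices (A modal per cell), one per run.
#' @slot raster the shared geometry.
#' @slot converged logical vector, per-run convergence flags.
#' @export
setClass("EnsembleResult",
  representation(modal = "list", raster = "PopulationRaster",
                 converged = "logical"))

setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf("EnsembleResult: %d runs on %d x %d grid (%d converged)\n",
              length(object@modal), nrow(object@raster@values),
              ncol(object@raster@values), sum(object@converged)))
})

#' Clustering pipeline configuration
#'
#' @param sigmaS population smoothing length (>= 0).
#' @param nRuns ensemble size (>= 2).
#' @param nC number of dialect clusters (>= 2); set it to the reference
#'   map's count (no automatic model selection).
#' @param samplePoints number of scored locations (`NULL` = every land
#'   cell; the full grid is appropriate for small fixtures).
#' @param tEnd evolution time per run.
#' @param dt solver step.
#' @param seed master seed; run k uses `seed + k`.
#' @return A list with class `"ClusteringConfig"`.
#' @export
clusteringConfig <- function(sigmaS = 0, nRuns = 20, nC = 2,
                             samplePoints = NULL, tEnd = 100, dt = 0.2,
                             seed = 1) {
  stopifnot(sigmaS >= 0, nRuns >= 2, nC >= 2)
  structure(list(sigmaS = sigmaS, nRuns = nRuns, nC = nC,
                 samplePoints = samplePoints, tEnd = tEnd, dt = dt,
                 seed = seed),
            class = "ClusteringConfig")
}

#' Boundary-aware Gaussian smoothing of a population raster
#'
#' Spreads each cell's population with a Gaussian of scale `sigmaS`,
#' renormalizing each source over land so that mass falling off-land
#' (beyond a coastline) is re-apportioned onto land: total population is
#' conserved exactly.
#'
#' @param raster a [PopulationRaster-class].
#' @param sigmaS smoothing length in physical units; 0 is the identity.
#' @return The smoothed [PopulationRaster-class].
#' @export
smoothPopulation <- function(raster, sigmaS) {
  if (sigmaS == 0) return(raster)
  d <- dim(raster@values)
  G <- .kernelFFT(d, raster@cellSize, function(x) exp(-x^2 / (2 * sigmaS^2)),
                  raster@boundary, truncate = 6 * sigmaS)
  mask <- raster@landMask * 1
  n <- .convApply(mask, G$fft, G$pad)  # per-source mass reaching land
  w <- ifelse(raster@landMask, raster@values / pmax(n, .Machine$double.eps), 0)
  out <- .convApply(w, G$fft, G$pad)
  out[!raster@landMask] <- 0
  out[out < 0] <- 0  # FFT round-off
  populationRaster(out, raster@cellSize, raster@landMask, raster@boundary,
                   raster@origin)
}

#' Run a randomized-initial-condition equilibrium ensemble
#'
#' For each of `nRuns` seeds, draws a uniform random initial memory field,
#' evolves it for `tEnd` memory timescales and records the modal-variant
#' map. Many different initial conditions are drawn toward a much smaller
#' number of stable isogloss configurations, which is what makes the
#' resulting dialect areas predictable.
#'
#' @param raster a [PopulationRaster-class] (smooth it first with
#'   [smoothPopulation()] if desired).
#' @param params a [ModelParams-class].
#' @param config a [clusteringConfig()].
#' @param dynamics `"local"` or `"nonlocal"`; the nonlocal route is
#'   required when density varies sharply on the interaction scale.
#' @param M metropolitan field for the nonlocal dynamics (default none).
#' @return An [EnsembleResult-class].
#' @export
runEnsemble <- function(raster, params, config,
                        dynamics = c("local", "nonlocal"), M = NULL) {
  dynamics <- match.arg(dynamics)
  op <- if (dynamics == "nonlocal")
    buildInteractionOperator(raster, M, params) else NULL
  modal <- vector("list", config$nRuns)
  conv <- logical(config$nRuns)
  for (k in seq_len(config$nRuns)) {
    st <- randomInit(raster, seed = config$seed + k)
    run <- runToEquilibrium(st, dynamics, params, op = op, raster = raster,
                            config = solverConfig(dt = config$dt,
                                                  maxTime = config$tEnd))
    modal[[k]] <- modalVariant(run$state, params)
    conv[k] <- run$converged
  }
  new("EnsembleResult", modal = modal, raster = raster, converged = conv)
}

#' Cluster locations into dialect areas
#'
#' At each scored location, the binary vector of modal variants across
#' ensemble runs defines the local "dialect". Locations are grouped by
#' Ward-linkage agglomerative clustering of these vectors (Euclidean
#' distances; Ward's criterion operates on their squares) and the tree is
#' cut into `nC` clusters.
#'
#' @param ensemble an [EnsembleResult-class].
#' @param config a [clusteringConfig()] (`nC`, `samplePoints`, `seed`
#'   used).
#' @return A [DialectMap-class] over the scored locations.
#' @export
clusterDialects <- function(ensemble, config) {
  mask <- ensemble@raster@landMask
  cells <- which(mask, arr.ind = TRUE)
  if (!is.null(config$samplePoints) && config$samplePoints < nrow(cells)) {
    set.seed(config$seed)
    cells <- cells[sort(sample.int(nrow(cells), config$samplePoints)), ,
                   drop = FALSE]
  }
  X <- vapply(ensemble@modal, function(mm) mm[cells] * 1,
              numeric(nrow(cells)))
  nDistinct <- nrow(unique(X))
  if (config$nC > nDistinct)
    stop(sprintf("nC exceeds the %d distinct modal vectors", nDistinct))
  hc <- hclust(dist(X), method = "ward.D2")
  labs <- cutree(hc, k = config$nC)
  new("DialectMap", labels = as.integer(labs), cells = unname(cells),
      dims = dim(mask))
}

setMethod("show", "DialectMap", function(object) {
  cat(sprintf("DialectMap: %d locations in %d clusters\n",
              length(object@labels), length(unique(object@labels))))
})

#' Construct a dialect map directly
#'
#' @param labels integer cluster labels.
#' @param cells integer matrix (n x 2) of grid indices.
#' @param dims grid dimensions.
#' @return A [DialectMap-class].
#' @export
dialectMap <- function(labels, cells, dims) {
  new("DialectMap", labels = as.integer(labels), cells = as.matrix(cells),
      dims = as.integer(dims))
}

#' Label raster of a dialect map
#'
#' @param map a [DialectMap-class].
#' @return Integer matrix with `NA` at unscored cells.
#' @export
labelRaster <- function(map) {
  out <- matrix(NA_integer_, map@dims[1], map@dims[2])
  out[map@cells] <- map@labels
  out
}

## maximum-weight assignment between label sets via weighted bipartite
## matching
.assignLabels <- function(C) {
  ka <- nrow(C); kb <- ncol(C)
  edges <- as.vector(rbind(rep(seq_len(ka), kb),
                           ka + rep(seq_len(kb), each = ka)))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, ka), rep(TRUE, kb)),
                                    edges = edges)
  igraph::E(g)$weight <- as.vector(C) + 1e-12  # keep zero-overlap edges
  m <- igraph::max_bipartite_match(g)
  match <- m$matching[seq_len(ka)] - ka
  match[match < 1 | is.na(match)] <- NA
  match
}

#' Overlap between two dialect maps after optimal label alignment
#'
#' Builds the label-confusion matrix over the common scored locations,
#' solves the optimal assignment between the two label sets
#' (maximum-weight bipartite matching, the Hungarian-algorithm step) and
#' reports `OL`, the fraction of land area with matching labels, and
#' `WOL`, the population-weighted fraction (when `population` is given).
#' Both are invariant to relabelling of either map.
#'
#' @param mapA,mapB [DialectMap-class] objects on the same geometry and
#'   scored locations (label counts may differ).
#' @param population optional [PopulationRaster-class] for `WOL`.
#' @return List with `OL`, `WOL` (`NA` without population), and `mapping`
#'   (the label permutation applied to `mapA`).
#' @export
alignAndOverlap <- function(mapA, mapB, population = NULL) {
  if (!identical(mapA@dims, mapB@dims))
    stop("maps are on different geometries")
  keyA <- paste(mapA@cells[, 1], mapA@cells[, 2])
  keyB <- paste(mapB@cells[, 1], mapB@cells[, 2])
  common <- intersect(keyA, keyB)
  if (!length(common)) stop("maps share no scored locations")
  ia <- match(common, keyA); ib <- match(common, keyB)
  la <- mapA@labels[ia]; lb <- mapB@labels[ib]
  cells <- mapA@cells[ia, , drop = FALSE]
  overlapOf <- function(w) {
    C <- matrix(0, max(la), max(lb))
    for (k in seq_along(la)) C[la[k], lb[k]] <- C[la[k], lb[k]] + w[k]
    mp <- .assignLabels(C)
    agree <- sum(vapply(seq_len(nrow(C)), function(r)
      if (is.na(mp[r])) 0 else C[r, mp[r]], numeric(1)))
    list(value = agree / sum(C), mapping = mp)
  }
  ol <- overlapOf(rep(1, length(la)))
  wol <- if (!is.null(population))
    overlapOf(population@values[cells])$value else NA_real_
  list(OL = ol$value, WOL = wol, mapping = ol$mapping)
}

#' Voronoi null model for dialect areas
#'
#' Draws `nC` seed points uniformly at random from the land cells and
#' labels every land cell by its nearest seed (ties to the lowest seed
#' index). The tessellation encodes no assumption about how dialects
#' form, making it the natural null against which pipeline-vs-reference
#' overlap is judged.
#'
#' @param raster a [PopulationRaster-class].
#' @param nC number of cells in the tessellation.
#' @param seed integer seed.
#' @return A [DialectMap-class] over all land cells.
#' @export
voronoiNull <- function(raster, nC, seed = NULL) {
  cells <- which(raster@landMask, arr.ind = TRUE)
  if (nC > nrow(cells)) stop("nC exceeds the number of land cells")
  if (!is.null(seed)) set.seed(seed)
  ctr <- cells[sample.int(nrow(cells), nC), , drop = FALSE]
  d2 <- outer(cells[, 1], ctr[, 1], "-")^2 + outer(cells[, 2], ctr[, 2], "-")^2
  labs <- max.col(-d2, ties.method = "first")
  new("DialectMap", labels = as.integer(labs), cells = unname(cells),
      dims = dim(raster@landMask))
}
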