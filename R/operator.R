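## FFT convolution machinery shared by the interaction operator, the local
## dynamics and population smoothing.

#' @importFrom stats fft nextn
NULL

## Padded-grid kernel transform. `kernelFun` maps physical distance to
## weight. Closed boundaries use zero padding (linear convolution);
## periodic boundaries use the minimum-image displacement on the torus.
.kernelFFT <- function(dims, cellSize, kernelFun, boundary, truncate = Inf) {
  if (boundary == "periodic") {
    pad <- as.integer(dims)
  } else {
    pad <- as.integer(c(nextn(2L * dims[1] - 1L, c(2, 3, 5)),
                        nextn(2L * dims[2] - 1L, c(2, 3, 5))))
  }
  offs <- function(n) {
    i <- 0:(n - 1)
    ifelse(i <= n %/% 2, i, i - n)
  }
  dx <- offs(pad[1]) * cellSize
  dy <- offs(pad[2]) * cellSize
  d <- sqrt(outer(dx^2, dy^2, "+"))
  K <- kernelFun(d)
  K[d > truncate] <- 0
  list(fft = fft(K), pad = pad)
}

.convApply <- function(z, fftK, pad) {
  nx <- nrow(z); ny <- ncol(z)
  if (all(pad == c(nx, ny))) {
    zp <- z
  } else {
    zp <- matrix(0, pad[1], pad[2])
    zp[seq_len(nx), seq_len(ny)] <- z
  }
  out <- Re(fft(fft(zp) * fftK, inverse = TRUE)) / prod(pad)
  out[seq_len(nx), seq_len(ny)]
}

#' Build the discretized interaction operator
#'
#' Discretizes the interaction density on the raster grid. The weight of
#' cell 2 in the sample of cell 1 is proportional to
#' `{(1 - M1 M2) exp(-d^2 / (2 sigma^2)) + M1 M2 / (1 + d^2 / gamma^2)} *
#' rho(r2)`, row-normalized to 1 over land cells, with `d` the Euclidean
#' travel distance (minimum-image on periodic rasters). The Gaussian kernel
#' is truncated at `5 sigma` (truncation error below 1e-5); the Lorentzian
#' is never truncated. Closed (coastline) boundaries are realized by zero
#' density off land plus per-row renormalization over land, which is what
#' makes equilibrium isoglosses meet coastlines perpendicularly.
#'
#' @param raster a [PopulationRaster-class].
#' @param M a [MetropolitanField-class] (or `NULL` for no metropolitans).
#' @param params a [ModelParams-class] supplying `sigma` and `gamma`.
#' @return An [InteractionOperator-class].
#' @export
buildInteractionOperator <- function(raster, M = NULL, params = modelParams()) {
  d <- dim(raster@values)
  if (!any(raster@landMask)) stop("empty land mask")
  if (is.null(M)) M <- metropolitanField(raster)
  if (!identical(dim(M@values), d)) stop("raster and M geometry disagree")
  sig <- params@sigma; gam <- params@gamma
  G <- .kernelFFT(d, raster@cellSize, function(x) exp(-x^2 / (2 * sig^2)),
                  raster@boundary, truncate = 5 * sig)
  L <- .kernelFFT(d, raster@cellSize, function(x) 1 / (1 + x^2 / gam^2),
                  raster@boundary)
  op <- new("InteractionOperator", raster = raster, M = M@values,
            params = params, fftG = G$fft, fftL = L$fft, pad = G$pad,
            norm = matrix(0, d[1], d[2]))
  N <- .opNumerator(op, matrix(1, d[1], d[2]))
  bad <- raster@landMask & (N <= 0)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("land cell (%d, %d) has no reachable population", ij[1], ij[2]))
  }
  op@norm <- N
  op
}

## Unnormalized application: sum_j [(1-M1 M2) G + M1 M2 L] rho_j f_j.
## Expands to C_G(rho f) - M * C_G(M rho f) + M * C_L(M rho f), each a
## convolution, so cost is a handful of FFTs regardless of grid size.
.opNumerator <- function(op, f) {
  rho <- op@raster@values
  f0 <- f
  f0[!op@raster@landMask] <- 0
  rf <- rho * f0
  out <- .convApply(rf, op@fftG, op@pad)
  if (any(op@M > 0)) {
    mrf <- op@M * rf
    out <- out - op@M * .convApply(mrf, op@fftG, op@pad) +
      op@M * .convApply(mrf, op@fftL, op@pad)
  }
  out
}

#' Spatial average of a field under the interaction operator
#'
#' Returns the interaction-density-weighted average `fbar(r) = sum_j
#' psi(r, r_j) f(r_j) dA`. Because rows are normalized, a constant field is
#' returned unchanged and the output is bounded by the input range.
#'
#' @param f numeric matrix on the raster grid (values off land are ignored).
#' @param op an [InteractionOperator-class].
#' @return Numeric matrix; `NA` off land.
#' @export
spatialAverage <- function(f, op) {
  if (!identical(dim(f), dim(op@raster@values)))
    stop("field geometry does not match operator")
  if (any(!is.finite(f[op@raster@landMask])))
    stop("field must be finite on land cells")
  out <- .opNumerator(op, f) / op@norm
  out[!op@raster@landMask] <- NA_real_
  out
}

#' Dense row-stochastic weight matrix (small grids)
#'
#' Materializes the operator as an explicit matrix over land cells,
#' computing every pairwise weight directly. Intended for small grids and
#' as a brute-force cross-check of the convolution-based application.
#'
#' @param raster a [PopulationRaster-class].
#' @param M a [MetropolitanField-class] (or `NULL`).
#' @param params a [ModelParams-class].
#' @return A `nLand x nLand` matrix whose rows sum to 1; the land cell
#'   linear indices are attached as attribute `"cells"`.
#' @export
denseWeights <- function(raster, M = NULL, params = modelParams()) {
  d <- dim(raster@values)
  if (prod(d) > 4096) stop("denseWeights is intended for grids up to 64 x 64")
  if (is.null(M)) M <- metropolitanField(raster)
  cells <- which(raster@landMask)
  ij <- arrayInd(cells, d)
  h <- raster@cellSize
  dx <- abs(outer(ij[, 1], ij[, 1], "-"))
  dy <- abs(outer(ij[, 2], ij[, 2], "-"))
  if (raster@boundary == "periodic") {
    dx <- pmin(dx, d[1] - dx)
    dy <- pmin(dy, d[2] - dy)
  }
  d2 <- (dx * h)^2 + (dy * h)^2
  sig <- params@sigma; gam <- params@gamma
  G <- exp(-d2 / (2 * sig^2))
  G[sqrt(d2) > 5 * sig] <- 0
  Lor <- 1 / (1 + d2 / gam^2)
  M12 <- outer(M@values[cells], M@values[cells])
  W <- ((1 - M12) * G + M12 * Lor) *
    matrix(raster@values[cells], length(cells), length(cells), byrow = TRUE)
  rs <- rowSums(W)
  if (any(rs <= 0)) {
    k <- which(rs <= 0)[1]
    stop(sprintf("land cell (%d, %d) has no reachable population",
                 ij[k, 1], ij[k, 2]))
  }
  W <- W / rs
  attr(W, "cells") <- cells
  W
}

setMethod("show", "InteractionOperator", function(object) {
  d <- dim(object@raster@values)
  cat(sprintf(
    "InteractionOperator on %d x %d grid (sigma=%g, gamma=%g, %s)\n",
    d[1], d[2], object@params@sigma, object@params@gamma,
    object@raster@boundary))
})

#' Unnormalized interaction weight between two cell sets
#'
#' Sums the raw (pre-normalization) interaction density over all pairs
#' with one cell in `cellsA` and one in `cellsB`. For two compact fully
#' metropolitan blobs far apart this reproduces the gravity law: weight
#' approximately proportional to `P1 P2 / r^2`.
#'
#' @param raster a [PopulationRaster-class].
#' @param M a [MetropolitanField-class] (or `NULL`).
#' @param params a [ModelParams-class].
#' @param cellsA,cellsB integer matrices (n x 2) of grid indices.
#' @return Scalar total weight (density-weighted both ways).
#' @export
interRegionWeight <- function(raster, M, params, cellsA, cellsB) {
  if (is.null(M)) M <- metropolitanField(raster)
  h <- raster@cellSize
  dx <- abs(outer(cellsA[, 1], cellsB[, 1], "-"))
  dy <- abs(outer(cellsA[, 2], cellsB[, 2], "-"))
  d <- dim(raster@values)
  if (raster@boundary == "periodic") {
    dx <- pmin(dx, d[1] - dx)
    dy <- pmin(dy, d[2] - dy)
  }
  d2 <- (dx * h)^2 + (dy * h)^2
  G <- exp(-d2 / (2 * params@sigma^2))
  G[sqrt(d2) > 5 * params@sigma] <- 0
  Lor <- 1 / (1 + d2 / params@gamma^2)
  M12 <- outer(M@values[cellsA], M@values[cellsB])
  W <- ((1 - M12) * G + M12 * Lor) *
    outer(raster@values[cellsA], raster@values[cellsB])
  sum(W)
}
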