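#' Solver configuration
#'
#' @param dt forward-Euler time step in units of the memory timescale
#'   (0 < dt <= 1). Equilibria of both dynamics are fixed points of
#'   `fbar = m` and therefore do not depend on `dt`.
#' @param tol equilibrium tolerance on `max |dm/dt|`.
#' @param maxTime time cap; a run reaching it is flagged non-converged.
#' @param seed integer seed for randomized initialization (or `NULL`).
#' @return A list with class `"SolverConfig"`.
#' @export
solverConfig <- function(dt = 0.1, tol = 1e-6, maxTime = 2000, seed = NULL) {
  stopifnot(dt > 0, dt <= 1, tol > 0, maxTime > 0)
  structure(list(dt = dt, tol = tol, maxTime = maxTime, seed = seed),
            class = "SolverConfig")
}

#' Create a memory-field state
#'
#' @param m numeric matrix of memories in `[0, 1]` (off-land cells may be
#'   anything; they are set to `NA`).
#' @param raster the [PopulationRaster-class] fixing the geometry.
#' @param t elapsed time.
#' @return A [FieldState-class].
#' @export
fieldState <- function(m, raster, t = 0) {
  stopifnot(identical(dim(m), dim(raster@values)))
  m[!raster@landMask] <- NA_real_
  new("FieldState", m = m, t = t)
}

#' Random uniform initial condition
#'
#' Memory at each land cell drawn i.i.d. uniform on `[0, 1]`; used to
#' explore the basin structure of the equilibrium isogloss configurations.
#'
#' @param raster a [PopulationRaster-class].
#' @param seed integer seed; the draw is reproducible per seed.
#' @return A [FieldState-class] at `t = 0`.
#' @export
randomInit <- function(raster, seed = NULL) {
  d <- dim(raster@values)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(runif(prod(d)), d[1], d[2])
  fieldState(m, raster)
}

.checkState <- function(m, mask) {
  bad <- mask & !is.finite(m)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite memory at land cell (%d, %d)", ij[1], ij[2]))
  }
}

#' One step of the nonlocal memory dynamics
#'
#' Forward-Euler update `m <- m + dt (fbar - m)` where
#' `fbar = spatialAverage(p(m))`. Because `fbar` is a convex combination of
#' values in `[0, 1]`, the update keeps memories in `[0, 1]` for any
#' `dt <= 1`.
#'
#' @param state a [FieldState-class].
#' @param op an [InteractionOperator-class].
#' @param params a [ModelParams-class].
#' @param dt time step (<= 1).
#' @return The advanced [FieldState-class].
#' @export
stepNonlocal <- function(state, op, params, dt = 0.1) {
  stopifnot(dt <= 1)
  mask <- op@raster@landMask
  m <- state@m
  .checkState(m, mask)
  f <- conformityMap(m, params)
  fbar <- spatialAverage(ifelse(mask, f, 0), op)
  m2 <- m + dt * (fbar - m)
  m2[mask] <- pmin(pmax(m2[mask], 0), 1)  # guard FFT round-off
  new("FieldState", m = m2, t = state@t + dt)
}

## 5-point Laplacian with zero-flux (mirror) ghosts at closed boundaries
## and off-land cells, or wrap-around for periodic rasters.
.laplacian <- function(z, h, boundary, mask) {
  nx <- nrow(z); ny <- ncol(z)
  z0 <- ifelse(mask, z, 0)
  if (boundary == "periodic") {
    up <- z0[c(nx, seq_len(nx - 1)), , drop = FALSE]
    dn <- z0[c(seq_len(nx - 1) + 1, 1), , drop = FALSE]
    lf <- z0[, c(ny, seq_len(ny - 1)), drop = FALSE]
    rt <- z0[, c(seq_len(ny - 1) + 1, 1), drop = FALSE]
    mu <- mask[c(nx, seq_len(nx - 1)), , drop = FALSE]
    md <- mask[c(seq_len(nx - 1) + 1, 1), , drop = FALSE]
    ml <- mask[, c(ny, seq_len(ny - 1)), drop = FALSE]
    mr <- mask[, c(seq_len(ny - 1) + 1, 1), drop = FALSE]
  } else {
    up <- z0[c(1, seq_len(nx - 1)), , drop = FALSE]
    dn <- z0[c(seq_len(nx - 1) + 1, nx), , drop = FALSE]
    lf <- z0[, c(1, seq_len(ny - 1)), drop = FALSE]
    rt <- z0[, c(seq_len(ny - 1) + 1, ny), drop = FALSE]
    mu <- mask[c(1, seq_len(nx - 1)), , drop = FALSE]
    md <- mask[c(seq_len(nx - 1) + 1, nx), , drop = FALSE]
    ml <- mask[, c(1, seq_len(ny - 1)), drop = FALSE]
    mr <- mask[, c(seq_len(ny - 1) + 1, ny), drop = FALSE]
  }
  ## mirror ghost: off-land neighbours contribute the centre value
  s <- ifelse(mu, up, z0) + ifelse(md, dn, z0) +
       ifelse(ml, lf, z0) + ifelse(mr, rt, z0)
  (s - 4 * z0) / h^2
}

#' One step of the local (reduced) dynamics
#'
#' Forward-Euler update of the saddle-point reduction of the nonlocal
#' equation, valid where population density varies slowly on the scale of
#' short-range interactions:
#' `m <- m + dt (f - m + (sigma^2 / 2) lap(rho f) / rho)` with `f = p(m)`.
#' The discrete Laplacian is the 5-point stencil; closed boundaries and
#' coastlines use mirrored (zero-flux) ghost cells.
#'
#' @param state a [FieldState-class].
#' @param raster a [PopulationRaster-class] with strictly positive density
#'   on land.
#' @param params a [ModelParams-class].
#' @param dt time step; for stability keep
#'   `dt < cellSize^2 / (2 sigma^2 beta)` or rely on the `[0, 1]` clip.
#' @return The advanced [FieldState-class].
#' @export
stepLocal <- function(state, raster, params, dt = 0.1) {
  stopifnot(dt <= 1)
  mask <- raster@landMask
  rho <- raster@values
  if (any(mask & rho == 0)) stop("zero density on a land cell")
  m <- state@m
  .checkState(m, mask)
  f <- conformityMap(ifelse(mask, m, 0.5), params)
  lap <- .laplacian(rho * f, raster@cellSize, raster@boundary, mask)
  md <- f - ifelse(mask, m, 0) + (params@sigma^2 / 2) * lap / ifelse(mask, rho, 1)
  m2 <- m + dt * md
  m2[mask] <- pmin(pmax(m2[mask], 0), 1)
  m2[!mask] <- NA_real_
  new("FieldState", m = m2, t = state@t + dt)
}

#' Evolve a field state to equilibrium
#'
#' Repeats the chosen update until `max |dm/dt|` stays below `config$tol`
#' for 10 consecutive steps, or until `config$maxTime` is reached (in which
#' case the run is flagged non-converged, not an error).
#'
#' @param state initial [FieldState-class].
#' @param dynamics `"nonlocal"` (requires `op`) or `"local"` (requires
#'   `raster`).
#' @param params a [ModelParams-class].
#' @param op an [InteractionOperator-class] for the nonlocal dynamics.
#' @param raster a [PopulationRaster-class] for the local dynamics.
#' @param config a [solverConfig()].
#' @param snapshotTimes optional numeric vector of times at which to record
#'   intermediate states.
#' @return A list with elements `state`, `steps`, `residual`, `converged`,
#'   and `snapshots` (a list of [FieldState-class], possibly empty).
#' @export
runToEquilibrium <- function(state, dynamics = c("nonlocal", "local"),
                             params, op = NULL, raster = NULL,
                             config = solverConfig(),
                             snapshotTimes = numeric()) {
  dynamics <- match.arg(dynamics)
  if (dynamics == "nonlocal" && is.null(op))
    stop("nonlocal dynamics requires an interaction operator")
  if (dynamics == "local" && is.null(raster))
    stop("local dynamics requires a raster")
  if (dynamics == "nonlocal") raster <- op@raster
  mask <- raster@landMask
  dt <- config$dt
  consec <- 0L
  steps <- 0L
  res <- Inf
  snaps <- list()
  snapQueue <- sort(snapshotTimes)
  while (state@t < config$maxTime) {
    prev <- state@m
    state <- if (dynamics == "nonlocal") {
      stepNonlocal(state, op, params, dt)
    } else {
      stepLocal(state, raster, params, dt)
    }
    steps <- steps + 1L
    res <- max(abs(state@m[mask] - prev[mask])) / dt
    consec <- if (res < config$tol) consec + 1L else 0L
    while (length(snapQueue) && state@t >= snapQueue[1] - 1e-9) {
      snaps[[length(snaps) + 1L]] <- state
      snapQueue <- snapQueue[-1]
    }
    if (consec >= 10L) break
  }
  list(state = state, steps = steps, residual = res,
       converged = consec >= 10L, snapshots = snaps)
}

#' Frequency field of a state
#'
#' The derived usage-frequency view `f = p(m)` of a memory state.
#'
#' @param state a [FieldState-class].
#' @param params a [ModelParams-class].
#' @return Numeric matrix (NA off land).
#' @export
frequencyField <- function(state, params) {
  f <- state@m
  ok <- is.finite(f)
  f[ok] <- conformityMap(f[ok], params)
  f
}

#' Modal-variant map of a state
#'
#' `TRUE` where variant A is locally modal, i.e. `f >= 1/2` (ties broken
#' toward A).
#'
#' @inheritParams frequencyField
#' @return Logical matrix (NA off land).
#' @export
modalVariant <- function(state, params) {
  frequencyField(state, params) >= 0.5
}
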