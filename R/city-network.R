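#' Create a city network for the hierarchical-diffusion reduction
#'
#' Cities are reduced to points carrying the populations of their
#' metropolitan cores; long-range coupling between cores follows the
#' gravity rule, a Lorentzian of separation with scale `gamma`.
#'
#' @param positions numeric matrix (n x 2) of city centres.
#' @param populations numeric vector of core populations.
#' @param params a [ModelParams-class] (`gamma`, `beta`, `alpha` used).
#' @param coreFactor core-radius multiplier c (default 1).
#' @param radii optional core radii (needed by
#'   [coreInteractionFraction()]).
#' @return A [CityNetwork-class].
#' @export
cityNetwork <- function(positions, populations, params = modelParams(),
                        coreFactor = 1, radii = NA_real_) {
  positions <- as.matrix(positions)
  if (length(radii) == 1 && is.na(radii))
    radii <- rep(NA_real_, nrow(positions))
  new("CityNetwork", positions = positions,
      populations = as.numeric(populations), params = params,
      coreFactor = coreFactor, radii = as.numeric(radii))
}

setMethod("show", "CityNetwork", function(object) {
  cat(sprintf("CityNetwork: %d cities, populations [%g, %g], gamma=%g\n",
              nrow(object@positions), min(object@populations),
              max(object@populations), object@params@gamma))
})

#' Row-normalized interaction weights between city cores
#'
#' `W[i, i] = P_i / N_i` and `W[i, j] = P_j / (1 + r_ij^2 / gamma^2) / N_i`
#' with `N_i = P_i + sum_j P_j / (1 + r_ij^2 / gamma^2)`: the language
#' sample of a speaker in core i is its own core plus gravity-weighted
#' contributions from every other core.
#'
#' @param net a [CityNetwork-class].
#' @return Row-stochastic numeric matrix.
#' @export
networkWeights <- function(net) {
  n <- nrow(net@positions)
  P <- net@populations
  d <- as.matrix(dist(net@positions))
  if (n > 1 && any(d[upper.tri(d)] == 0)) stop("coincident cities")
  W <- matrix(P, n, n, byrow = TRUE) / (1 + d^2 / net@params@gamma^2)
  diag(W) <- P
  W <- W / rowSums(W)
  dimnames(W) <- NULL
  W
}

#' Integrate the city ODE system
#'
#' Solves `dm_i/dt = sum_j W_ij p(m_j) - m_i` (hierarchical diffusion of a
#' variant between city cores) with a classical fixed-step 4th-order
#' Runge-Kutta scheme. The row-stochastic weights keep memories in
#' `[0, 1]`.
#'
#' @param net a [CityNetwork-class].
#' @param m0 initial memories in `[0, 1]` (one per city).
#' @param T final time (units of the memory timescale).
#' @param dt integrator step (<= 1).
#' @param recordEvery record interval for the returned trajectory.
#' @return A [CityTrajectory-class].
#' @export
simulateCityOdes <- function(net, m0, T, dt = 0.01, recordEvery = 0.5) {
  if (dt > 1) stop("dt must be <= 1")
  stopifnot(all(m0 >= 0 & m0 <= 1), length(m0) == nrow(net@positions))
  W <- networkWeights(net)
  p <- net@params
  rhs <- function(t, m, parms) {
    list(as.vector(W %*% conformityMap(pmin(pmax(m, 0), 1), p)) - m)
  }
  times <- seq(0, T, by = dt)
  sol <- deSolve::ode(y = m0, times = times, func = rhs, parms = NULL,
                      method = "rk4")
  keep <- unique(c(seq(1, nrow(sol), by = max(1L, round(recordEvery / dt))),
                   nrow(sol)))
  m <- pmin(pmax(sol[keep, -1, drop = FALSE], 0), 1)
  f <- apply(m, 2, conformityMap, params = p)
  new("CityTrajectory", times = sol[keep, 1], m = unname(m),
      f = matrix(f, nrow = length(keep)))
}

setMethod("show", "CityTrajectory", function(object) {
  cat(sprintf("CityTrajectory: %d cities over t in [%g, %g]\n",
              ncol(object@m), min(object@times), max(object@times)))
})

#' Tidy data frame of a city trajectory
#'
#' @param traj a [CityTrajectory-class].
#' @return Data frame with columns `t`, `city`, `m`, `f`.
#' @export
trajectoryToDataFrame <- function(traj) {
  n <- ncol(traj@m)
  data.frame(t = rep(traj@times, n),
             city = rep(seq_len(n), each = length(traj@times)),
             m = as.vector(traj@m), f = as.vector(traj@f))
}

#' First time each city's frequency crosses 1/2
#'
#' Cities that never cross within the simulated horizon get `NA`; a city
#' that "never adopts" is reported through `max_t f_i(t) < 1/2`, not a
#' special state.
#'
#' @param traj a [CityTrajectory-class].
#' @return Numeric vector of adoption times (NA when never).
#' @export
adoptionTimes <- function(traj) {
  apply(traj@f, 2, function(fc) {
    k <- which(fc >= 0.5)
    if (length(k)) traj@times[k[1]] else NA_real_
  })
}

#' Fraction of a core speaker's interactions within their own city
#'
#' Numeric quadrature of the two-kernel split for a centrally located
#' speaker of city `i`: Lorentzian-weighted density inside the
#' metropolitan core (radius `c R_i`) plus Gaussian-weighted density
#' outside, normalized by the same quantity plus the gravity-weighted
#' populations of all other cores. For an isolated city with
#' `sigma << c R_i << gamma` the fraction approaches 1, and in general the
#' own-core population dominates.
#'
#' @param i city index.
#' @param net a [CityNetwork-class] with `radii` set.
#' @param sigma short-range interaction scale (must satisfy
#'   `sigma < c R_i`; a warning flags the approximation-regime violation).
#' @param densityProfile radial density function `rho_i(r)`; default is
#'   the bare Gaussian with peak `populations[i] / (pi R_i^2 (1 - e^-1))`
#'   matching the core population.
#' @return Fraction in `[0, 1]`.
#' @export
coreInteractionFraction <- function(i, net, sigma, densityProfile = NULL) {
  R <- net@radii[i]
  if (is.na(R)) stop("city radii are required")
  cR <- net@coreFactor * R
  gam <- net@params@gamma
  if (sigma >= cR)
    warning("sigma >= core radius: outside the approximation regime")
  if (is.null(densityProfile)) {
    om <- net@populations[i] / (pi * R^2 * (1 - exp(-1)))
    densityProfile <- function(r) om * exp(-r^2 / R^2)
  }
  own <- 2 * pi * (
    integrate(function(r) r * densityProfile(r) / (1 + r^2 / gam^2),
              0, cR)$value +
    integrate(function(r) r * exp(-r^2 / (2 * sigma^2)) * densityProfile(r),
              cR, Inf)$value)
  d <- sqrt(colSums((t(net@positions) - net@positions[i, ])^2))
  other <- sum((net@populations / (1 + d^2 / gam^2))[-i])
  own / (own + other)
}
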