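#' Mean-field memory dynamics under immigration
#'
#' Right-hand side of the mean-field reduction of the agent model with
#' immigration of pure-B speakers at rate `nu`:
#' `dm/dt = m^beta / (m^beta + (1 - m)^beta) - (1 + nu) m`.
#'
#' @param m mean memory in `[0, 1]` (vectorized).
#' @param beta conformity number.
#' @param nu immigration (replacement) rate per memory timescale.
#' @return Rate of change of the mean memory.
#' @export
meanFieldRhs <- function(m, beta, nu) {
  if (any(m < 0 | m > 1)) stop("m must lie in [0, 1]")
  conformityMap(m, alpha = 1, beta = beta) - (1 + nu) * m
}

#' Fixed points of the mean-field dynamics
#'
#' Locates all roots of [meanFieldRhs()] in `[0, 1]` and classifies their
#' stability by the sign of the derivative. For `nu` below the critical
#' rate the system is bistable: extinction at `m = 0` coexists with a
#' surviving dialect at `m* > 1/2`.
#'
#' @param beta conformity number.
#' @param nu immigration rate.
#' @return Data frame with columns `m` and `stable`; the surviving fixed
#'   point (largest stable root above 1/2), when present, is attached as
#'   attribute `"mStar"`.
#' @export
meanFieldFixedPoints <- function(beta, nu) {
  g <- function(m) meanFieldRhs(m, beta, nu)
  grid <- seq(0, 1, length.out = 4001)
  vg <- g(grid)
  roots <- grid[abs(vg) < 1e-14]
  s <- sign(vg)
  idx <- which(s[-length(s)] * s[-1] < 0)
  roots <- c(roots, vapply(idx, function(k)
    uniroot(g, c(grid[k], grid[k + 1]), tol = 1e-12)$root, numeric(1)))
  roots <- sort(unique(round(roots, 10)))
  h <- 1e-6
  stable <- vapply(roots, function(r) {
    a <- max(r - h, 0); b <- min(r + h, 1)
    (g(b) - g(a)) / (b - a) < 0
  }, logical(1))
  out <- data.frame(m = roots, stable = stable)
  mStar <- roots[stable & roots > 0.5]
  attr(out, "mStar") <- if (length(mStar)) max(mStar) else NA_real_
  out
}

#' Critical immigration rate
#'
#' The largest immigration rate for which the mean-field dynamics retains
#' a nonzero fixed point, computed from the tangency condition: `nu_c =
#' max_{m in (0, 1)} [p(m) / m - 1]` with `p` the conformity map at the
#' given `beta`. Above `nu_c` the variant initially used by all speakers
#' is eventually wiped out; larger conformity sustains higher immigration.
#'
#' @param beta conformity number; for `beta <= 1` there is no bistability
#'   and the rate is 0.
#' @return List with `nuC`, the tangency point `mTan`, and a `status`
#'   string.
#' @export
criticalImmigrationRate <- function(beta) {
  if (beta <= 1)
    return(list(nuC = 0, mTan = NA_real_, status = "no bistability for beta <= 1"))
  obj <- function(m) conformityMap(m, alpha = 1, beta = beta) / m - 1
  opt <- optimize(obj, c(1e-9, 1 - 1e-9), maximum = TRUE, tol = 1e-10)
  list(nuC = opt$objective, mTan = opt$maximum, status = "ok")
}

#' Solve the mean-field trajectory
#'
#' Integrates [meanFieldRhs()] from `m(0) = m0` with a fixed-step
#' 4th-order Runge-Kutta scheme.
#'
#' @param beta conformity number.
#' @param nu immigration rate.
#' @param m0 initial mean memory.
#' @param T final time.
#' @param dt integrator step.
#' @return Data frame with columns `t` and `m`.
#' @export
meanFieldTrajectory <- function(beta, nu, m0 = 1, T = 20, dt = 0.01) {
  sol <- deSolve::ode(y = c(m = m0), times = seq(0, T, by = dt),
                      func = function(t, y, p)
                        list(meanFieldRhs(min(max(y, 0), 1), beta, nu)),
                      parms = NULL, method = "rk4")
  data.frame(t = sol[, 1], m = sol[, 2])
}
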