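#' Curvature- and density-driven isogloss velocity
#'
#' The Allen-Cahn-type normal velocity of an isogloss,
#' `v = -(sigma^2 / beta) (kappa / 2 + relgrad)`, where `kappa` is the
#' signed curvature (positive when the contour bows toward the A-domain
#' interior) and `relgrad` is the directional log-density gradient
#' `grad(rho) . ghat / rho` along the outward normal `ghat`. Positive `v`
#' is motion along `ghat`. Curvature shortens isoglosses (surface tension);
#' the density term drives them away from regions of high population
#' density.
#'
#' @param kappa signed curvature (1/length).
#' @param relgrad directional relative density gradient (1/length).
#' @param params a [ModelParams-class] (`sigma`, `beta` used).
#' @return Normal velocity (length per memory timescale).
#' @export
allenCahnVelocity <- function(kappa, relgrad, params) {
  -(params@sigma^2 / params@beta) * (kappa / 2 + relgrad)
}

#' Frequency gradient across a stationary front
#'
#' Magnitude of the frequency-field gradient at the isogloss of a
#' stationary straight transition region, in the weak-conformity limit:
#' `|f'| = sqrt((4 log 2 - 1)(beta - 1) / 6) / sigma`. The front steepens
#' as `sqrt(beta - 1)` and widens linearly with `sigma`.
#'
#' @param beta conformity number (> 1).
#' @param sigma short-range interaction scale.
#' @return Gradient magnitude (1/length).
#' @export
frontGradient <- function(beta, sigma) {
  if (any(beta <= 1)) stop("frontGradient requires beta > 1")
  sqrt((4 * log(2) - 1) * (beta - 1) / 6) / sigma
}

## d p(1/2) / d alpha at alpha = 1, computed numerically so the bias
## coefficient is derived from the conformity map rather than hard-coded.
.alphaSlopeAtHalf <- function(beta, h = 1e-6) {
  (conformityMap(0.5, alpha = 1 + h, beta = beta) -
   conformityMap(0.5, alpha = 1 - h, beta = beta)) / (2 * h)
}

.curvAtHalf <- function(alpha, beta, h = 1e-4) {
  (conformityMap(0.5 + h, alpha = alpha, beta = beta) -
   2 * conformityMap(0.5, alpha = alpha, beta = beta) +
   conformityMap(0.5 - h, alpha = alpha, beta = beta)) / h^2
}

#' Linear-response coefficient of the bias-driven front speed
#'
#' For small inherent bias the straight-front speed is `|v| ~ C(beta,
#' sigma) (alpha - 1)` with `C = |dp/dalpha|_{m = 1/2, alpha = 1} * beta /
#' |f'|`, the displacement rate of the usage offset divided by the front
#' slope. `C` has the form `const * beta^2 sigma / sqrt(beta - 1)`; the
#' dimensionless constant (about 0.6376) is computed from the expansion of
#' the conformity map, not hard-coded.
#'
#' @param beta conformity number (> 1).
#' @param sigma short-range interaction scale.
#' @return Speed per unit `(alpha - 1)`, with the dimensionless constant
#'   attached as attribute `"constant"`.
#' @export
biasVelocityCoefficient <- function(beta, sigma) {
  if (beta <= 1) stop("biasVelocityCoefficient requires beta > 1")
  C <- abs(.alphaSlopeAtHalf(beta)) * beta / frontGradient(beta, sigma)
  structure(C, constant = C * sqrt(beta - 1) / (beta^2 * sigma))
}

#' Bias-driven front speed
#'
#' Speed with which a straight front in uniform density moves against the
#' A-domain when `alpha > 1` (negative when `alpha < 1`). Two routes are
#' provided. `"expansion"` evaluates the travelling-wave balance at the
#' actual `alpha`: `v = (1/2 - p(1/2)) beta / |f'| - (sigma^2 / 2) (|f'| /
#' beta) p''(1/2)`, retaining the finite-`alpha` offset and the curvature
#' of the conformity map at the isogloss. `"linear"` uses the linear
#' response `C(beta, sigma) (alpha - 1)` of
#' [biasVelocityCoefficient()]; the two agree as `alpha -> 1`.
#'
#' @param alpha inherent bias.
#' @param beta conformity number (> 1).
#' @param sigma short-range interaction scale.
#' @param method `"expansion"` or `"linear"`.
#' @return Speed against the A-domain (length per memory timescale).
#' @export
biasVelocity <- function(alpha, beta, sigma,
                         method = c("expansion", "linear")) {
  method <- match.arg(method)
  if (alpha == 1) return(0)
  if (method == "linear")
    return(as.numeric(biasVelocityCoefficient(beta, sigma)) * (alpha - 1))
  fp <- frontGradient(beta, sigma)
  (0.5 - conformityMap(0.5, alpha = alpha, beta = beta)) * beta / fp -
    (sigma^2 / 2) * (fp / beta) * .curvAtHalf(alpha, beta)
}

#' Total isogloss velocity
#'
#' Sum of the three additive contributions: surface tension (curvature),
#' population-gradient drift, and inherent bias:
#' `v = allenCahnVelocity(kappa, relgrad) - biasVelocity(alpha)`.
#' At `alpha = 1` this reduces exactly to [allenCahnVelocity()].
#'
#' @inheritParams allenCahnVelocity
#' @param biasMethod passed to [biasVelocity()].
#' @return Normal velocity along the outward normal of the A-domain.
#' @export
totalVelocity <- function(kappa, relgrad, params,
                          biasMethod = c("expansion", "linear")) {
  biasMethod <- match.arg(biasMethod)
  allenCahnVelocity(kappa, relgrad, params) -
    biasVelocity(params@alpha, params@beta, params@sigma, biasMethod)
}

#' Stable radius of an isogloss surrounding a city
#'
#' For a circular isogloss of radius `a` around a radially symmetric city
#' `rho(r) = omega exp(-r^2 / R^2) + background`, the total velocity is
#' evaluated with `kappa = 1/a` and the analytic log-density gradient
#' `relgrad(a) = -(2 a / R^2) omega e / (omega e + background)` (with
#' `e = exp(-a^2 / R^2)`; the normal points outward, down the density
#' gradient). Roots of `v(a) = 0` are located by a log-spaced scan
#' followed by bisection; each root is classified stable when `v` changes
#' from positive (expansion) to negative (shrinkage) with increasing
#' radius. Without a decaying background ratio there may be no stable
#' root; absence is a result, not an error.
#'
#' @param city a [CitySpec-class] (bare-Gaussian mode: `omega`, `radius`).
#' @param params a [ModelParams-class].
#' @param background constant background density level (>= 0).
#' @param biasMethod passed to [biasVelocity()].
#' @param maxRadius upper end of the search interval (default `10 R`).
#' @return List with `radius` (outermost stable root or `NA`), `status`,
#'   and `roots`, a data frame of all roots with stability flags.
#' @export
stableRadius <- function(city, params, background = 0,
                         biasMethod = c("expansion", "linear"),
                         maxRadius = NULL) {
  biasMethod <- match.arg(biasMethod)
  R <- city@radius; om <- city@omega
  if (is.null(maxRadius)) maxRadius <- 10 * R
  vb <- biasVelocity(params@alpha, params@beta, params@sigma, biasMethod)
  v <- function(a) {
    e <- om * exp(-a^2 / R^2)
    relgrad <- -(2 * a / R^2) * e / (e + background)
    allenCahnVelocity(1 / a, relgrad, params) - vb
  }
  grid <- exp(seq(log(R / 100), log(maxRadius), length.out = 600))
  vg <- vapply(grid, v, numeric(1))
  sgn <- sign(vg)
  idx <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  if (!length(idx)) {
    return(list(radius = NA_real_, status = "no root in (0, maxRadius]",
                roots = data.frame(radius = numeric(), stable = logical())))
  }
  roots <- vapply(idx, function(k) {
    uniroot(v, c(grid[k], grid[k + 1]), tol = 1e-8 * R)$root
  }, numeric(1))
  stable <- vg[idx] > 0  # v > 0 inside, < 0 outside => attracting
  out <- data.frame(radius = roots, stable = stable)
  st <- roots[stable]
  list(radius = if (length(st)) max(st) else NA_real_,
       status = if (length(st)) "ok" else "roots exist but none stable",
       roots = out)
}

#' Sufficient condition for a dialect domain to shrink under global mixing
#'
#' When all speakers interact through the long-range Lorentzian kernel,
#' bounding the A-domain by a covering circle sector (angle `thetaA`,
#' radius `r`) and the B-domain by an inscribed sector (angle `thetaB`,
#' radius `R`) gives the sufficient shrink condition
#' `thetaA log(1 + r^2 / gamma^2) < thetaB log(1 + R^2 / gamma^2)`.
#' In the `gamma -> Inf` limit the test compares the sector areas.
#'
#' @param thetaA,thetaB sector angles in radians.
#' @param r radius of the sector covering domain A.
#' @param R radius of the sector inscribed in domain B.
#' @param gamma long-range interaction scale.
#' @return `TRUE` when domain A is guaranteed to shrink.
#' @export
sectorShrinkTest <- function(thetaA, r, thetaB, R, gamma) {
  stopifnot(thetaA > 0, thetaA <= 2 * pi, thetaB > 0, thetaB <= 2 * pi,
            r > 0, R > 0, gamma > 0)
  thetaA * log1p(r^2 / gamma^2) < thetaB * log1p(R^2 / gamma^2)
}
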