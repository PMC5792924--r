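## Shared fixtures and cached expensive computations.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

## The bare-Gaussian city with constant background used by the
## stable-radius worked example (R = 30 sqrt(2), omega/background = 2).
workedExampleCity <- function() citySpec(c(0, 0), 2, 30 * sqrt(2))

workedExampleParams <- function(alpha) {
  modelParams(sigma = 5, beta = 1.1, alpha = alpha)
}

workedExampleRaster <- function(h = 2.5, n = 121) {
  half <- n * h / 2
  buildCityDensity(list(workedExampleCity()), n, n, h,
                   mode = "bare_gaussian", background = 1,
                   origin = c(-half, -half))
}

## Equilibrium isogloss radius of the worked example under the nonlocal
## dynamics (dt-independent fixed point; dt = 0.5 for speed).
workedExampleRadius <- function(alpha) {
  cached(paste0("weRadius", alpha), {
    r <- workedExampleRaster()
    p <- workedExampleParams(alpha)
    op <- buildInteractionOperator(r, params = p)
    cc <- cellCenters(r)
    m0 <- ifelse(outer(cc$x^2, cc$y^2, "+") < 50^2, 1, 0)
    run <- runToEquilibrium(fieldState(m0, r), "nonlocal", p, op = op,
                            config = solverConfig(dt = 0.5, maxTime = 3000))
    stopifnot(run$converged)
    cs <- extractIsoglosses(run$state, r, p)
    stopifnot(length(cs) == 1)
    measureRadius(cs[[1]], c(0, 0))$mean
  })
}

uniformRaster <- function(n, h = 1, boundary = "periodic", value = 1) {
  populationRaster(matrix(value, n, n), h, boundary = boundary)
}

discMask <- function(n, radius, h = 1) {
  xs <- (seq_len(n) - (n + 1) / 2) * h
  X <- matrix(xs, n, n); Y <- t(X)
  X^2 + Y^2 <= radius^2
}
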