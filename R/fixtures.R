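## Seeded synthetic geographies reproducing the standard experiment
## configurations used throughout the package's tests and examples.

.fixtureNames <- c("four_city", "line20", "two_lobes", "stripe_two_city",
                   "shrink_two_city", "island_sectors", "archipelago")

#' List available synthetic-geography fixtures
#'
#' @return Character vector of fixture names.
#' @export
listFixtures <- function() .fixtureNames

#' Build a named experiment fixture
#'
#' Returns the complete, seeded configuration of one of the standard
#' synthetic experiments:
#' \describe{
#'   \item{four_city}{200 x 200 landscape with two large cities
#'     (`omega = R = 10`) and two small satellites (`omega = R = 5`),
#'     hinterland radius five times the city radius, `sigma = 2 sqrt(2)`,
#'     `gamma = 25`, `beta = 1.1`, `alpha = 1`; one large city initialized
#'     to variant A. Includes the matching [CityNetwork-class] (core
#'     populations from integrating each Gaussian over its core disc).}
#'   \item{line20}{A line of 20 cities, spacing 50, `gamma = 25`, core
#'     populations `P_1 = 30`, `P_i = 5` otherwise, `m_1(0) = 1`.}
#'   \item{two_lobes}{Two-lobed land mask (lobe diameter 80) with one
#'     `omega = 10, R = 10` city per lobe, `sigma = 4`, `beta = 1.1`;
#'     stripe initial condition. Override `alpha` to study bias.}
#'   \item{stripe_two_city}{400 x 400 periodic lattice geography, two
#'     `R = 100` cities at (200, 100) and (200, 300), capped density with
#'     background 0.1, `sigma = 3`, `beta = 1.1`; equal-stripe initial
#'     memories and the mixing ramp `epsilon(t) = 5e-4 t`.}
#'   \item{shrink_two_city}{As above with radii `R = 100` and `R = 50`,
#'     `beta = 2`, fixed mixing `epsilon = 0.1`.}
#'   \item{island_sectors}{Disc island with a sector-shaped A-domain and
#'     the matching sector-bound parameters (`thetaA`, `r`, `thetaB`,
#'     `R`).}
#'   \item{archipelago}{Seeded random multi-island landscape for
#'     regionalization tests.}
#' }
#'
#' @param name fixture name (see [listFixtures()]).
#' @param overrides named list of parameter patches (unknown keys error).
#' @param seed integer seed for any randomized component.
#' @return A list with class `"isoglossFixture"`; components depend on
#'   the fixture but always include `name`, `params`, `manifest`, and
#'   where applicable `raster`, `M`, `state0`, `network`, `epsilon`,
#'   `dynamics`.
#' @export
makeFixture <- function(name, overrides = list(), seed = 1) {
  if (!name %in% .fixtureNames)
    stop("unknown fixture '", name, "'; available: ",
         paste(.fixtureNames, collapse = ", "))
  fx <- switch(name,
    four_city = .fxFourCity(overrides, seed),
    line20 = .fxLine20(overrides, seed),
    two_lobes = .fxTwoLobes(overrides, seed),
    stripe_two_city = .fxStripe(overrides, seed, shrink = FALSE),
    shrink_two_city = .fxStripe(overrides, seed, shrink = TRUE),
    island_sectors = .fxIsland(overrides, seed),
    archipelago = .fxArchipelago(overrides, seed))
  fx$name <- name
  fx$seed <- seed
  class(fx) <- "isoglossFixture"
  fx
}

#' @export
print.isoglossFixture <- function(x, ...) {
  cat(sprintf("isogloss fixture '%s' (seed %d)\n", x$name, x$seed))
  invisible(x)
}

.applyOverrides <- function(defaults, overrides) {
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop("unknown override(s): ", paste(bad, collapse = ", "))
  utils::modifyList(defaults, overrides)
}

.discState <- function(raster, center, radius) {
  d <- dim(raster@values)
  cc <- cellCenters(raster)
  X <- matrix(cc$x, d[1], d[2]); Y <- matrix(cc$y, d[1], d[2], byrow = TRUE)
  m <- ifelse((X - center[1])^2 + (Y - center[2])^2 <= radius^2, 1, 0)
  fieldState(m, raster)
}

.fxFourCity <- function(overrides, seed) {
  ## short-range scale recorded as 2*sqrt(2); the printed "22" is read as
  ## 2 sqrt(2) (overridable)
  p <- .applyOverrides(list(
    size = 200L, cellSize = 1, omegaLarge = 10, omegaSmall = 5,
    hinterlandFactor = 5, sigma = 2 * sqrt(2), gamma = 25, beta = 1.1,
    alpha = 1, largePos = list(c(25, 25), c(175, 175)),
    smallPos = list(c(65, 40), c(40, 70))), overrides)
  cities <- c(
    lapply(p$largePos, function(ct)
      citySpec(ct, p$omegaLarge, p$omegaLarge,
               p$hinterlandFactor * p$omegaLarge)),
    lapply(p$smallPos, function(ct)
      citySpec(ct, p$omegaSmall, p$omegaSmall,
               p$hinterlandFactor * p$omegaSmall)))
  raster <- buildCityDensity(cities, p$size, p$size, p$cellSize,
                             mode = "with_hinterland")
  params <- modelParams(sigma = p$sigma, gamma = p$gamma, beta = p$beta,
                        alpha = p$alpha)
  M <- metropolitanField(raster, cities)
  pops <- vapply(cities, function(ct)
    pi * ct@omega * ct@radius^2 * (1 - exp(-1)), numeric(1))
  net <- cityNetwork(do.call(rbind, lapply(cities, function(ct) ct@center)),
                     pops, params,
                     radii = vapply(cities, function(ct) ct@radius,
                                    numeric(1)))
  state0 <- .discState(raster, cities[[1]]@center, cities[[1]]@radius)
  list(raster = raster, params = params, M = M, cities = cities,
       network = net, m0 = c(1, 0, 0, 0), state0 = state0,
       dynamics = "nonlocal",
       manifest = list(omega_large = p$omegaLarge, R_large = p$omegaLarge,
                       omega_small = p$omegaSmall, R_small = p$omegaSmall,
                       hinterland_factor = p$hinterlandFactor,
                       sigma = p$sigma, gamma = p$gamma, beta = p$beta,
                       alpha = p$alpha, size = p$size))
}

.fxLine20 <- function(overrides, seed) {
  p <- .applyOverrides(list(nCities = 20L, spacing = 50, gamma = 25,
                            P1 = 30, Pother = 5, beta = 1.1, alpha = 1),
                       overrides)
  pos <- cbind((seq_len(p$nCities) - 1) * p$spacing, 0)
  pops <- c(p$P1, rep(p$Pother, p$nCities - 1))
  params <- modelParams(gamma = p$gamma, beta = p$beta, alpha = p$alpha)
  net <- cityNetwork(pos, pops, params)
  list(network = net, params = params,
       m0 = c(1, rep(0, p$nCities - 1)),
       manifest = list(n_cities = p$nCities, spacing = p$spacing,
                       gamma = p$gamma, P1 = p$P1, P_other = p$Pother,
                       beta = p$beta))
}

.fxTwoLobes <- function(overrides, seed) {
  p <- .applyOverrides(list(
    lobeDiameter = 80, centerSep = 70, cellSize = 2, omega = 10, R = 10,
    sigma = 4, beta = 1.1, alpha = 1), overrides)
  rad <- p$lobeDiameter / 2
  c1 <- c(10 + rad, 10 + rad)
  c2 <- c(10 + rad + p$centerSep, 10 + rad)
  nx <- ceiling((c2[1] + rad + 10) / p$cellSize)
  ny <- ceiling((c1[2] + rad + 10) / p$cellSize)
  xs <- (seq_len(nx) - 0.5) * p$cellSize
  ys <- (seq_len(ny) - 0.5) * p$cellSize
  X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
  mask <- ((X - c1[1])^2 + (Y - c1[2])^2 <= rad^2) |
          ((X - c2[1])^2 + (Y - c2[2])^2 <= rad^2)
  cities <- list(citySpec(c1, p$omega, p$R), citySpec(c2, p$omega, p$R))
  raster <- buildCityDensity(cities, nx, ny, p$cellSize,
                             mode = "bare_gaussian", landMask = mask)
  params <- modelParams(sigma = p$sigma, gamma = 25, beta = p$beta,
                        alpha = p$alpha)
  mid <- (c1[1] + c2[1]) / 2
  m <- ifelse(X < mid, 1, 0)
  list(raster = raster, params = params, cities = cities,
       state0 = fieldState(m, raster), dynamics = "nonlocal",
       lobeCenters = list(c1, c2),
       manifest = list(lobe_diameter = p$lobeDiameter, omega = p$omega,
                       R = p$R, sigma = p$sigma, beta = p$beta,
                       alpha = p$alpha))
}

.fxStripe <- function(overrides, seed, shrink) {
  defaults <- if (shrink) {
    list(size = 400L, R1 = 100, R2 = 50, rho0 = 0.1, sigma = 3, beta = 2,
         epsilon = 0.1, pos1 = c(200, 100), pos2 = c(200, 300))
  } else {
    list(size = 400L, R1 = 100, R2 = 100, rho0 = 0.1, sigma = 3,
         beta = 1.1, epsilonRate = 5e-4, pos1 = c(200, 100),
         pos2 = c(200, 300))
  }
  p <- .applyOverrides(defaults, overrides)
  cities <- list(citySpec(p$pos1, 1, p$R1), citySpec(p$pos2, 1, p$R2))
  raster <- buildCityDensity(cities, p$size, p$size, 1, mode = "capped",
                             background = p$rho0, boundary = "periodic")
  params <- modelParams(sigma = p$sigma, gamma = 25, beta = p$beta,
                        alpha = 1)
  ## equal stripes: variant A on the half containing city 1
  mem <- matrix(0, p$size, p$size)
  mem[, seq_len(p$size / 2)] <- 1
  eps <- if (shrink) p$epsilon else function(t) p$epsilonRate * t
  manifest <- if (shrink) {
    list(size = p$size, R1 = p$R1, R2 = p$R2, rho0 = p$rho0,
         sigma = p$sigma, beta = p$beta, epsilon = p$epsilon)
  } else {
    list(size = p$size, R = p$R1, rho0 = p$rho0, sigma = p$sigma,
         beta = p$beta, epsilon_rate = p$epsilonRate)
  }
  list(raster = raster, params = params, cities = cities,
       memoryInit = mem, epsilon = eps, manifest = manifest)
}

.fxIsland <- function(overrides, seed) {
  p <- .applyOverrides(list(islandRadius = 40, cellSize = 1,
                            thetaA = pi / 2, density = 1), overrides)
  n <- ceiling(2.2 * p$islandRadius / p$cellSize)
  xs <- (seq_len(n) - (n + 1) / 2) * p$cellSize
  X <- matrix(xs, n, n); Y <- t(X)
  mask <- X^2 + Y^2 <= p$islandRadius^2
  vals <- matrix(p$density, n, n); vals[!mask] <- 0
  raster <- populationRaster(vals, p$cellSize, mask,
                             origin = c(xs[1] - p$cellSize / 2,
                                        xs[1] - p$cellSize / 2))
  ang <- atan2(Y, X)
  m <- ifelse(abs(ang) <= p$thetaA / 2, 1, 0)
  bound <- list(thetaA = p$thetaA, r = p$islandRadius,
                thetaB = 2 * pi - p$thetaA, R = p$islandRadius)
  list(raster = raster, params = modelParams(sigma = 3, beta = 1.1),
       state0 = fieldState(m, raster), sector = bound,
       dynamics = "nonlocal",
       manifest = list(island_radius = p$islandRadius, thetaA = p$thetaA))
}

.fxArchipelago <- function(overrides, seed) {
  p <- .applyOverrides(list(size = 100L, cellSize = 1, nIslands = 5L,
                            radiusRange = c(12, 24), background = 0.5,
                            sigma = 3, beta = 1.1), overrides)
  set.seed(seed)
  n <- p$size
  xs <- (seq_len(n) - 0.5) * p$cellSize
  X <- matrix(xs, n, n); Y <- matrix(xs, n, n, byrow = TRUE)
  mask <- matrix(FALSE, n, n)
  vals <- matrix(0, n, n)
  for (k in seq_len(p$nIslands)) {
    ctr <- runif(2, 0.15 * n, 0.85 * n) * p$cellSize
    rad <- runif(1, p$radiusRange[1], p$radiusRange[2])
    d2 <- (X - ctr[1])^2 + (Y - ctr[2])^2
    mask <- mask | (d2 <= rad^2)
    vals <- vals + 3 * exp(-d2 / (rad / 2)^2)
  }
  vals <- vals + p$background
  vals[!mask] <- 0
  raster <- populationRaster(vals, p$cellSize, mask)
  list(raster = raster,
       params = modelParams(sigma = p$sigma, beta = p$beta),
       dynamics = "nonlocal",
       manifest = list(size = p$size, n_islands = p$nIslands,
                       background = p$background, sigma = p$sigma,
                       beta = p$beta))
}

#' Serialize a fixture's configuration
#'
#' Writes the fixture's parameter manifest (every headline parameter of
#' the configuration) as YAML, the same structured format consumed by
#' [readModelConfig()]-style tooling.
#'
#' @param fixture an object from [makeFixture()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
fixtureToConfig <- function(fixture, path) {
  yaml::write_yaml(c(list(name = fixture$name, seed = fixture$seed),
                     fixture$manifest), path)
  invisible(path)
}
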