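test_that("occupancy sampling is Bernoulli per site and seeded", {
  r1 <- uniformRaster(20, value = 1)
  expect_equal(nrow(sampleLattice(r1, seed = 1)@coords), 400)
  r2 <- uniformRaster(80, value = 0.1)
  n <- nrow(sampleLattice(r2, seed = 2)@coords)
  expect_lt(abs(n - 640), 3 * sqrt(640 * 0.9) + 1)
  expect_identical(sampleLattice(r2, seed = 3)@coords,
                   sampleLattice(r2, seed = 3)@coords)
  expect_error(sampleLattice(populationRaster(matrix(2, 4, 4), 1), 1),
               "capped")
})

test_that("city discs are occupied more densely than the background", {
  fx <- makeFixture("stripe_two_city",
                    overrides = list(size = 120L, R1 = 30, R2 = 30,
                                     pos1 = c(60, 30), pos2 = c(60, 90)))
  lat <- sampleLattice(fx$raster, seed = 4)
  occ <- matrix(FALSE, 120, 120); occ[lat@coords] <- TRUE
  xs <- (seq_len(120) - 0.5)
  X <- matrix(xs, 120, 120); Y <- matrix(xs, 120, 120, byrow = TRUE)
  inCity <- (X - 60)^2 + (Y - 30)^2 < 20^2
  farAway <- (X - 60)^2 + (Y - 30)^2 > 60^2 & (X - 60)^2 + (Y - 90)^2 > 60^2
  expect_gt(mean(occ[inCity]), 5 * mean(occ[farAway]))
})

test_that("embedded network links follow the Gaussian displacement law", {
  r <- uniformRaster(12, value = 1)
  hits <- 0; tries <- 0
  for (sd in 1:6) {
    lat <- buildEmbeddedNetwork(sampleLattice(r, seed = sd), sigma = 3,
                                seed = 100 + sd)
    A <- lat@adjacency
    expect_true(Matrix::isSymmetric(A))
    expect_true(all(Matrix::diag(A) == 0))
    co <- lat@coords
    # count realized links among horizontally adjacent pairs
    for (i in seq_len(nrow(co))) {
      right <- which(co[, 1] == co[i, 1] %% 12 + 1 & co[, 2] == co[i, 2])
      if (length(right)) {
        tries <- tries + 1
        hits <- hits + (A[i, right] > 0)
      }
    }
  }
  expect_equal(hits / tries, exp(-1 / 18), tolerance = 0.03)
})

test_that("expected degree matches the Gaussian lattice sum", {
  p <- 0.1; sig <- 3
  d <- as.matrix(expand.grid(-18:18, -18:18))
  H <- exp(-(d[, 1]^2 + d[, 2]^2) / (2 * sig^2))
  H <- H[!(d[, 1] == 0 & d[, 2] == 0)]
  expected <- p * sum(H)
  r <- uniformRaster(60, value = p)
  degs <- vapply(1:10, function(sd) {
    lat <- buildEmbeddedNetwork(sampleLattice(r, seed = sd), sig,
                                seed = 50 + sd)
    mean(Matrix::rowSums(lat@adjacency))
  }, numeric(1))
  expect_lt(abs(mean(degs) / expected - 1), 0.05)
})

test_that("agent updates share the fixed points and symmetry of the field model", {
  r <- uniformRaster(15, value = 1)
  p <- modelParams(sigma = 2, beta = 1.4, alpha = 1)
  lat <- buildEmbeddedNetwork(sampleLattice(r, seed = 1, memory = 1), 2,
                              seed = 2)
  expect_equal(stepAgents(lat, p, 0.1)@memory, lat@memory)
  lat05 <- lat; lat05@memory <- rep(0.5, length(lat@memory))
  expect_equal(stepAgents(lat05, p, 0.1)@memory, lat05@memory)
  set.seed(3)
  m0 <- runif(length(lat@memory))
  a <- lat; a@memory <- m0
  b <- lat; b@memory <- 1 - m0
  for (i in 1:10) { a <- stepAgents(a, p, 0.2); b <- stepAgents(b, p, 0.2) }
  expect_lt(max(abs(a@memory + b@memory - 1)), 1e-12)
})

test_that("mixing exchanges conserve the multiset of memories", {
  r <- uniformRaster(20, value = 0.5)
  lat <- sampleLattice(r, seed = 9)
  set.seed(10)
  lat@memory <- runif(length(lat@memory))
  before <- sort(lat@memory)
  set.seed(11)
  out <- applyMixing(lat, epsilon = 0.8, dt = 1)
  expect_identical(sort(out@memory), before)
  expect_false(identical(out@memory, lat@memory))
  expect_identical(applyMixing(lat, 0, 0.1)@memory, lat@memory)
  tiny <- lat; tiny@coords <- lat@coords[1, , drop = FALSE]
  tiny@memory <- lat@memory[1]
  expect_error(applyMixing(tiny, 0.5, 0.1), "at least 2")
})

test_that("immigration replaces the expected fraction with incoming memory", {
  r <- uniformRaster(40, value = 1)
  lat <- sampleLattice(r, seed = 12, memory = 1)
  expect_identical(applyImmigration(lat, 0, 0.1)@memory, lat@memory)
  set.seed(13)
  out <- applyImmigration(lat, nu = 0.5, dt = 0.5, value = 0)
  frac <- mean(out@memory == 0)
  expect_lt(abs(frac - 0.25), 4 * sqrt(0.25 * 0.75 / 1600))
})

test_that("memories stay in [0,1] under interleaved step/mix/immigrate", {
  r <- uniformRaster(20, value = 0.6)
  p <- modelParams(sigma = 2, beta = 1.8, alpha = 1.2)
  lat <- buildEmbeddedNetwork(sampleLattice(r, seed = 14, memory = 0.7), 2,
                              seed = 15)
  sim <- simulateAgents(lat, p, tEnd = 10, dt = 0.5, epsilon = 0.4,
                        nu = 0.2, seed = 16)
  expect_true(all(sim$lattice@memory >= 0 & sim$lattice@memory <= 1))
})

test_that("immigration below the critical rate sustains the dialect, above kills it", {
  r <- uniformRaster(60, value = 0.5, boundary = "periodic")
  p <- modelParams(sigma = 3, beta = 1.5)
  finals <- function(nu) vapply(1:3, function(sd) {
    lat <- buildEmbeddedNetwork(sampleLattice(r, seed = 40 + sd, memory = 1),
                                3, seed = 50 + sd)
    mean(simulateAgents(lat, p, tEnd = 60, dt = 0.1, nu = nu,
                        seed = 60 + sd)$lattice@memory)
  }, numeric(1))
  lo <- finals(0.08); hi <- finals(0.16)  # nu_c(1.5) = 0.118
  expect_true(all(lo > 0.5))
  expect_true(all(hi < 0.1))
})

test_that("fixed mixing shrinks and eliminates the small-city domain", {
  fx <- makeFixture("shrink_two_city",
                    overrides = list(size = 120L, R1 = 30, R2 = 15,
                                     pos1 = c(60, 30), pos2 = c(60, 90)))
  lat <- buildEmbeddedNetwork(
    sampleLattice(fx$raster, seed = 7, memory = fx$memoryInit), 3, seed = 8)
  sim <- simulateAgents(lat, fx$params, tEnd = 70, dt = 0.1,
                        epsilon = fx$epsilon, seed = 9, recordEvery = 5,
                        summarize = function(l)
                          c(frac = mean(conformityMap(l@memory,
                                                      fx$params) < 0.5)))
  frac <- sim$records$frac
  # smoothed over successive records the minority area never grows much
  expect_true(all(diff(frac) < 0.02))
  expect_equal(tail(frac, 1), 0)
  expect_gt(frac[1], 0.25)
})

test_that("a slow mixing ramp destroys the two-domain state", {
  fx <- makeFixture("stripe_two_city",
                    overrides = list(size = 120L, R1 = 30, R2 = 30,
                                     pos1 = c(60, 30), pos2 = c(60, 90),
                                     epsilonRate = 2e-3))
  lat <- buildEmbeddedNetwork(
    sampleLattice(fx$raster, seed = 21, memory = fx$memoryInit), 3, seed = 22)
  sim <- simulateAgents(lat, fx$params, tEnd = 100, dt = 0.1,
                        epsilon = fx$epsilon, seed = 23, recordEvery = 10,
                        summarize = function(l)
                          c(fA = mean(conformityMap(l@memory,
                                                    fx$params) >= 0.5)))
  fA <- sim$records$fA
  # balanced while mixing is weak, consensus once the ramp bites
  expect_lt(abs(fA[2] - 0.5), 0.1)
  expect_lt(min(tail(fA, 1), 1 - tail(fA, 1)), 0.02)
})
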