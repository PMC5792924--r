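test_that("uniform memories are fixed points of both dynamics", {
  r <- uniformRaster(16)
  p <- modelParams(sigma = 2, gamma = 5, beta = 1.3)
  op <- buildInteractionOperator(r, params = p)
  for (m0 in c(0.5, 1)) {
    st <- fieldState(matrix(m0, 16, 16), r)
    out1 <- stepNonlocal(st, op, p, 0.5)
    out2 <- stepLocal(st, r, p, 0.1)
    expect_lt(max(abs(out1@m - m0)), 1e-12)
    expect_lt(max(abs(out2@m - m0)), 1e-12)
  }
})

test_that("relabelling the variants is an exact symmetry when alpha = 1", {
  r <- uniformRaster(20)
  p <- modelParams(sigma = 2, gamma = 6, beta = 1.4, alpha = 1)
  op <- buildInteractionOperator(r, params = p)
  set.seed(8)
  m0 <- matrix(runif(400), 20, 20)
  a <- fieldState(m0, r); b <- fieldState(1 - m0, r)
  for (i in 1:20) {
    a <- stepNonlocal(a, op, p, 0.2)
    b <- stepNonlocal(b, op, p, 0.2)
  }
  expect_lt(max(abs(a@m + b@m - 1)), 1e-12)
  a2 <- fieldState(m0, r); b2 <- fieldState(1 - m0, r)
  for (i in 1:20) {
    a2 <- stepLocal(a2, r, p, 0.1)
    b2 <- stepLocal(b2, r, p, 0.1)
  }
  expect_lt(max(abs(a2@m + b2@m - 1)), 1e-12)
})

test_that("memories stay in [0,1] for any admissible step size", {
  set.seed(11)
  vals <- matrix(runif(15 * 15, 0.1, 4), 15, 15)
  r <- populationRaster(vals, 1, boundary = "periodic")
  p <- modelParams(sigma = 1.5, gamma = 4, beta = 2, alpha = 1.3)
  op <- buildInteractionOperator(r, params = p)
  st <- randomInit(r, seed = 3)
  for (i in 1:30) st <- stepNonlocal(st, op, p, dt = 1)
  expect_true(all(st@m >= 0 & st@m <= 1))
})

test_that("solutions translate with the initial condition on uniform ground", {
  n <- 24
  r <- uniformRaster(n)
  p <- modelParams(sigma = 2, gamma = 5, beta = 1.5)
  op <- buildInteractionOperator(r, params = p)
  set.seed(5)
  m0 <- matrix(runif(n * n), n, n)
  shift <- function(z) z[c(6:n, 1:5), c(8:n, 1:7)]
  a <- fieldState(m0, r); b <- fieldState(shift(m0), r)
  for (i in 1:15) {
    a <- stepNonlocal(a, op, p, 0.5)
    b <- stepNonlocal(b, op, p, 0.5)
  }
  expect_lt(max(abs(shift(a@m) - b@m)), 1e-10)
})

test_that("local and nonlocal steps agree to fourth order in sigma", {
  n <- 96; h <- 0.25
  r <- populationRaster(matrix(1, n, n), h, boundary = "periodic")
  cc <- cellCenters(r)
  X <- matrix(cc$x, n, n); Y <- matrix(cc$y, n, n, byrow = TRUE)
  m <- 0.5 + 0.4 * exp(-((X - 12)^2 + (Y - 12)^2) / 9)
  diffAt <- function(sig) {
    ps <- modelParams(sigma = sig, beta = 1.3)
    op <- buildInteractionOperator(r, params = ps)
    s0 <- fieldState(m, r)
    max(abs(stepNonlocal(s0, op, ps, 0.1)@m - stepLocal(s0, r, ps, 0.1)@m))
  }
  ratio <- diffAt(1) / diffAt(0.5)
  # halving sigma shrinks the one-step difference ~16x (sigma^4 residual)
  expect_gt(ratio, 10)
  expect_lt(ratio, 22)
})

test_that("random initialization is uniform, seeded, and seed-sensitive", {
  r <- uniformRaster(100)
  a <- randomInit(r, seed = 42)
  expect_lt(abs(mean(a@m) - 0.5), 0.015)
  b <- randomInit(r, seed = 42)
  expect_identical(a@m, b@m)
  c3 <- randomInit(r, seed = 43)
  expect_gt(mean(a@m != c3@m), 0.99)
})

test_that("equilibrium detection stops early and flags non-convergence", {
  r <- uniformRaster(10)
  p <- modelParams(sigma = 2, beta = 1.2)
  op <- buildInteractionOperator(r, params = p)
  run <- runToEquilibrium(fieldState(matrix(1, 10, 10), r), "nonlocal", p,
                          op = op, config = solverConfig(dt = 0.5,
                                                         maxTime = 100))
  expect_true(run$converged)
  expect_lt(run$state@t, 50)
  slow <- runToEquilibrium(randomInit(r, 1), "nonlocal", p, op = op,
                           config = solverConfig(dt = 0.1, tol = 1e-12,
                                                 maxTime = 1))
  expect_false(slow$converged)
})

test_that("a straight front on uniform ground is stationary without bias", {
  n <- 200; h <- 2
  r <- populationRaster(matrix(1, n, 4), h)
  p <- modelParams(sigma = 5, beta = 1.1, alpha = 1)
  st <- fieldState(matrix(ifelse(seq_len(n) * h < 200, 1, 0), n, 4), r)
  snaps <- list()
  for (i in 1:300) {
    st <- stepLocal(st, r, p, 0.1)
    if (i %% 50 == 0) snaps[[length(snaps) + 1]] <- st
  }
  v <- measureFrontSpeed(snaps, r, p, axis = 1, burnIn = 0.3)
  expect_lt(abs(v), 1e-3 * p@sigma)
})

test_that("total isogloss length is non-increasing during coarsening", {
  r <- uniformRaster(64)
  p <- modelParams(sigma = 3, beta = 1.5)
  op <- buildInteractionOperator(r, params = p)
  for (sd in 1:3) {
    st <- randomInit(r, seed = sd)
    lens <- c()
    for (tt in 1:60) {
      st <- stepNonlocal(st, op, p, 0.5)
      if (tt %% 10 == 0) lens <- c(lens, totalIsoglossLength(st, r, p))
    }
    expect_true(all(diff(lens) <= 1e-9 + 0.01 * lens[-length(lens)]))
  }
})

test_that("non-finite memories are reported with the offending cell", {
  r <- uniformRaster(8)
  p <- modelParams(sigma = 2)
  op <- buildInteractionOperator(r, params = p)
  m <- matrix(0.5, 8, 8); m[3, 4] <- NaN
  st <- new("FieldState", m = m, t = 0)
  expect_error(stepNonlocal(st, op, p, 0.1), "\\(3, 4\\)")
})
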