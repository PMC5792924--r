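test_that("population smoothing conserves mass and respects coastlines", {
  mask <- discMask(40, 17)
  set.seed(1)
  vals <- matrix(runif(1600, 0, 2), 40, 40); vals[!mask] <- 0
  r <- populationRaster(vals, 1, mask)
  expect_identical(smoothPopulation(r, 0), r)
  sm <- smoothPopulation(r, 4)
  expect_equal(sum(rasterValues(sm)), sum(vals), tolerance = 1e-9)
  expect_true(all(rasterValues(sm)[!mask] == 0))
  # a unit spike far from any coast spreads to the discrete Gaussian
  vals2 <- matrix(0, 60, 60); vals2[30, 30] <- 1
  r2 <- populationRaster(vals2, 1)
  sm2 <- smoothPopulation(r2, 6)
  expect_equal(rasterValues(sm2)[30, 30], 1 / (2 * pi * 36), tolerance = 0.01)
  expect_equal(sum(rasterValues(sm2)), 1, tolerance = 1e-9)
})

test_that("identical half-splits are recovered exactly by the clustering", {
  mask <- matrix(TRUE, 10, 10)
  r <- populationRaster(matrix(1, 10, 10), 1, mask)
  half <- matrix(rep(c(TRUE, FALSE), each = 50), 10, 10)
  ens <- new("EnsembleResult",
             modal = list(half, !half, half, half), raster = r,
             converged = rep(TRUE, 4))
  dm <- clusterDialects(ens, clusteringConfig(nRuns = 4, nC = 2, seed = 1))
  labs <- labelRaster(dm)
  expect_equal(length(unique(labs[half])), 1)
  expect_equal(length(unique(labs[!half])), 1)
  expect_true(labs[1, 1] != labs[10, 10])
  expect_error(clusterDialects(ens, clusteringConfig(nC = 3, seed = 1)),
               "distinct")
})

test_that("duplicating ensemble runs does not change the partition", {
  mask <- matrix(TRUE, 8, 8)
  r <- populationRaster(matrix(1, 8, 8), 1, mask)
  set.seed(7)
  runs <- lapply(1:3, function(k) matrix(runif(64) < 0.5, 8, 8))
  ensA <- new("EnsembleResult", modal = runs, raster = r,
              converged = rep(TRUE, 3))
  ensB <- new("EnsembleResult", modal = c(runs, runs), raster = r,
              converged = rep(TRUE, 6))
  cfg <- clusteringConfig(nRuns = 3, nC = 4, seed = 2)
  mA <- clusterDialects(ensA, cfg)
  mB <- clusterDialects(ensB, clusteringConfig(nRuns = 6, nC = 4, seed = 2))
  # same partition up to label names
  expect_equal(alignAndOverlap(mA, mB)$OL, 1)
})

test_that("overlap scoring is relabelling-invariant and matches brute force", {
  cells <- as.matrix(expand.grid(1:10, 1:10))
  la <- rep(1:2, each = 50)
  mA <- dialectMap(la, cells, c(10, 10))
  expect_equal(alignAndOverlap(mA, mA)$OL, 1)
  perm <- dialectMap(3 - la, cells, c(10, 10))
  expect_equal(alignAndOverlap(mA, perm)$OL, 1)
  # a shifted split only partially aligns
  shifted <- dialectMap(rep(c(1, 2), times = c(30, 70)), cells, c(10, 10))
  expect_equal(alignAndOverlap(mA, shifted)$OL, 0.8)
  # brute-force assignment oracle on random label maps
  set.seed(9)
  for (rep in 1:5) {
    lx <- sample(1:4, 100, replace = TRUE)
    ly <- sample(1:4, 100, replace = TRUE)
    mX <- dialectMap(lx, cells, c(10, 10))
    mY <- dialectMap(ly, cells, c(10, 10))
    got <- alignAndOverlap(mX, mY)$OL
    C <- unclass(table(factor(lx, 1:4), factor(ly, 1:4)))
    best <- 0
    perms <- function(v) if (length(v) == 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (pm in perms(1:4))
      best <- max(best, sum(C[cbind(1:4, pm)]))
    expect_equal(got, best / 100)
  }
})

test_that("population weighting changes the overlap accordingly", {
  cells <- as.matrix(expand.grid(1:4, 1:4))
  vals <- matrix(1, 4, 4); vals[1, 1] <- 100
  r <- populationRaster(vals, 1)
  la <- rep(1, 16); lb <- rep(2, 16)
  lb[1] <- 99  # disagree nowhere after alignment except tiny labels
  mA <- dialectMap(la, cells, c(4, 4))
  mB <- dialectMap(c(1, rep(2, 15)), cells, c(4, 4))
  out <- alignAndOverlap(mA, mB, population = r)
  # best single-label alignment: either the heavy cell or the 15 others
  expect_equal(out$OL, 15 / 16)
  expect_equal(out$WOL, 100 / 115)
})

test_that("Voronoi null model labels every cell by its nearest seed", {
  mask <- discMask(30, 13)
  r <- populationRaster(matrix(1, 30, 30) * mask, 1, mask)
  one <- voronoiNull(r, 1, seed = 5)
  expect_equal(length(unique(one@labels)), 1)
  vm <- voronoiNull(r, 5, seed = 6)
  expect_identical(voronoiNull(r, 5, seed = 6)@labels, vm@labels)
  # exhaustive nearest-seed verification
  cells <- vm@cells
  set.seed(6)
  allCells <- which(mask, arr.ind = TRUE)
  ctr <- allCells[sample.int(nrow(allCells), 5), , drop = FALSE]
  for (k in sample(nrow(cells), 50)) {
    d2 <- (cells[k, 1] - ctr[, 1])^2 + (cells[k, 2] - ctr[, 2])^2
    expect_equal(vm@labels[k], which.min(d2))
  }
  expect_error(voronoiNull(r, 1e6, 1), "exceeds")
})

test_that("pipeline output is deterministic per master seed", {
  fx <- makeFixture("archipelago", seed = 3)
  cfg <- clusteringConfig(nRuns = 5, nC = 3, tEnd = 15, dt = 0.5, seed = 9)
  m1 <- clusterDialects(runEnsemble(fx$raster, fx$params, cfg,
                                    dynamics = "nonlocal"), cfg)
  m2 <- clusterDialects(runEnsemble(fx$raster, fx$params, cfg,
                                    dynamics = "nonlocal"), cfg)
  expect_identical(m1@labels, m2@labels)
  expect_identical(m1@cells, m2@cells)
})

test_that("pipeline recovers its own ground truth far above the Voronoi null", {
  ## chain of eight lobed sub-regions, one city each: the pipeline finds
  ## the same eight areas from independent ensembles, while random
  ## tessellations sit several standard deviations below
  h <- 2; radius <- 16; sp <- 27
  centers <- as.matrix(expand.grid(20 + (0:3) * sp, c(20, 60)))
  nx <- round((max(centers[, 1]) + 20) / h); ny <- round(80 / h)
  xs <- (seq_len(nx) - 0.5) * h; ys <- (seq_len(ny) - 0.5) * h
  X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
  mask <- Reduce(`|`, lapply(seq_len(nrow(centers)), function(k)
    (X - centers[k, 1])^2 + (Y - centers[k, 2])^2 <= radius^2))
  cities <- lapply(seq_len(nrow(centers)), function(k)
    citySpec(centers[k, ], 10, 5))
  r <- buildCityDensity(cities, nx, ny, h, mode = "bare_gaussian",
                        landMask = mask)
  p <- modelParams(sigma = 4, beta = 1.1)
  pipe <- function(seed) {
    cfg <- clusteringConfig(nRuns = 12, nC = 8, tEnd = 40, dt = 0.5,
                            seed = seed)
    clusterDialects(runEnsemble(r, p, cfg, dynamics = "nonlocal"), cfg)
  }
  truth <- pipe(21)
  pred <- pipe(77)
  olPipe <- alignAndOverlap(pred, truth)$OL
  nulls <- vapply(1:20, function(k)
    alignAndOverlap(voronoiNull(r, 8, seed = 100 + k), truth)$OL,
    numeric(1))
  expect_gt(olPipe, mean(nulls) + 3 * sd(nulls))
})
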