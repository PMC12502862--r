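# Parameter sampling, dataset assembly, splitting, persistence.

test_that("parameter sampling respects ranges and is seed-deterministic", {
  ps <- sampleParameters(1680, seed = 3)
  expect_equal(nrow(ps), 1680)
  expect_true(all(ps$kappa >= 2 & ps$kappa <= 20))
  expect_true(all(ps$f >= 0 & ps$f <= 0.5))
  expect_true(all(ps$gammaL >= 0 & ps$gammaL <= 2))
  expect_identical(ps, sampleParameters(1680, seed = 3))

  # degenerate interval pins the coordinate
  deg <- sampleParameters(5, list(kappa = c(3, 3), f = c(0, 0.5),
                                  gammaL = c(0, 2)), seed = 1)
  expect_equal(deg$kappa, rep(3, 5))
  expect_error(sampleParameters(5, list(kappa = c(5, 2), f = c(0, 1),
                                        gammaL = c(0, 1))), "interval")

  # uniform-mean sanity: mean kappa near (2+20)/2 = 11
  big <- sampleParameters(1e4, seed = 9)
  se <- sd(big$kappa) / sqrt(1e4)
  expect_lt(abs(mean(big$kappa) - 11), 3 * se)
})

test_that("dataset rows have the contracted shape and are reproducible", {
  grid <- makeQGrid(11, 50 * pi / 10)
  sch <- MCSchedule(50, 100, 50, seed = 1)
  ps <- sampleParameters(2, seed = 4)
  ds <- buildDataset(ps, 10, sch, grid, seed = 4)
  expect_equal(dim(scatteringMatrix(ds)), c(2L, 121L))
  expect_equal(nrow(targetTable(ds)), 2)
  expect_true(all(scatteringMatrix(ds) >= 0 & scatteringMatrix(ds) <= 1))

  # same parameters + same per-row seed => identical rows
  ds2 <- buildDataset(ps[1, , drop = FALSE], 10, sch, grid, seed = 4)
  expect_identical(scatteringMatrix(ds2)[1, ], scatteringMatrix(ds)[1, ])
  expect_identical(targetTable(ds2)$r2_over_L2[1],
                   targetTable(ds)$r2_over_L2[1])
})

test_that("gyration radius grows with stiffness in a quiescent build", {
  ps <- data.frame(kappa = seq(2, 20, length.out = 8), f = 0, gammaL = 0)
  ds <- buildDataset(ps, 30, MCSchedule(500, 1000, 20), makeQGrid(11, pi),
                     seed = 6)
  tg <- targetTable(ds)
  expect_gt(cor(tg$kappa, tg$rg2_norm), 0.9)
})

test_that("splitting is a disjoint partition with the documented sizes", {
  # synthetic dataset: membership logic does not need simulated maps
  g <- makeQGrid(3, 1)
  set.seed(2)
  n <- 1680
  F <- matrix(stats::runif(n * 9), n, 9)
  tg <- data.frame(kappa = stats::runif(n), f = stats::runif(n),
                   gammaL = stats::runif(n), r2_over_L2 = stats::runif(n),
                   rg2_norm = stats::runif(n), rxz_norm = stats::runif(n))
  ds <- ScatteringDataset(F, tg, g)
  parts <- splitDataset(ds, 0.7, seed = 11)
  expect_equal(nMaps(parts$train), 1176)
  expect_equal(nMaps(parts$test), 504)

  # disjoint union: every original row appears exactly once
  key <- function(d) apply(scatteringMatrix(d), 1, paste, collapse = ",")
  expect_length(intersect(key(parts$train), key(parts$test)), 0)
  expect_setequal(c(key(parts$train), key(parts$test)), key(ds))

  # determinism and small-n edge case
  parts2 <- splitDataset(ds, 0.7, seed = 11)
  expect_identical(scatteringMatrix(parts2$train),
                   scatteringMatrix(parts$train))
  small <- ScatteringDataset(F[1:4, ], tg[1:4, ], g)
  halves <- splitDataset(small, 0.5, seed = 1)
  expect_equal(nMaps(halves$train), 2)
  expect_equal(nMaps(halves$test), 2)
  expect_error(splitDataset(ScatteringDataset(F[1, , drop = FALSE],
                                              tg[1, , drop = FALSE], g)),
               "at least 2")
  expect_error(splitDataset(small, 1.2), "strictly between")
})

test_that("dataset persistence round-trips bitwise", {
  ds <- miniDataset()
  dir <- withr::local_tempdir()
  writeScatteringDataset(ds, dir)
  back <- readScatteringDataset(dir)
  expect_identical(scatteringMatrix(back), scatteringMatrix(ds))
  expect_identical(targetTable(back)$rg2_norm, targetTable(ds)$rg2_norm)
  expect_identical(qxValues(qGrid(back)), qxValues(qGrid(ds)))
  expect_identical(back@manifest$gridSignature, ds@manifest$gridSignature)
})

test_that("the stored grid signature matches every constituent map", {
  ds <- miniDataset()
  expect_identical(ds@manifest$gridSignature, gridSignature(qGrid(ds)))
  # rows satisfy the per-map intensity bounds (origin column equals 1)
  originCol <- (which(abs(qxValues(qGrid(ds))) < 1e-12) - 1) *
    length(qzValues(qGrid(ds))) + which(abs(qzValues(qGrid(ds))) < 1e-12)
  expect_equal(scatteringMatrix(ds)[, originCol],
               rep(1, nMaps(ds)), tolerance = 1e-9)
})
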