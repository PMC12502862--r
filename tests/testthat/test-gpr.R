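# Gaussian-process regression: kernel, marginal likelihood, fitting,
# prediction, scoring.

test_that("kernel matrix matches elementwise formula evaluation", {
  spec <- KernelSpec(l = 1, sigma = 0.1)
  # single point against itself: 1 + sigma^2
  expect_equal(kernelMatrix(matrix(2, 1, 1), spec = spec),
               matrix(1.01, 1, 1))
  # distant points decorrelate
  far <- kernelMatrix(matrix(0, 1, 2), matrix(c(100, 100), 1, 2),
                      spec = spec)
  expect_equal(far[1, 1], 0)

  # 3 fixed 2-d points vs hand-computed entries
  X <- rbind(c(0, 0), c(1, 0), c(1, 2))
  K <- kernelMatrix(X, spec = spec)
  oracle <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    d2 <- sum((X[a, ] - X[b, ])^2)
    oracle[a, b] <- exp(-d2 / 2) + (a == b) * 0.01
  }
  expect_equal(K, oracle, tolerance = 1e-12)
  expect_error(kernelMatrix(X, matrix(0, 1, 3), spec = spec), "dimension")
})

test_that("log marginal likelihood matches dense linear-algebra oracle", {
  # scalar closed form: n = 1, y = m, K = 1 + sigma^2
  spec <- KernelSpec(l = 1, sigma = 0.3, constantMean = 2)
  expect_equal(logMarginalLikelihood(matrix(0, 1, 1), 2, spec),
               -0.5 * log(1.09) - 0.5 * log(2 * pi))

  # dense oracle with explicit inverse and determinant
  set.seed(6)
  X <- matrix(stats::rnorm(20), 10, 2)
  y <- stats::rnorm(10)
  for (spec in list(KernelSpec(0.8, 0.2, 0.1), KernelSpec(2, 0.05, 0))) {
    K <- kernelMatrix(X, spec = spec)
    r <- y - spec@constantMean
    dense <- -0.5 * drop(t(r) %*% solve(K) %*% r) -
      0.5 * determinant(K)$modulus[1] - 5 * log(2 * pi)
    expect_equal(logMarginalLikelihood(X, y, spec), dense, tolerance = 1e-8)
  }

  # more noise always shrinks the data-fit quadratic form for fixed y != m
  qform <- function(sigma) {
    spec <- KernelSpec(1, sigma, 0)
    K <- kernelMatrix(X, spec = spec)
    drop(t(y) %*% solve(K) %*% y)
  }
  expect_lt(qform(0.5), qform(0.1))
})

test_that("posterior mean matches a hand-solved 3-point problem", {
  X <- matrix(c(-1, 0, 2), 3, 1)
  y <- c(0.5, 1, -1)
  spec <- KernelSpec(l = 1.3, sigma = 0.2, constantMean = 0)
  mod <- fitGPR(X, y = y, restarts = 0, scaleTargets = FALSE)
  # overwrite with the fixed spec to isolate the prediction formula
  K <- kernelMatrix(X, spec = spec) + diag(1e-10, 3)
  L <- chol(K)
  mod@kernel <- spec
  mod@alpha <- as.numeric(backsolve(L, forwardsolve(t(L), y)))
  mod@yScale <- 1
  xstar <- matrix(c(0.5, 5), 2, 1)
  kstar <- exp(-(outer(xstar[, 1], X[, 1], "-"))^2 / (2 * 1.3^2))
  expect_equal(predict(mod, xstar),
               as.numeric(kstar %*% solve(K, y)), tolerance = 1e-10)
  # far from all training points the prediction reverts to the prior mean
  expect_lt(abs(predict(mod, matrix(100, 1, 1))), 1e-10)
})

test_that("small-noise fits interpolate their training targets", {
  set.seed(10)
  X <- matrix(stats::runif(30, -2, 2), 15, 2)
  y <- sin(X[, 1]) + 0.5 * X[, 2]
  mod <- fitGPR(X, y = y, restarts = 3, seed = 2)
  expect_lt(mod@kernel@sigma, 0.05)  # smooth noiseless data
  expect_equal(predict(mod, X), y, tolerance = 1e-3)
})

test_that("constant targets collapse to the constant prediction", {
  set.seed(12)
  X <- matrix(stats::runif(20), 10, 2)
  mod <- fitGPR(X, y = rep(3.5, 10), restarts = 2, seed = 3)
  expect_equal(predict(mod, matrix(stats::runif(6), 3, 2)), rep(3.5, 3),
               tolerance = 1e-6)
  expect_lt(mod@kernel@sigma, 1e-6)  # noise scale driven to its floor
})

test_that("hyperparameters are recovered from GP-sampled data", {
  toy <- makeFixture("gp_toy_dataset", list(n = 100, l = 1, sigma = 0.1),
                     seed = 42)
  mod <- fitGPR(toy$X, y = toy$y, restarts = 5, seed = 4,
                scaleTargets = FALSE)
  expect_lt(abs(mod@kernel@l - toy$l) / toy$l, 0.3)
  expect_gt(mod@kernel@sigma, toy$sigma / 2)
  expect_lt(mod@kernel@sigma, toy$sigma * 2)
})

test_that("predictions are invariant under training-row permutation", {
  d <- miniDataset()
  set.seed(33)
  perm <- sample(nMaps(d))
  dperm <- ScatteringDataset(scatteringMatrix(d)[perm, ],
                             targetTable(d)[perm, ], qGrid(d))
  m1 <- fitGPR(d, "gammaL", restarts = 2, seed = 5)
  m2 <- fitGPR(dperm, "gammaL", restarts = 2, seed = 5)
  Xnew <- scatteringMatrix(d)[1:4, ]
  expect_equal(predict(m1, Xnew), predict(m2, Xnew), tolerance = 1e-6)
})

test_that("grid mismatch is refused at prediction time", {
  d <- miniDataset()
  mod <- fitGPR(d, "kappa", restarts = 1, seed = 6)
  other <- makeQGrid(11, 1)  # same size, different qMax
  fake <- ScatteringMap(unflattenMap(scatteringMatrix(d)[1, ], qGrid(d)),
                        other, 1)
  expect_error(predict(mod, fake), "grid")
  # the same map on its own grid is accepted
  ok <- ScatteringMap(unflattenMap(scatteringMatrix(d)[1, ], qGrid(d)),
                      qGrid(d), 1)
  expect_length(predict(mod, ok), 1)
})

test_that("the optimum dominates the local likelihood surface", {
  # no point of an (l, sigma) grid around the trained optimum scores a
  # higher log marginal likelihood than the optimizer's result
  rep <- deskReport()
  d <- deskData()
  X <- scatteringMatrix(d$train)
  for (tn in c("kappa", "rxz_norm")) {
    mod <- rep@models[[tn]]
    ys <- (mod@y - mod@kernel@constantMean) / mod@yScale
    lGrid <- mod@kernel@l * 10^seq(-0.5, 0.5, length.out = 5)
    sGrid <- pmax(mod@kernel@sigma, 1e-8) * 10^seq(-0.5, 0.5, length.out = 5)
    vals <- outer(lGrid, sGrid, Vectorize(function(l, s)
      logMarginalLikelihood(X, ys, KernelSpec(l, min(s, 1), 0))))
    expect_lte(max(vals), mod@logMarginalLikelihood + 1e-4)
  }
})

test_that("r2 score follows its definition", {
  expect_equal(r2Score(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r2Score(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r2Score(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r2Score(c(1, 1), c(1, 2)), "variance")
  expect_error(r2Score(1, 1), "two")
})

test_that("model persistence round-trips hyperparameters and predictions", {
  d <- miniDataset()
  mod <- fitGPR(d, "f", restarts = 1, seed = 8)
  dir <- withr::local_tempdir()
  writeGPRModel(mod, dir)
  back <- readGPRModel(dir)
  expect_equal(back@kernel@l, mod@kernel@l)
  expect_equal(back@kernel@sigma, mod@kernel@sigma)
  expect_equal(back@yScale, mod@yScale)
  Xnew <- scatteringMatrix(d)[1:3, ]
  expect_equal(predict(back, Xnew), predict(mod, Xnew), tolerance = 1e-10)
})
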