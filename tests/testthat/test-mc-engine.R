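# Monte Carlo moves, Metropolis acceptance, and sampling correctness.

test_that("rotation primitive: identity angle and collinear axis are no-ops", {
  j <- joints(straightChain(10))
  # zero angle: exact identity
  expect_equal(drivenchain:::cpp_rotate_segment(j, 1, 9, j[1, ], c(0, 1, 0), 0),
               j)
  # rotating a straight chain about its own axis leaves positions unchanged
  expect_equal(drivenchain:::cpp_rotate_segment(j, 1, 9, j[1, ], c(1, 0, 0),
                                                1.3),
               j, tolerance = 1e-12)
})

test_that("move proposals preserve bond lengths and respect fixed joints", {
  bondLengths <- function(cfg) {
    j <- joints(cfg)
    sqrt(rowSums((j[-1, ] - j[-nrow(j), ])^2))
  }
  set.seed(42)
  cfg <- ChainConfiguration(randomValidChain(20, 9))
  for (rep in 1:20) {
    ck <- crankshaftMove(cfg, maxAngle = pi / 2)
    expect_equal(bondLengths(ck), rep(1, 20), tolerance = 1e-9)
    # crankshaft fixes at least the two axis joints and the anchor
    expect_identical(joints(ck)[1, ], joints(cfg)[1, ])
    moved <- which(rowSums(abs(joints(ck) - joints(cfg))) > 1e-12)
    if (length(moved))  # moved block is strictly interior and contiguous
      expect_true(min(moved) > 1 && max(moved) < 21 &&
                  all(diff(moved) == 1))

    pv <- pivotMove(cfg, maxAngle = pi / 2)
    expect_equal(bondLengths(pv), rep(1, 20), tolerance = 1e-9)
    expect_identical(joints(pv)[1, ], joints(cfg)[1, ])
    movedPv <- which(rowSums(abs(joints(pv) - joints(cfg))) > 1e-12)
    if (length(movedPv))  # pivot moves a contiguous tail
      expect_true(max(movedPv) == 21 && all(diff(movedPv) == 1))
  }
})

test_that("overlap detection agrees with the brute-force pair loop", {
  expect_false(hasOverlap(straightChain(30)))
  # fold so joints i and i+2 coincide
  fold <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0))
  expect_true(hasOverlap(fold))
  # exactly-touching non-consecutive spheres do not count
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_false(hasOverlap(square))
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    v <- matrix(stats::rnorm(3 * n), n, 3)
    j <- rbind(0, apply(v / sqrt(rowSums(v^2)), 2, cumsum))
    expect_identical(hasOverlap(j), bruteForceOverlap(j))
  }
})

test_that("Metropolis rule: zero-energy moves of an ideal chain always accept", {
  cfg <- ChainConfiguration(joints(straightChain(10)), selfAvoiding = FALSE)
  p <- EnergyParameters(0, 0, 0)
  set.seed(4)
  for (i in 1:50) {
    step <- metropolisStep(cfg, p, maxAngle = pi / 2)
    expect_true(step$accepted)  # dE = 0 and no overlap check
    cfg <- step$config
  }
})

test_that("simulation is deterministic given the seed", {
  sch <- MCSchedule(100, 200, 20, seed = 77)
  r1 <- runSimulation(EnergyParameters(5, 0.2, 0.01), 15, sch)
  r2 <- runSimulation(EnergyParameters(5, 0.2, 0.01), 15, sch)
  expect_identical(observables(r1), observables(r2))
  expect_identical(energyTrace(r1), energyTrace(r2))
  r3 <- runSimulation(EnergyParameters(5, 0.2, 0.01), 15,
                      MCSchedule(100, 200, 20, seed = 78))
  expect_false(identical(observables(r1), observables(r3)))
})

test_that("every retained sample satisfies the chain invariants", {
  res <- runSimulation(EnergyParameters(4, 0.1, 0.02), 25,
                       MCSchedule(300, 600, 30, seed = 5))
  for (cfg in chainSamples(res)) {
    expect_s4_class(cfg, "ChainConfiguration")  # validity runs on creation
    expect_false(hasOverlap(cfg))
    expect_identical(joints(cfg)[1, ], c(x = 0, y = 0, z = 0))
  }
  expect_true(all(acceptanceRates(res) >= 0 & acceptanceRates(res) <= 1))
})

test_that("ideal-chain tangent correlations vanish without bending", {
  res <- runSimulation(EnergyParameters(0, 0, 0), 30,
                       MCSchedule(500, 2000, 10, seed = 13),
                       selfAvoid = FALSE)
  k <- dim(res@samples)[3]
  # mean t_i . t_j over non-adjacent pairs (|i-j| = 3) across samples
  cors <- vapply(seq_len(k), function(i) {
    t <- diff(res@samples[, , i])
    mean(rowSums(t[seq_len(27), ] * t[4:30, ]))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 3 * blockSE(cors))
})

test_that("tangent correlation decays geometrically for a bending-only chain", {
  kappa <- 5
  rho <- 1 / tanh(kappa) - 1 / kappa  # <cos theta> for weight e^{kappa cos}
  res <- runSimulation(EnergyParameters(kappa, 0, 0), 40,
                       MCSchedule(1000, 4000, 10, seed = 21),
                       selfAvoid = FALSE)
  k <- dim(res@samples)[3]
  for (lag in 1:5) {
    cors <- vapply(seq_len(k), function(i) {
      t <- diff(res@samples[, , i])
      n <- nrow(t)
      mean(rowSums(t[seq_len(n - lag), ] * t[(1 + lag):n, ]))
    }, numeric(1))
    expect_lt(abs(mean(cors) - rho^lag), 3 * blockSE(cors) + 0.005)
  }
})

test_that("mean extension along x grows monotonically with the force", {
  ext <- vapply(c(0.1, 0.3, 0.6), function(f) {
    res <- runSimulation(EnergyParameters(0, f, 0), 30,
                         MCSchedule(500, 2000, 10, seed = 31),
                         selfAvoid = FALSE)
    mean(vapply(seq_len(dim(res@samples)[3]),
                function(i) res@samples[31, 1, i], numeric(1)))
  }, numeric(1))
  expect_true(all(ext > 0))
  expect_true(all(diff(ext) > 0))
})
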