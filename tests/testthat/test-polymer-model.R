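# Chain representation, driven-chain energy, conformation variables.

test_that("energy matches hand-evaluated cases", {
  # straight rod: no bending, stretch term -f*L, no shear (z = 0)
  rod <- straightChain(200)
  expect_equal(totalEnergy(rod, EnergyParameters(kappa = 7)), 0)
  expect_equal(totalEnergy(rod, EnergyParameters(10, 0.5, 0)), -100)

  # 2-bond L-shape: one 90-degree kink, one x-bond starting at z = 1
  ell <- ChainConfiguration(rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1)))
  expect_equal(totalEnergy(ell, EnergyParameters(10, 0.5, 1)), 8.5)
  expect_equal(energyTerms(ell, EnergyParameters(10, 0.5, 1)),
               c(bending = 10, stretch = -0.5, shear = -1))
})

test_that("energy agrees with independent term-by-term summation", {
  # oracle: naive loop over the energy definition, independent of the
  # vectorised implementation and of the C++ path used inside the sampler
  oracle <- function(j, kappa, f, gamma, lb = 1) {
    n <- nrow(j) - 1
    t <- (j[-1, , drop = FALSE] - j[-(n + 1), , drop = FALSE]) / lb
    e <- 0
    for (i in 2:n) e <- e + kappa * (1 - sum(t[i - 1, ] * t[i, ]))
    for (i in 1:n) e <- e - f * lb * t[i, 1] - gamma * lb * j[i, 3] * t[i, 1]
    e
  }
  for (seed in 1:5) {
    j <- randomValidChain(15, seed)
    cfg <- ChainConfiguration(j)
    p <- EnergyParameters(kappa = 3 + seed, f = 0.1 * seed, gamma = 0.05)
    expect_equal(totalEnergy(cfg, p), oracle(j, p@kappa, p@f, p@gamma),
                 tolerance = 1e-12)
    expect_equal(sum(energyTerms(cfg, p)), totalEnergy(cfg, p))
    # C++ evaluation used inside the sampler agrees with the R path
    expect_equal(sum(drivenchain:::cpp_energy_terms(j, p@kappa, p@f,
                                                    p@gamma, 1)),
                 totalEnergy(cfg, p), tolerance = 1e-12)
  }
})

test_that("bending term is nonnegative and zero only for parallel tangents", {
  p <- EnergyParameters(kappa = 8)
  expect_equal(energyTerms(straightChain(30), p)[["bending"]], 0)
  for (seed in 1:5) {
    cfg <- ChainConfiguration(randomValidChain(20, seed))
    expect_gt(energyTerms(cfg, p)[["bending"]], 0)
  }
})

test_that("bending + stretch energy is invariant under rotations about x", {
  rotx <- function(j, a) {
    R <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
    j %*% t(R)
  }
  p <- EnergyParameters(kappa = 6, f = 0.4, gamma = 0)
  for (seed in 1:4) {
    j <- randomValidChain(18, seed)
    e0 <- totalEnergy(ChainConfiguration(j), p)
    e1 <- totalEnergy(ChainConfiguration(rotx(j, 0.8 + 0.3 * seed)), p)
    expect_equal(e1, e0, tolerance = 1e-9)
  }
})

test_that("conformation variables match closed forms and the pair average", {
  n <- 12
  rod <- straightChain(n)
  cv <- conformationVariables(rod)
  expect_equal(cv@r2, n^2)
  expect_equal(cv@rg2, n * (n + 2) / 12)  # variance of equally spaced points
  expect_equal(cv@rxz, 0)

  # any configuration confined to the (x, y) plane has rxz = 0
  zig <- makeFixture("planar_zigzag", list(n = 11))
  expect_equal(conformationVariables(zig)@rxz, 0)

  # centroid form equals the half pair-average over all ordered pairs
  for (seed in 1:4) {
    j <- randomValidChain(14, seed)
    cv <- conformationVariables(ChainConfiguration(j))
    m <- nrow(j)
    pr2 <- prxz <- 0
    for (a in seq_len(m)) for (b in seq_len(m)) {
      pr2 <- pr2 + sum((j[a, ] - j[b, ])^2)
      prxz <- prxz + (j[a, 1] - j[b, 1]) * (j[a, 3] - j[b, 3])
    }
    expect_equal(cv@rg2, pr2 / (2 * m^2), tolerance = 1e-12)
    expect_equal(cv@rxz, prxz / (2 * m^2), tolerance = 1e-12)
    expect_lte(abs(cv@rxz), cv@rg2)
  }
})

test_that("tangent vectors are unit length and correctly oriented", {
  expect_equal(tangentVectors(straightChain(5)),
               matrix(rep(c(1, 0, 0), each = 5), 5, 3))
  ell <- ChainConfiguration(rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1)))
  expect_equal(tangentVectors(ell), rbind(c(0, 0, 1), c(1, 0, 0)))
  for (seed in 1:4) {
    t <- tangentVectors(ChainConfiguration(randomValidChain(25, seed)))
    expect_equal(sqrt(rowSums(t^2)), rep(1, 25), tolerance = 1e-9)
  }
})

test_that("configuration invariants are enforced", {
  # end not at origin
  expect_error(ChainConfiguration(rbind(c(1, 0, 0), c(2, 0, 0))), "origin")
  # broken bond length
  expect_error(ChainConfiguration(rbind(c(0, 0, 0), c(0, 0, 1.5))), "length")
  # non-finite coordinates
  expect_error(ChainConfiguration(rbind(c(0, 0, 0), c(NA, 0, 1))), "finite")
  # hard-sphere overlap (joints 0 and 2 coincident), unless flagged off
  fold <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0))
  expect_error(ChainConfiguration(fold), "overlap")
  expect_s4_class(ChainConfiguration(fold, selfAvoiding = FALSE),
                  "ChainConfiguration")
})

test_that("chain CSV round trip preserves coordinates exactly", {
  cfg <- ChainConfiguration(randomValidChain(20, 3))
  f <- withr::local_tempfile(fileext = ".csv")
  writeChainCSV(cfg, f)
  expect_identical(joints(readChainCSV(f)), joints(cfg))
})
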