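# Shared fixtures. Expensive objects are built once per test run and cached.

.cache <- new.env(parent = emptyenv())

# The scaled-down study: 400 parameter combinations, N = 50 chains,
# 21 x 21 Q grid with qMax = 50*pi/L, 2000 configurations averaged per map,
# 70/30 split. Built once (several minutes) and reused across test files.
deskData <- function() {
  if (is.null(.cache$desk)) {
    grid <- makeQGrid(21, 50 * pi / 50)
    ps <- sampleParameters(400, seed = 7)
    ds <- buildDataset(ps, 50, MCSchedule(4000, 24000, 12), grid, seed = 7)
    parts <- splitDataset(ds, 0.7, seed = 8)
    .cache$desk <- list(ds = ds, train = parts$train, test = parts$test)
  }
  .cache$desk
}

# Per-target regressors on the desk split, fitted once.
deskReport <- function() {
  if (is.null(.cache$deskReport)) {
    d <- deskData()
    .cache$deskReport <- invertDataset(d$train, d$test, restarts = 5,
                                       seed = 9)
  }
  .cache$deskReport
}

# A small dataset for structural/monotonicity checks (seconds, not minutes).
miniDataset <- function() {
  if (is.null(.cache$mini)) {
    grid <- makeQGrid(11, 50 * pi / 30)
    ps <- sampleParameters(24, seed = 5)
    .cache$mini <- buildDataset(ps, 30, MCSchedule(500, 1000, 20), grid,
                                seed = 5)
  }
  .cache$mini
}

# Random self-avoiding configuration grown bond by bond (rejection sampling);
# independent of the MC engine's move set.
randomValidChain <- function(n, seed) {
  set.seed(seed)
  j <- matrix(0, n + 1, 3)
  i <- 2
  while (i <= n + 1) {
    v <- stats::rnorm(3)
    cand <- j[i - 1, ] + v / sqrt(sum(v^2))
    d2 <- rowSums((j[seq_len(max(1, i - 2)), , drop = FALSE] -
                   matrix(cand, max(1, i - 2), 3, byrow = TRUE))^2)
    if (i <= 2 || all(d2 >= 1)) {
      j[i, ] <- cand
      i <- i + 1
    }
  }
  j
}

# Brute-force O(M^2) pair-sum intensity: the oracle the amplitude-based
# computation is checked against.
bruteForceIntensity <- function(points, grid) {
  qx <- qxValues(grid); qz <- qzValues(grid)
  M <- nrow(points)
  out <- matrix(0, length(qx), length(qz))
  for (a in seq_along(qx)) for (b in seq_along(qz)) {
    s <- 0
    for (j in seq_len(M)) for (k in seq_len(M)) {
      phase <- qx[a] * (points[j, 1] - points[k, 1]) +
               qz[b] * (points[j, 3] - points[k, 3])
      s <- s + cos(phase)
    }
    out[a, b] <- s / M^2
  }
  out
}

# Brute-force overlap oracle: all-pairs loop in R.
bruteForceOverlap <- function(j, lb = 1) {
  m <- nrow(j)
  for (a in seq_len(m - 2)) for (b in (a + 2):m) {
    if (sqrt(sum((j[a, ] - j[b, ])^2)) < lb * (1 - 1e-12)) return(TRUE)
  }
  FALSE
}
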