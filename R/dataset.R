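# Dataset assembly: sample parameter combinations, run the forward model,
# collect flattened maps and inversion targets, split, persist.

#' Default parameter ranges
#'
#' Uniform sampling ranges for the energy parameters: kappa in `[2, 20]`,
#' f in `[0, 0.5]`, gamma*L in `[0, 2]`.
#' @export
defaultParameterRanges <- function() {
  list(kappa = c(2, 20), f = c(0, 0.5), gammaL = c(0, 2))
}

#' Sample energy-parameter combinations
#'
#' Independent uniform draws of (kappa, f, gamma*L) within the given ranges;
#' deterministic given `seed`.
#'
#' @param n number of combinations
#' @param ranges named list of length-2 intervals for kappa, f, gammaL
#' @param seed integer seed
#' @return data.frame with columns kappa, f, gammaL
#' @examples
#' head(sampleParameters(5, seed = 7))
#' @export
sampleParameters <- function(n, ranges = defaultParameterRanges(), seed = 1) {
  stopifnot(n >= 1)
  for (nm in c("kappa", "f", "gammaL")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || !all(is.finite(r)) || r[2] < r[1])
      stop(sprintf("range for %s must be a finite interval", nm))
  }
  set.seed(seed)
  data.frame(
    kappa = stats::runif(n, ranges$kappa[1], ranges$kappa[2]),
    f = stats::runif(n, ranges$f[1], ranges$f[2]),
    gammaL = stats::runif(n, ranges$gammaL[1], ranges$gammaL[2]))
}

# Deterministic per-row seed from (master seed, row index), kept below 2^31.
.rowSeed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + i * 30269) %% 2147483647)
}

#' Build a scattering dataset
#'
#' Runs one Monte Carlo simulation per parameter row (gamma = gammaL / L with
#' L = nBonds * bondLength), computes the ensemble-averaged scattering map on
#' `grid`, and assembles the flattened maps into the matrix `F` along with
#' the six inversion targets: kappa, f, gammaL and the ensemble means of
#' R^2/L^2, Rg^2/L^normExponent and R_xz/L^normExponent.
#'
#' Rows are mutually independent: each uses a seed derived deterministically
#' from `(seed, row index)`, so any row is reproducible in isolation. A row
#' whose simulation fails is excluded with a message and recorded in the
#' manifest, never silently dropped.
#'
#' @param samples data.frame from [sampleParameters()]
#' @param nBonds chain length N
#' @param schedule an [MCSchedule-class] (its seed slot is overridden per row)
#' @param grid a [QGrid-class]
#' @param bondLength bond length l_b
#' @param seed master seed for per-row seed derivation
#' @param normExponent L exponent normalising rg2 and rxz (default 2,
#'   dimensionless; 1 matches a by-contour-length convention)
#' @param noiseSD optional multiplicative intensity noise (default 0, off)
#' @param selfAvoid enforce hard-sphere self-avoidance
#' @param verbose print per-row progress
#' @return a [ScatteringDataset-class]
#' @export
buildDataset <- function(samples, nBonds, schedule, grid, bondLength = 1,
                         seed = 1, normExponent = 2, noiseSD = 0,
                         selfAvoid = TRUE, verbose = FALSE) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1,
            is(schedule, "MCSchedule"), is(grid, "QGrid"))
  L <- nBonds * bondLength
  n <- nrow(samples)
  np <- nGridPoints(grid)
  F <- matrix(NA_real_, n, np)
  tg <- data.frame(kappa = samples$kappa, f = samples$f,
                   gammaL = samples$gammaL,
                   r2_over_L2 = NA_real_, rg2_norm = NA_real_,
                   rxz_norm = NA_real_)
  failed <- integer(0)
  for (i in seq_len(n)) {
    rowSchedule <- schedule
    rowSchedule@seed <- .rowSeed(seed, i)
    res <- tryCatch({
      params <- EnergyParameters(kappa = samples$kappa[i], f = samples$f[i],
                                 gamma = samples$gammaL[i] / L)
      sim <- runSimulation(params, nBonds, rowSchedule,
                           bondLength = bondLength, selfAvoid = selfAvoid)
      map <- ensembleIntensity(sim, grid)
      obs <- colMeans(observables(sim))
      list(map = map, obs = obs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, i)
      message(sprintf("row %d failed and is excluded: %s", i,
                      conditionMessage(res)))
      next
    }
    v <- flattenMap(res$map)
    if (noiseSD > 0) {
      set.seed(.rowSeed(seed + 1L, i))
      v <- pmin(1, pmax(0, v * (1 + stats::rnorm(np, 0, noiseSD))))
    }
    F[i, ] <- v
    tg$r2_over_L2[i] <- res$obs["r2"] / L^2
    tg$rg2_norm[i] <- res$obs["rg2"] / L^normExponent
    tg$rxz_norm[i] <- res$obs["rxz"] / L^normExponent
    if (verbose) message(sprintf("row %d/%d done", i, n))
  }
  keep <- setdiff(seq_len(n), failed)
  manifest <- list(
    nBonds = nBonds, bondLength = bondLength, seed = seed,
    normExponent = normExponent, noiseSD = noiseSD, selfAvoid = selfAvoid,
    schedule = list(nEquilibrationSweeps = schedule@nEquilibrationSweeps,
                    nSampleSweeps = schedule@nSampleSweeps,
                    sampleInterval = schedule@sampleInterval,
                    maxRotationAngle = schedule@maxRotationAngle,
                    autoTune = schedule@autoTune),
    gridSignature = gridSignature(grid),
    excludedRows = failed,
    created = format(Sys.time(), tz = "UTC"))
  new("ScatteringDataset", F = F[keep, , drop = FALSE],
      targets = tg[keep, , drop = FALSE], grid = grid, manifest = manifest)
}

#' Construct a scattering dataset from components
#'
#' @param F matrix of flattened maps; @param targets target table;
#' @param grid a [QGrid-class]; @param manifest provenance list
#' @export
ScatteringDataset <- function(F, targets, grid, manifest = list()) {
  if (is.null(manifest$gridSignature))
    manifest$gridSignature <- gridSignature(grid)
  rownames(targets) <- NULL
  new("ScatteringDataset", F = as.matrix(F), targets = targets, grid = grid,
      manifest = manifest)
}

#' @rdname ScatteringDataset-class
#' @param x,object a [ScatteringDataset-class]
#' @export
setMethod("scatteringMatrix", "ScatteringDataset", function(x) x@F)

#' @rdname ScatteringDataset-class
#' @export
setMethod("targetTable", "ScatteringDataset", function(x) x@targets)

#' @rdname ScatteringDataset-class
#' @export
setMethod("qGrid", "ScatteringDataset", function(x) x@grid)

setMethod("show", "ScatteringDataset", function(object) {
  cat(sprintf("ScatteringDataset: %d maps x %d grid points (%d x %d grid)\n",
              nrow(object@F), ncol(object@F), length(object@grid@qx),
              length(object@grid@qz)))
})

#' Number of rows in a dataset
#' @param ds a [ScatteringDataset-class]
#' @export
nMaps <- function(ds) nrow(ds@F)

#' Split a dataset into train and test sets
#'
#' Disjoint uniformly random row partition; the train set gets
#' `round(trainFraction * n)` rows and the test set the remainder. Both
#' parts carry the same grid and manifest. Deterministic given `seed`.
#'
#' @param ds a [ScatteringDataset-class] with at least 2 rows
#' @param trainFraction in (0, 1); default 0.7 (70/30 protocol)
#' @param seed integer seed
#' @return list with elements `train` and `test`
#' @export
splitDataset <- function(ds, trainFraction = 0.7, seed = 1) {
  n <- nMaps(ds)
  if (n < 2) stop("need at least 2 rows to split")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  set.seed(seed)
  nTrain <- round(trainFraction * n)
  nTrain <- min(max(nTrain, 1L), n - 1L)
  idx <- sample.int(n, nTrain)
  sub <- function(rows) {
    m <- ds@manifest
    m$splitSeed <- seed
    ScatteringDataset(ds@F[rows, , drop = FALSE],
                      ds@targets[rows, , drop = FALSE], ds@grid, m)
  }
  list(train = sub(sort(idx)), test = sub(setdiff(seq_len(n), idx)))
}

#' Persist / load a scattering dataset
#'
#' Writes a directory container of plain-text files: `F.csv` (flattened
#' maps), `targets.csv`, and `manifest.json` (provenance plus the grid axes
#' at full precision). The round trip is bitwise exact.
#'
#' @param ds a [ScatteringDataset-class]
#' @param dir directory path (created if needed)
#' @return `readScatteringDataset`: a [ScatteringDataset-class]
#' @export
writeScatteringDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeExactCSV(data.table::as.data.table(ds@F), file.path(dir, "F.csv"))
  .writeExactCSV(ds@targets, file.path(dir, "targets.csv"))
  meta <- ds@manifest
  # axes as %.17g strings: JSON numeric serialisation rounds doubles
  meta$qx <- sprintf("%.17g", ds@grid@qx)
  meta$qz <- sprintf("%.17g", ds@grid@qz)
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeScatteringDataset
#' @export
readScatteringDataset <- function(dir) {
  F <- as.matrix(.readNumericCSV(file.path(dir, "F.csv")))
  dimnames(F) <- NULL
  targets <- as.data.frame(.readNumericCSV(file.path(dir, "targets.csv")))
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  grid <- QGrid(as.numeric(meta$qx), as.numeric(meta$qz))
  meta$qx <- NULL
  meta$qz <- NULL
  ScatteringDataset(F, targets, grid, meta)
}
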