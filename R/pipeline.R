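# End-to-end pipeline: configuration profiles, stage orchestration,
# provenance manifests, and deterministic fixtures for tests.

#' Pipeline configuration profiles
#'
#' Returns the fully resolved configuration list for one of the built-in
#' profiles:
#' \describe{
#'   \item{smoke}{20 maps, N = 20, 11 x 11 grid, tiny schedule — an
#'     end-to-end contract check that completes in well under a minute.}
#'   \item{desk}{400 maps, N = 50, 21 x 21 grid, 2000 configurations
#'     averaged per map — the scaled-down study used throughout the tests
#'     and the vignette.}
#'   \item{paper}{1680 maps, N = 200, 51 x 51 grid, full schedule — the
#'     full-scale protocol (hours of CPU; trivially parallel by row).}
#' }
#' Every profile uses qMax = 50*pi/L and the uniform sampling ranges of
#' [defaultParameterRanges()].
#'
#' @param profile one of `"smoke"`, `"desk"`, `"paper"`
#' @param seed master seed recorded in the configuration
#' @return named configuration list
#' @export
pipelineProfile <- function(profile = c("desk", "smoke", "paper"), seed = 1) {
  profile <- match.arg(profile)
  base <- switch(profile,
    smoke = list(nSamples = 20, nBonds = 20, gridN = 11,
                 schedule = list(nEquilibrationSweeps = 200,
                                 nSampleSweeps = 200, sampleInterval = 20)),
    desk = list(nSamples = 400, nBonds = 50, gridN = 21,
                schedule = list(nEquilibrationSweeps = 4000,
                                nSampleSweeps = 24000, sampleInterval = 12)),
    paper = list(nSamples = 1680, nBonds = 200, gridN = 51,
                 schedule = list(nEquilibrationSweeps = 20000,
                                 nSampleSweeps = 10000,
                                 sampleInterval = 100)))
  c(base, list(profile = profile, bondLength = 1, qMaxFactor = 50,
               trainFraction = 0.7, restarts = 5, seed = seed,
               ranges = defaultParameterRanges(),
               targets = inversionTargets()))
}

#' Read / write a pipeline configuration
#'
#' Configurations are plain YAML; parse -> serialize -> parse is idempotent.
#'
#' @param config configuration list; @param file path
#' @return `readPipelineConfig`: configuration list
#' @export
writePipelineConfig <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(file) yaml::read_yaml(file)

.configSchedule <- function(config, seed) {
  s <- config$schedule
  MCSchedule(s$nEquilibrationSweeps, s$nSampleSweeps, s$sampleInterval,
             maxRotationAngle = if (is.null(s$maxRotationAngle)) pi / 2
                                else s$maxRotationAngle,
             seed = seed,
             autoTune = isTRUE(s$autoTune))
}

#' Run the full inversion pipeline
#'
#' Executes build-dataset -> split -> SVD -> train -> evaluate from a single
#' configuration (a profile name, a YAML file path, or a configuration
#' list). When `outDir` is given, each stage's artifact is persisted there
#' (dataset/, train/, test/, svd_spectrum.csv, models/,
#' inversion_report.csv, manifest.json) so the run is resumable and fully
#' documented; identical configurations and seeds reproduce identical
#' artifacts.
#'
#' @param config profile name, YAML path, or configuration list (see
#'   [pipelineProfile()])
#' @param outDir optional output directory
#' @param verbose print stage progress
#' @return list with elements `dataset`, `train`, `test`, `svd`,
#'   `spectrum`, `report`, `config`
#' @examples
#' \donttest{
#' art <- runPipeline(pipelineProfile("smoke", seed = 7))
#' inversionSummary(art$report)
#' }
#' @export
runPipeline <- function(config = "desk", outDir = NULL, verbose = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config)) readPipelineConfig(config)
              else pipelineProfile(config)
  }
  .validatePipelineConfig(config)
  say <- function(...) if (verbose) message(sprintf(...))

  L <- config$nBonds * config$bondLength
  grid <- makeQGrid(config$gridN, config$qMaxFactor * pi / L)
  say("stage 1/5: building %d-map dataset (N = %d, %d x %d grid)",
      config$nSamples, config$nBonds, config$gridN, config$gridN)
  params <- sampleParameters(config$nSamples, config$ranges,
                             seed = config$seed)
  schedule <- .configSchedule(config, config$seed)
  ds <- buildDataset(params, config$nBonds, schedule, grid,
                     bondLength = config$bondLength, seed = config$seed,
                     verbose = verbose)

  say("stage 2/5: 70/30 split")
  parts <- splitDataset(ds, config$trainFraction, seed = config$seed + 1L)

  say("stage 3/5: singular value decomposition")
  sv <- decomposeScattering(parts$train)
  spectrum <- spectrumReport(sv, topK = min(20L, length(singularValues(sv))))

  say("stage 4/5: training %d regressors", length(config$targets))
  report <- invertDataset(parts$train, parts$test, targets = config$targets,
                          restarts = config$restarts,
                          seed = config$seed + 2L, verbose = verbose)

  say("stage 5/5: writing artifacts")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeScatteringDataset(ds, file.path(outDir, "dataset"))
    writeScatteringDataset(parts$train, file.path(outDir, "train"))
    writeScatteringDataset(parts$test, file.path(outDir, "test"))
    data.table::fwrite(spectrum, file.path(outDir, "svd_spectrum.csv"))
    data.table::fwrite(inversionSummary(report),
                       file.path(outDir, "inversion_report.csv"))
    for (tn in names(report@models))
      writeGPRModel(report@models[[tn]], file.path(outDir, "models", tn))
    manifest <- list(
      package = "drivenchain",
      version = as.character(utils::packageVersion("drivenchain")),
      config = config,
      created = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(dataset = ds, train = parts$train, test = parts$test, svd = sv,
       spectrum = spectrum, report = report, config = config)
}

# Schema validation: all violations reported at once.
.validatePipelineConfig <- function(config) {
  problems <- character(0)
  need <- c("nSamples", "nBonds", "gridN", "schedule", "bondLength",
            "qMaxFactor", "trainFraction", "restarts", "seed", "ranges",
            "targets")
  missing <- setdiff(need, names(config))
  if (length(missing))
    problems <- c(problems, paste("missing fields:",
                                  paste(missing, collapse = ", ")))
  if (!is.null(config$gridN) && config$gridN %% 2 != 1)
    problems <- c(problems, "gridN must be odd")
  if (!is.null(config$trainFraction) &&
      (config$trainFraction <= 0 || config$trainFraction >= 1))
    problems <- c(problems, "trainFraction must lie in (0, 1)")
  if (!is.null(config$nSamples) && config$nSamples < 2)
    problems <- c(problems, "nSamples must be >= 2")
  if (length(problems))
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

#' Deterministic fixtures
#'
#' Small invariant-satisfying objects for tests and examples:
#' \describe{
#'   \item{straight_rod}{straight chain along x; `params$n` bonds.}
#'   \item{planar_zigzag}{chain zig-zagging in the (x, y) plane with 90
#'     degree turns; `params$n` bonds. All joints have z = 0, so its
#'     gyration-tensor xz component vanishes.}
#'   \item{ideal_random_walk}{freely jointed chain with uniformly random
#'     bond directions; self-avoidance deliberately bypassed and flagged
#'     (`selfAvoiding = FALSE`).}
#'   \item{gp_toy_dataset}{list with inputs `X` (`params$n` rows,
#'     `params$d` columns, default 2) and targets `y` drawn from a GP with
#'     RBF kernel (`params$l`, default 1) plus observation noise
#'     (`params$sigma`, default 0.1) — for hyperparameter-recovery tests.}
#' }
#'
#' @param kind fixture kind (see above)
#' @param params named list of kind-specific parameters
#' @param seed integer seed (random kinds)
#' @return a [ChainConfiguration-class], or a list for `gp_toy_dataset`
#' @export
makeFixture <- function(kind, params = list(), seed = 1) {
  kinds <- c("straight_rod", "planar_zigzag", "ideal_random_walk",
             "gp_toy_dataset")
  if (!kind %in% kinds)
    stop("unknown fixture kind '", kind, "'; available: ",
         paste(kinds, collapse = ", "))
  n <- if (is.null(params$n)) 50L else as.integer(params$n)
  switch(kind,
    straight_rod = straightChain(n),
    planar_zigzag = {
      # unit steps alternating +x, +y, +x, -y, ... (all 90-degree turns)
      dirs <- cbind(rep(c(1, 0), length.out = n),
                    rep(c(0, 1, 0, -1), length.out = n) *
                      (seq_len(n) %% 2 == 0), 0)
      ChainConfiguration(rbind(0, apply(dirs, 2, cumsum)))
    },
    ideal_random_walk = {
      set.seed(seed)
      v <- matrix(stats::rnorm(3 * n), n, 3)
      v <- v / sqrt(rowSums(v^2))
      ChainConfiguration(rbind(0, apply(v, 2, cumsum)),
                         selfAvoiding = FALSE)
    },
    gp_toy_dataset = {
      set.seed(seed)
      d <- if (is.null(params$d)) 2L else as.integer(params$d)
      l <- if (is.null(params$l)) 1 else params$l
      sigma <- if (is.null(params$sigma)) 0.1 else params$sigma
      X <- matrix(stats::runif(n * d, -2, 2), n, d)
      K <- exp(-.cross2(X, X) / (2 * l^2)) + diag(1e-10, n)
      f <- drop(t(chol(K)) %*% stats::rnorm(n))
      list(X = X, y = f + stats::rnorm(n, 0, sigma), l = l, sigma = sigma)
    })
}
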