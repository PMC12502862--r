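# Metropolis Monte Carlo sampling with crankshaft and pivot moves.

#' Construct a Monte Carlo schedule
#'
#' Defaults (20000 equilibration sweeps, 10000 sampling sweeps at interval
#' 100, amplitude pi/2) are sized for full-scale N = 200 runs; scaled-down
#' schedules are used for desk-scale datasets (see the package vignette).
#'
#' @param nEquilibrationSweeps,nSampleSweeps,sampleInterval sweep counts
#'   (one sweep = N attempted moves)
#' @param maxRotationAngle move amplitude, radians, in (0, pi]
#' @param seed integer RNG seed
#' @param autoTune adjust the amplitude toward ~50% acceptance during the
#'   first half of equilibration, then freeze (default off)
#' @return an [MCSchedule-class]
#' @export
MCSchedule <- function(nEquilibrationSweeps = 20000, nSampleSweeps = 10000,
                       sampleInterval = 100, maxRotationAngle = pi / 2,
                       seed = 1, autoTune = FALSE) {
  new("MCSchedule",
      nEquilibrationSweeps = as.integer(nEquilibrationSweeps),
      nSampleSweeps = as.integer(nSampleSweeps),
      sampleInterval = as.integer(sampleInterval),
      maxRotationAngle = maxRotationAngle, seed = as.integer(seed),
      autoTune = autoTune)
}

setMethod("show", "MCSchedule", function(object) {
  cat(sprintf(
    "MCSchedule: %d equil + %d sampling sweeps (interval %d), amplitude %.3g rad, seed %d%s\n",
    object@nEquilibrationSweeps, object@nSampleSweeps, object@sampleInterval,
    object@maxRotationAngle, object@seed,
    if (object@autoTune) ", auto-tuned" else ""))
})

# Proposal configurations may violate the hard-sphere invariant (overlapping
# proposals are what the Metropolis step rejects), so they are built by slot
# update, which skips the class validity check.
.newChainLike <- function(config, joints) {
  config@joints <- joints
  config
}

#' Crankshaft move proposal
#'
#' Picks joint indices a < b (0-based, b >= a + 2) and rotates the joints
#' strictly between them by a uniform angle in `[-maxAngle, maxAngle]` about
#' the axis through joints a and b. Both endpoints stay fixed; all bond
#' lengths are preserved (rigid rotation). Uses R's RNG.
#'
#' @param config a [ChainConfiguration-class] with N >= 3
#' @param maxAngle maximum rotation angle (radians)
#' @return the proposal [ChainConfiguration-class]
#' @export
crankshaftMove <- function(config, maxAngle = pi / 2) {
  n <- nBonds(config)
  if (n < 3) stop("crankshaft needs at least 3 bonds")
  a <- sample.int(n - 1L, 1L) - 1L          # 0 .. N-2
  b <- a + 1L + sample.int(n - a - 1L, 1L)  # a+2 .. N
  angle <- stats::runif(1, -maxAngle, maxAngle)
  j <- config@joints
  axis <- j[b + 1L, ] - j[a + 1L, ]
  prop <- cpp_rotate_segment(j, a + 1L, b - 1L, j[a + 1L, ], axis, angle)
  dimnames(prop) <- dimnames(j)
  .newChainLike(config, prop)
}

#' Pivot move proposal
#'
#' Picks a pivot joint p uniformly among joints 0..N-1 and rotates the tail
#' sub-chain p+1..N about a uniformly random axis through joint p by a
#' uniform angle in `[-maxAngle, maxAngle]`. The anchored joint 0 never
#' moves. Uses R's RNG.
#'
#' @inheritParams crankshaftMove
#' @return the proposal [ChainConfiguration-class]
#' @export
pivotMove <- function(config, maxAngle = pi / 2) {
  n <- nBonds(config)
  p <- sample.int(n, 1L) - 1L  # 0 .. N-1
  axis <- stats::rnorm(3)
  angle <- stats::runif(1, -maxAngle, maxAngle)
  j <- config@joints
  prop <- cpp_rotate_segment(j, p + 1L, n, j[p + 1L, ], axis, angle)
  dimnames(prop) <- dimnames(j)
  .newChainLike(config, prop)
}

#' One Metropolis step
#'
#' Proposes a crankshaft or pivot move (equal probability; pivot only when
#' N < 3), rejects outright on hard-sphere overlap when the configuration is
#' self-avoiding, and otherwise accepts with probability min(1, exp(-dE)).
#' On rejection the input configuration is returned.
#'
#' @param config a [ChainConfiguration-class]
#' @param params an [EnergyParameters-class]
#' @param maxAngle move amplitude (radians)
#' @return list with elements `config` and `accepted`
#' @export
metropolisStep <- function(config, params, maxAngle = pi / 2) {
  crank <- nBonds(config) >= 3 && stats::runif(1) < 0.5
  prop <- if (crank) crankshaftMove(config, maxAngle)
          else pivotMove(config, maxAngle)
  if (config@selfAvoiding && cpp_has_overlap(prop@joints, prop@bondLength))
    return(list(config = config, accepted = FALSE))
  de <- totalEnergy(prop, params) - totalEnergy(config, params)
  if (de <= 0 || stats::runif(1) < exp(-de))
    list(config = prop, accepted = TRUE)
  else
    list(config = config, accepted = FALSE)
}

#' Run a Monte Carlo simulation
#'
#' Samples chain configurations under the driven-chain energy, starting from
#' a straight rod along x (always overlap-free). After the equilibration
#' phase, one configuration is retained every `sampleInterval` sweeps;
#' conformation variables are computed per retained sample. Fully
#' deterministic given `schedule@seed`.
#'
#' @param params an [EnergyParameters-class]
#' @param nBonds number of bonds N
#' @param schedule an [MCSchedule-class]
#' @param bondLength bond length l_b
#' @param selfAvoid enforce hard-sphere self-avoidance (default `TRUE`;
#'   ideal-chain reference runs switch it off)
#' @return an [MCResult-class]
#' @examples
#' res <- runSimulation(EnergyParameters(kappa = 5), nBonds = 20,
#'                      MCSchedule(200, 200, 20, seed = 42))
#' colMeans(observables(res))
#' @export
runSimulation <- function(params, nBonds, schedule = MCSchedule(),
                          bondLength = 1, selfAvoid = TRUE) {
  stopifnot(is(params, "EnergyParameters"), is(schedule, "MCSchedule"))
  validObject(schedule)
  init <- straightChain(nBonds, bondLength)
  set.seed(schedule@seed)
  raw <- cpp_run_mc(init@joints, params@kappa, params@f, params@gamma,
                    bondLength,
                    schedule@nEquilibrationSweeps, schedule@nSampleSweeps,
                    schedule@sampleInterval, schedule@maxRotationAngle,
                    selfAvoid, schedule@autoTune)
  if (is.finite(raw$acceptance_equil) && raw$acceptance_equil < 0.01)
    warning(sprintf("equilibration acceptance rate %.2f%% is below 1%%",
                    100 * raw$acceptance_equil))
  samples <- raw$samples
  k <- dim(samples)[3]
  obs <- t(vapply(seq_len(k), function(i) .confVars(samples[, , i]),
                  numeric(3)))
  new("MCResult", samples = samples,
      observables = as.data.frame(obs),
      acceptanceRates = raw$acceptance,
      energyTrace = as.numeric(raw$energy_trace),
      params = params, schedule = schedule, bondLength = bondLength,
      selfAvoiding = selfAvoid, finalMaxAngle = raw$max_angle_final)
}

#' @rdname MCResult-class
#' @param x,object an [MCResult-class]
#' @export
setMethod("observables", "MCResult", function(x) x@observables)

#' @rdname MCResult-class
#' @export
setMethod("acceptanceRates", "MCResult", function(x) x@acceptanceRates)

#' @rdname MCResult-class
#' @export
setMethod("energyTrace", "MCResult", function(x) x@energyTrace)

#' @rdname MCResult-class
#' @export
setMethod("chainSamples", "MCResult", function(x) {
  k <- dim(x@samples)[3]
  lapply(seq_len(k), function(i)
    ChainConfiguration(x@samples[, , i], x@bondLength,
                       selfAvoiding = x@selfAvoiding))
})

setMethod("show", "MCResult", function(object) {
  k <- dim(object@samples)[3]
  cat(sprintf("MCResult: %d retained samples of an N = %d chain\n",
              k, dim(object@samples)[1] - 1L))
  cat(sprintf("  kappa = %g, f = %g, gamma = %g; acceptance: crankshaft %.1f%%, pivot %.1f%%\n",
              object@params@kappa, object@params@f, object@params@gamma,
              100 * object@acceptanceRates["crankshaft"],
              100 * object@acceptanceRates["pivot"]))
})

#' Blocked standard error of a Monte Carlo series
#'
#' Standard error of the mean of a (possibly autocorrelated) sample series,
#' estimated from block means.
#'
#' @param x numeric series of per-sample values
#' @param nBlocks number of blocks (default 20)
#' @return standard error estimate
#' @export
blockSE <- function(x, nBlocks = 20) {
  n <- length(x)
  nBlocks <- max(2L, min(nBlocks, n %/% 2L))
  size <- n %/% nBlocks
  bm <- vapply(seq_len(nBlocks),
               function(b) mean(x[((b - 1) * size + 1):(b * size)]),
               numeric(1))
  stats::sd(bm) / sqrt(nBlocks)
}
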