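#' @useDynLib drivenchain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.BOND_RTOL <- 1e-9

#' Energy parameters of the driven chain
#'
#' Holds the three energy couplings of the driven worm-like chain in thermal
#' units (k_B T = 1 throughout): the bending modulus `kappa` (k_B T), the
#' stretching force `f` along x (k_B T / l_b) and the shear-rate coupling
#' `gamma` along z. `gamma` is the bare per-simulation coupling; for sampling
#' and inversion the contour-length-normalised `gamma * L` is used.
#'
#' @slot kappa bending modulus, >= 0
#' @slot f stretching force along x, >= 0
#' @slot gamma shear coupling along z, >= 0
#' @export
setClass("EnergyParameters",
  representation(kappa = "numeric", f = "numeric", gamma = "numeric"),
  prototype(kappa = 10, f = 0, gamma = 0),
  validity = function(object) {
    v <- c(kappa = object@kappa, f = object@f, gamma = object@gamma)
    if (length(object@kappa) != 1 || length(object@f) != 1 ||
        length(object@gamma) != 1)
      return("kappa, f and gamma must be scalars")
    if (!all(is.finite(v))) return("energy parameters must be finite")
    if (any(v < 0)) return("energy parameters must be >= 0")
    TRUE
  }
)

#' A bead-rod chain configuration
#'
#' An N-bond chain is stored as its N+1 joint positions (rows of `joints`,
#' columns x, y, z) in units of the bond length. Joint 1 is anchored at the
#' origin. Validity enforces the anchoring, unit bond lengths (relative
#' tolerance 1e-9), and - unless `selfAvoiding` is `FALSE` - the hard-sphere
#' constraint that no two non-consecutive joints sit closer than one bond
#' length (sphere radius l_b/2 on every joint).
#'
#' @slot joints numeric matrix, (N+1) x 3
#' @slot bondLength bond length l_b (default 1)
#' @slot selfAvoiding logical; `FALSE` flags fixtures (e.g. ideal random
#'   walks) that deliberately bypass the hard-sphere constraint
#' @export
setClass("ChainConfiguration",
  representation(joints = "matrix", bondLength = "numeric",
                 selfAvoiding = "logical"),
  prototype(bondLength = 1, selfAvoiding = TRUE),
  validity = function(object) {
    j <- object@joints
    lb <- object@bondLength
    if (!is.numeric(j) || ncol(j) != 3) return("joints must be an (N+1) x 3 numeric matrix")
    if (nrow(j) < 2) return("a chain needs at least one bond (two joints)")
    if (!all(is.finite(j))) return("joint coordinates must be finite")
    if (length(lb) != 1 || !is.finite(lb) || lb <= 0)
      return("bondLength must be a positive scalar")
    if (any(abs(j[1, ]) > 1e-9 * lb)) return("joint 1 must sit at the origin")
    bl <- sqrt(rowSums((j[-1, , drop = FALSE] - j[-nrow(j), , drop = FALSE])^2))
    if (any(abs(bl - lb) > .BOND_RTOL * lb))
      return("all bonds must have length bondLength (rel. tol. 1e-9)")
    if (object@selfAvoiding && cpp_has_overlap(j, lb))
      return("hard-sphere overlap: non-consecutive joints closer than bondLength")
    TRUE
  }
)

#' Conformation variables of a chain
#'
#' Squared end-to-end distance R^2 = |r_N - r_0|^2, squared radius of
#' gyration Rg^2 (mean squared distance of joints from their centroid) and
#' the xz component of the gyration tensor R_xz (centroid-referenced mean of
#' (x - xbar)(z - zbar); may be negative). All in units of l_b^2.
#'
#' @slot r2,rg2,rxz numeric scalars
#' @export
setClass("ConformationVariables",
  representation(r2 = "numeric", rg2 = "numeric", rxz = "numeric"),
  validity = function(object) {
    if (!all(is.finite(c(object@r2, object@rg2, object@rxz))))
      return("conformation variables must be finite")
    if (object@r2 < 0) return("r2 must be >= 0")
    if (object@rg2 < 0) return("rg2 must be >= 0")
    if (abs(object@rxz) > object@rg2 * (1 + 1e-12))
      return("|rxz| cannot exceed rg2")
    TRUE
  }
)

#' Monte Carlo schedule
#'
#' Sweep counts and move amplitude for a Metropolis run. One sweep is N
#' attempted moves. After `nEquilibrationSweeps` discarded sweeps, one
#' configuration is retained every `sampleInterval` sweeps of the
#' `nSampleSweeps` sampling phase. With `autoTune = TRUE` the rotation
#' amplitude is adjusted toward ~50% acceptance during the first half of
#' equilibration and then frozen.
#'
#' @slot nEquilibrationSweeps,nSampleSweeps,sampleInterval integer counts
#' @slot maxRotationAngle maximum rotation angle per move, radians, in (0, pi]
#' @slot seed integer RNG seed
#' @slot autoTune logical
#' @export
setClass("MCSchedule",
  representation(nEquilibrationSweeps = "integer", nSampleSweeps = "integer",
                 sampleInterval = "integer", maxRotationAngle = "numeric",
                 seed = "integer", autoTune = "logical"),
  prototype(nEquilibrationSweeps = 20000L, nSampleSweeps = 10000L,
            sampleInterval = 100L, maxRotationAngle = pi / 2, seed = 1L,
            autoTune = FALSE),
  validity = function(object) {
    counts <- c(object@nEquilibrationSweeps, object@nSampleSweeps,
                object@sampleInterval)
    if (any(counts < 1L)) return("all sweep counts must be >= 1")
    if (object@sampleInterval > object@nSampleSweeps)
      return("sampleInterval cannot exceed nSampleSweeps")
    a <- object@maxRotationAngle
    if (!is.finite(a) || a <= 0 || a > pi)
      return("maxRotationAngle must lie in (0, pi]")
    TRUE
  }
)

#' Result of a Monte Carlo run
#'
#' Retained configurations are stored as an (N+1) x 3 x K array (`samples`),
#' with per-sample conformation variables in `observables` and the per-sweep
#' total energy in `energyTrace`.
#'
#' @slot samples numeric array (N+1) x 3 x K
#' @slot observables data.frame with columns r2, rg2, rxz (one row per sample)
#' @slot acceptanceRates named numeric, per move type, in `[0, 1]`
#' @slot energyTrace numeric, one entry per sweep
#' @slot params [EnergyParameters-class] used for the run
#' @slot schedule [MCSchedule-class] used for the run
#' @slot bondLength bond length l_b
#' @slot selfAvoiding whether the hard-sphere constraint was enforced
#' @slot finalMaxAngle rotation amplitude in force during sampling
#' @export
setClass("MCResult",
  representation(samples = "array", observables = "data.frame",
                 acceptanceRates = "numeric", energyTrace = "numeric",
                 params = "EnergyParameters", schedule = "MCSchedule",
                 bondLength = "numeric", selfAvoiding = "logical",
                 finalMaxAngle = "numeric"),
  validity = function(object) {
    r <- object@acceptanceRates
    r <- r[is.finite(r)]
    if (length(r) && (any(r < 0) || any(r > 1)))
      return("acceptance rates must lie in [0, 1]")
    if (!all(is.finite(object@energyTrace)))
      return("energy trace must be finite")
    if (dim(object@samples)[3] != nrow(object@observables))
      return("one observables row per retained sample required")
    TRUE
  }
)

#' Rectangular scattering-vector grid
#'
#' Sorted Q values (units 1/l_b) along the flow direction x and the gradient
#' direction z. Maps on the grid flatten row-major with Q_x as the outer
#' (slow) index and Q_z as the inner (fast) index; see [flattenMap()].
#'
#' @slot qx,qz sorted numeric vectors
#' @export
setClass("QGrid",
  representation(qx = "numeric", qz = "numeric"),
  validity = function(object) {
    for (v in list(object@qx, object@qz)) {
      if (length(v) < 1 || !all(is.finite(v))) return("Q values must be finite")
      if (is.unsorted(v, strictly = TRUE)) return("Q values must be strictly increasing")
    }
    TRUE
  }
)

#' A 2D scattering map
#'
#' Ensemble-averaged normalised intensity I_xz(Q_x, Q_z) on a [QGrid-class]
#' (rows index Q_x, columns Q_z). Validity enforces 0 <= I <= 1, I = 1 at the
#' origin when the grid contains it, and inversion symmetry I(Q) = I(-Q) on
#' symmetric grids, all to 1e-9.
#'
#' @slot grid a [QGrid-class]
#' @slot intensity numeric matrix, length(qx) x length(qz)
#' @slot nConfigurations number of configurations averaged over
#' @export
setClass("ScatteringMap",
  representation(grid = "QGrid", intensity = "matrix",
                 nConfigurations = "integer"),
  validity = function(object) {
    qx <- object@grid@qx; qz <- object@grid@qz
    I <- object@intensity
    if (nrow(I) != length(qx) || ncol(I) != length(qz))
      return("intensity dimensions must match the grid")
    if (!all(is.finite(I))) return("intensities must be finite")
    if (min(I) < -1e-9 || max(I) > 1 + 1e-9)
      return("intensities must lie in [0, 1]")
    ix0 <- which(abs(qx) < 1e-12); iz0 <- which(abs(qz) < 1e-12)
    if (length(ix0) == 1 && length(iz0) == 1 &&
        abs(I[ix0, iz0] - 1) > 1e-9)
      return("I at Q = 0 must equal 1")
    if (all(abs(rev(qx) + qx) < 1e-12) && all(abs(rev(qz) + qz) < 1e-12)) {
      if (max(abs(I - I[nrow(I):1, ncol(I):1])) > 1e-9)
        return("inversion symmetry I(Q) = I(-Q) violated")
    }
    TRUE
  }
)

#' A scattering dataset for inversion
#'
#' Matrix `F` of flattened scattering maps (one row per simulated parameter
#' combination) together with the per-row table of the six inversion targets:
#' the energy parameters kappa, f, gamma*L and the ensemble-mean conformation
#' variables R^2/L^2, Rg^2 and R_xz (the latter two normalised by L to the
#' power recorded in the manifest as `normExponent`, default 2).
#'
#' @slot F numeric matrix, n_samples x n_grid_points
#' @slot targets data.frame with columns kappa, f, gammaL, r2_over_L2,
#'   rg2_norm, rxz_norm
#' @slot grid the common [QGrid-class] of every row
#' @slot manifest provenance list (seeds, schedule, chain spec, grid
#'   signature, excluded rows)
#' @export
setClass("ScatteringDataset",
  representation(F = "matrix", targets = "data.frame", grid = "QGrid",
                 manifest = "list"),
  validity = function(object) {
    if (nrow(object@F) != nrow(object@targets))
      return("F and targets must have the same number of rows")
    np <- length(object@grid@qx) * length(object@grid@qz)
    if (ncol(object@F) != np)
      return("each F row must have one entry per grid point")
    if (nrow(object@F) > 0) {
      if (!all(is.finite(object@F))) return("F must be finite")
      if (min(object@F) < -1e-9 || max(object@F) > 1 + 1e-9)
        return("F entries must lie in [0, 1]")
    }
    need <- c("kappa", "f", "gammaL", "r2_over_L2", "rg2_norm", "rxz_norm")
    if (!all(need %in% names(object@targets)))
      return(paste("targets must contain columns:", paste(need, collapse = ", ")))
    TRUE
  }
)

#' Singular value decomposition of a scattering matrix
#'
#' Thin SVD F = U diag(d) V^T with a fixed sign convention (the
#' largest-magnitude entry of every right singular vector is positive), so
#' projections are reproducible across linear-algebra backends.
#'
#' @slot d non-increasing singular values, >= 0
#' @slot u,v left/right singular vector matrices (thin)
#' @export
setClass("SVDResult",
  representation(d = "numeric", u = "matrix", v = "matrix"),
  validity = function(object) {
    if (any(object@d < 0)) return("singular values must be >= 0")
    if (is.unsorted(rev(object@d))) return("singular values must be non-increasing")
    if (ncol(object@u) != length(object@d) || ncol(object@v) != length(object@d))
      return("u and v must have one column per singular value")
    TRUE
  }
)

#' RBF + white-noise kernel specification
#'
#' Covariance k(x, x') = exp(-d(x, x')^2 / (2 l^2)) + sigma^2 delta_{x,x'},
#' with d the Euclidean distance, `l` the correlation length and `sigma` the
#' observational noise scale (sigma^2 enters the diagonal; `sigma` is the
#' reported hyperparameter). `constantMean` is the constant prior mean of the
#' regression function.
#'
#' @slot l correlation length, > 0
#' @slot sigma noise scale, >= 0
#' @slot constantMean constant prior mean
#' @export
setClass("KernelSpec",
  representation(l = "numeric", sigma = "numeric", constantMean = "numeric"),
  prototype(l = 1, sigma = 0.1, constantMean = 0),
  validity = function(object) {
    if (!is.finite(object@l) || object@l <= 0) return("l must be positive and finite")
    if (!is.finite(object@sigma) || object@sigma < 0) return("sigma must be >= 0 and finite")
    if (!is.finite(object@constantMean)) return("constantMean must be finite")
    TRUE
  }
)

#' A trained Gaussian-process regressor for one inversion target
#'
#' Stores the optimised kernel, the training inputs/targets and the cached
#' Cholesky factor of the training covariance, plus the Q grid the inputs
#' were flattened from (prediction refuses maps from a different grid).
#'
#' @slot kernel optimised [KernelSpec-class]
#' @slot X training input matrix (rows = flattened maps)
#' @slot y training target vector
#' @slot cholL upper Cholesky factor of the training covariance
#' @slot alpha cached K^{-1}(y - m)
#' @slot targetName name of the inversion target
#' @slot logMarginalLikelihood value at the optimum
#' @slot yScale internal target scale: targets are standardised to unit
#'   variance about the constant mean before training (the unit-amplitude
#'   RBF kernel assumes O(1) signal variance), and predictions are mapped
#'   back; `sigma` is therefore a noise scale relative to the target
#'   standard deviation. 1 when scaling was disabled.
#' @slot gridSignature signature string of the training Q grid ("" when
#'   trained on a bare matrix)
#' @export
setClass("GPRModel",
  representation(kernel = "KernelSpec", X = "matrix", y = "numeric",
                 cholL = "matrix", alpha = "numeric", targetName = "character",
                 logMarginalLikelihood = "numeric", yScale = "numeric",
                 gridSignature = "character"),
  prototype(yScale = 1),
  validity = function(object) {
    if (nrow(object@X) != length(object@y))
      return("one target per training row required")
    TRUE
  }
)

#' Held-out inversion accuracy report
#'
#' Per-target optimised hyperparameters, log marginal likelihood and r^2
#' score on held-out rows, with the predicted-vs-reference pairs.
#'
#' @slot summary data.frame with columns target, l, sigma, lml, r2
#' @slot predictions named list of data.frames (reference, predicted)
#' @slot models named list of [GPRModel-class]
#' @export
setClass("InversionReport",
  representation(summary = "data.frame", predictions = "list",
                 models = "list"),
  validity = function(object) {
    if (nrow(object@summary) && any(object@summary$r2 > 1 + 1e-12))
      return("r2 cannot exceed 1")
    TRUE
  }
)
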