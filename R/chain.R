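# Chain configurations, the driven-chain energy, and conformation variables.

#' Construct a chain configuration
#'
#' @param joints numeric (N+1) x 3 matrix of joint positions (columns x, y,
#'   z) in units of the bond length; row 1 must be the origin.
#' @param bondLength bond length l_b (default 1).
#' @param selfAvoiding enforce the hard-sphere no-overlap invariant
#'   (default `TRUE`). Ideal-chain fixtures set this to `FALSE` and are
#'   thereby flagged as non-self-avoiding.
#' @return a [ChainConfiguration-class]
#' @examples
#' rod <- straightChain(10)
#' nBonds(rod)
#' @export
ChainConfiguration <- function(joints, bondLength = 1, selfAvoiding = TRUE) {
  joints <- as.matrix(joints)
  storage.mode(joints) <- "double"
  colnames(joints) <- c("x", "y", "z")
  new("ChainConfiguration", joints = joints, bondLength = bondLength,
      selfAvoiding = selfAvoiding)
}

#' Construct energy parameters
#'
#' @param kappa bending modulus (k_B T); @param f stretching force along x
#'   (k_B T / l_b); @param gamma shear coupling along z. All >= 0; the
#'   temperature is fixed at k_B T = 1 (natural units).
#' @return an [EnergyParameters-class]
#' @export
EnergyParameters <- function(kappa = 10, f = 0, gamma = 0) {
  new("EnergyParameters", kappa = as.numeric(kappa), f = as.numeric(f),
      gamma = as.numeric(gamma))
}

#' A straight rod along x
#'
#' @param nBonds number of bonds N; @param bondLength bond length.
#' @return a [ChainConfiguration-class] with joints at (0..N, 0, 0) * l_b
#' @export
straightChain <- function(nBonds, bondLength = 1) {
  ChainConfiguration(cbind(0:nBonds * bondLength, 0, 0), bondLength)
}

#' @rdname ChainConfiguration-class
#' @export
setMethod("joints", "ChainConfiguration", function(x) x@joints)

#' @rdname ChainConfiguration-class
#' @export
setMethod("nBonds", "ChainConfiguration", function(x) nrow(x@joints) - 1L)

#' @rdname ChainConfiguration-class
#' @export
setMethod("bondLength", "ChainConfiguration", function(x) x@bondLength)

setMethod("show", "ChainConfiguration", function(object) {
  cat(sprintf("ChainConfiguration: %d bonds, l_b = %g%s\n",
              nBonds(object), object@bondLength,
              if (object@selfAvoiding) "" else " (self-avoidance off)"))
  e <- object@joints[nrow(object@joints), ]
  cat(sprintf("  free end at (%.3f, %.3f, %.3f)\n", e[1], e[2], e[3]))
})

setMethod("show", "EnergyParameters", function(object) {
  cat(sprintf("EnergyParameters: kappa = %g, f = %g, gamma = %g (k_BT = 1)\n",
              object@kappa, object@f, object@gamma))
})

#' Bond tangent vectors
#'
#' Unit tangents t_i = (r_{i+1} - r_i) / l_b, one row per bond.
#'
#' @param x a [ChainConfiguration-class]
#' @return numeric N x 3 matrix of unit vectors
#' @export
setMethod("tangentVectors", "ChainConfiguration", function(x) {
  j <- x@joints
  t <- (j[-1, , drop = FALSE] - j[-nrow(j), , drop = FALSE]) / x@bondLength
  nrm <- sqrt(rowSums(t^2))
  if (any(nrm < 1e-300)) stop("zero-length bond: invalid configuration")
  unname(t)
})

#' Driven-chain energy
#'
#' The energy of an N-bond chain under bending stiffness, an x-directed
#' stretching force and a z-gradient shear coupling:
#' \deqn{E = \sum_{i=1}^{N-1} \kappa (1 - t_{i-1}\cdot t_i)
#'       - f\, l_b \sum_{i=0}^{N-1} (t_i\cdot \hat x)
#'       - \gamma\, l_b \sum_{i=0}^{N-1} z_i\, (t_i\cdot \hat x)}
#' with \eqn{z_i} the z coordinate of the bond's starting joint.
#' `energyTerms` returns the additive decomposition
#' `c(bending, stretch, shear)`; `totalEnergy` their sum. The bending term is
#' always >= 0 and vanishes iff all consecutive tangents are parallel.
#'
#' @param config a [ChainConfiguration-class]
#' @param params an [EnergyParameters-class]
#' @return `energyTerms`: named numeric of length 3; `totalEnergy`: scalar
#'   (k_B T).
#' @examples
#' totalEnergy(straightChain(200), EnergyParameters(kappa = 10, f = 0.5))
#' @rdname chainEnergy
#' @export
setMethod("energyTerms", signature("ChainConfiguration", "EnergyParameters"),
  function(config, params) {
    t <- tangentVectors(config)
    lb <- config@bondLength
    n <- nrow(t)
    bend <- if (n >= 2)
      params@kappa * sum(1 - rowSums(t[-1, , drop = FALSE] *
                                     t[-n, , drop = FALSE])) else 0
    stretch <- -params@f * lb * sum(t[, 1])
    z0 <- config@joints[seq_len(n), 3]  # starting joint of each bond
    shear <- -params@gamma * lb * sum(z0 * t[, 1])
    c(bending = bend, stretch = stretch, shear = shear)
  })

#' @rdname chainEnergy
#' @export
setMethod("totalEnergy", signature("ChainConfiguration", "EnergyParameters"),
  function(config, params) {
    e <- sum(energyTerms(config, params))
    if (!is.finite(e)) stop("non-finite energy: invalid configuration")
    e
  })

# Vectorised conformation variables for an (N+1) x 3 coordinate matrix.
.confVars <- function(j) {
  d <- j[nrow(j), ] - j[1, ]
  ctr <- colMeans(j)
  dx <- j[, 1] - ctr[1]; dy <- j[, 2] - ctr[2]; dz <- j[, 3] - ctr[3]
  c(r2 = sum(d^2), rg2 = mean(dx^2 + dy^2 + dz^2), rxz = mean(dx * dz))
}

#' Conformation variables
#'
#' Squared end-to-end distance `r2 = |r_N - r_0|^2`, squared radius of
#' gyration `rg2` and the xz gyration-tensor component `rxz`, computed in
#' centroid form (O(N)); the equivalent half-pair-average forms
#' \eqn{R_g^2 = \langle |r_i - r_j|^2 \rangle_{i,j} / 2} and
#' \eqn{R_{xz} = \langle (x_i - x_j)(z_i - z_j) \rangle_{i,j} / 2}
#' (averages over all ordered joint pairs) give identical values.
#'
#' @param x a [ChainConfiguration-class]
#' @return a [ConformationVariables-class]
#' @examples
#' conformationVariables(straightChain(10))
#' @export
setMethod("conformationVariables", "ChainConfiguration", function(x) {
  v <- .confVars(x@joints)
  new("ConformationVariables", r2 = unname(v["r2"]), rg2 = unname(v["rg2"]),
      rxz = unname(v["rxz"]))
})

#' @rdname conformationVariables
#' @param object a `ConformationVariables`
#' @export
setMethod("show", "ConformationVariables", function(object) {
  cat(sprintf("ConformationVariables: R2 = %.6g, Rg2 = %.6g, Rxz = %.6g\n",
              object@r2, object@rg2, object@rxz))
})

#' Hard-sphere overlap test
#'
#' `TRUE` iff some non-consecutive pair of joints sits closer than one bond
#' length (hard spheres of radius l_b/2 on every joint). Consecutive joints,
#' at exactly l_b, never count; the comparison carries a 1e-12 relative
#' slack so exactly-touching spheres do not trigger.
#'
#' @param x a [ChainConfiguration-class] or a bare (N+1) x 3 matrix
#' @param bondLength bond length when `x` is a bare matrix
#' @return logical scalar
#' @export
hasOverlap <- function(x, bondLength = 1) {
  if (is(x, "ChainConfiguration")) {
    cpp_has_overlap(x@joints, x@bondLength)
  } else {
    cpp_has_overlap(as.matrix(x), bondLength)
  }
}

#' Read/write a chain as CSV
#'
#' Plain CSV with columns x, y, z, one row per joint, full double precision.
#'
#' @param config a [ChainConfiguration-class]; @param file path
#' @param bondLength,selfAvoiding passed to the constructor on read
#' @return `readChainCSV`: a [ChainConfiguration-class]
#' @export
writeChainCSV <- function(config, file) {
  .writeExactCSV(data.table::as.data.table(joints(config)), file)
  invisible(file)
}

#' @rdname writeChainCSV
#' @export
readChainCSV <- function(file, bondLength = 1, selfAvoiding = TRUE) {
  j <- as.matrix(.readNumericCSV(file))
  ChainConfiguration(j, bondLength = bondLength, selfAvoiding = selfAvoiding)
}
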