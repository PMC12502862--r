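# 2D scattering function I_xz(Q) on a rectangular Q grid.

#' Construct a Q grid
#'
#' `QGrid(qx, qz)` wraps explicit axes; `makeQGrid(nPerAxis, qMax)` builds
#' the symmetric uniform grid on `[-qMax, qMax]^2` with `nPerAxis` points per
#' axis. `nPerAxis` must be odd so that Q = 0 is a grid point (required for
#' the I(0) = 1 normalisation check). The full-scale protocol uses 51 points
#' per axis with qMax = 50*pi/L.
#'
#' @param qx,qz strictly increasing numeric vectors (units 1/l_b)
#' @param nPerAxis odd number of points per axis
#' @param qMax grid half-width (units 1/l_b)
#' @return a [QGrid-class]
#' @examples
#' g <- makeQGrid(51, 50 * pi / 200)
#' nGridPoints(g)
#' @export
QGrid <- function(qx, qz) new("QGrid", qx = as.numeric(qx), qz = as.numeric(qz))

#' @rdname QGrid
#' @export
makeQGrid <- function(nPerAxis, qMax) {
  if (nPerAxis %% 2 != 1)
    stop("nPerAxis must be odd so that Q = 0 lies on the grid")
  if (qMax <= 0) stop("qMax must be positive")
  ax <- seq(-qMax, qMax, length.out = nPerAxis)
  ax[(nPerAxis + 1) / 2] <- 0  # exact origin
  QGrid(ax, ax)
}

#' @rdname QGrid-class
#' @export
setMethod("qxValues", "QGrid", function(x) x@qx)

#' @rdname QGrid-class
#' @export
setMethod("qzValues", "QGrid", function(x) x@qz)

#' Number of grid points
#' @param grid a [QGrid-class]
#' @export
nGridPoints <- function(grid) length(grid@qx) * length(grid@qz)

#' Grid signature string
#'
#' Canonical full-precision text rendering of the axes; stored with datasets
#' and trained models so that a map sampled on a different grid is refused at
#' prediction time.
#'
#' @param grid a [QGrid-class]
#' @export
gridSignature <- function(grid) {
  paste(c(sprintf("%d|%d", length(grid@qx), length(grid@qz)),
          sprintf("%.17g", grid@qx), sprintf("%.17g", grid@qz)),
        collapse = ",")
}

setMethod("show", "QGrid", function(object) {
  cat(sprintf("QGrid: %d x %d points, qx in [%.4g, %.4g], qz in [%.4g, %.4g]\n",
              length(object@qx), length(object@qz), min(object@qx),
              max(object@qx), min(object@qz), max(object@qz)))
})

#' Scattering intensity of a single configuration
#'
#' The normalised interference pattern of M point scatterers,
#' \deqn{I(Q) = \left|\sum_j \exp(i\, Q\cdot r_j)\right|^2 / M^2,}
#' evaluated at Q = (Q_x, 0, Q_z) on every grid point. Computed through the
#' complex scattering amplitude, which factorises over the grid axes into
#' one matrix product (never the O(M^2) pair sum, though it equals it).
#'
#' @param points M x 3 coordinate matrix or a [ChainConfiguration-class]
#'   (scatterers are the N+1 joints, anchored joint included)
#' @param grid a [QGrid-class]
#' @return numeric matrix, length(qx) x length(qz)
#' @export
singleConfigIntensity <- function(points, grid) {
  if (is(points, "ChainConfiguration")) points <- points@joints
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("at least one scatterer is required")
  .intensityXZ(points[, 1], points[, 3], grid@qx, grid@qz)
}

# Amplitude A[a,b] = sum_j exp(i (qx_a x_j + qz_b z_j)) via outer products.
.intensityXZ <- function(x, z, qx, qz) {
  ex <- exp(1i * outer(qx, x))           # |qx| x M
  ez <- exp(1i * outer(z, qz))           # M x |qz|
  a <- ex %*% ez
  (Mod(a) / length(x))^2
}

#' Ensemble-averaged scattering map
#'
#' Arithmetic mean of the single-configuration intensities over the retained
#' Monte Carlo samples (no orientational averaging: the anisotropy of the
#' driven ensemble is the signal).
#'
#' @param result an [MCResult-class] (or a list of configurations /
#'   coordinate matrices)
#' @param grid a [QGrid-class]
#' @return a [ScatteringMap-class]
#' @export
ensembleIntensity <- function(result, grid) {
  if (is(result, "MCResult")) {
    k <- dim(result@samples)[3]
    confs <- lapply(seq_len(k), function(i) result@samples[, , i])
  } else {
    confs <- lapply(result, function(c)
      if (is(c, "ChainConfiguration")) c@joints else as.matrix(c))
  }
  if (length(confs) < 1) stop("at least one retained sample is required")
  acc <- 0
  for (j in confs) acc <- acc + .intensityXZ(j[, 1], j[, 3], grid@qx, grid@qz)
  ScatteringMap(acc / length(confs), grid, nConfigurations = length(confs))
}

#' Construct a scattering map
#'
#' @param intensity numeric matrix, length(qx) x length(qz)
#' @param grid a [QGrid-class]
#' @param nConfigurations number of configurations averaged over
#' @return a [ScatteringMap-class]
#' @export
ScatteringMap <- function(intensity, grid, nConfigurations = 1) {
  new("ScatteringMap", grid = grid, intensity = unname(as.matrix(intensity)),
      nConfigurations = as.integer(nConfigurations))
}

#' @rdname ScatteringMap-class
#' @param x,object a [ScatteringMap-class]
#' @export
setMethod("intensityMatrix", "ScatteringMap", function(x) x@intensity)

#' @rdname ScatteringMap-class
#' @export
setMethod("qGrid", "ScatteringMap", function(x) x@grid)

#' Flatten a scattering map to a vector
#'
#' Row-major flattening with Q_x as the outer (slow) index and Q_z as the
#' inner (fast) index: element `(a-1) * length(qz) + b` is I(qx\[a\], qz\[b\]).
#' This is the fixed order of every dataset row; [unflattenMap()] inverts it.
#'
#' @param x a [ScatteringMap-class]
#' @return numeric vector of length `nGridPoints(grid)`
#' @rdname flattenMap
#' @export
setMethod("flattenMap", "ScatteringMap", function(x) as.vector(t(x@intensity)))

#' Rebuild an intensity matrix from a flattened row
#'
#' @param v flattened intensity vector (see [flattenMap()])
#' @param grid the [QGrid-class] it was flattened from
#' @return numeric matrix, length(qx) x length(qz)
#' @export
unflattenMap <- function(v, grid) {
  matrix(v, nrow = length(grid@qx), ncol = length(grid@qz), byrow = TRUE)
}

setMethod("show", "ScatteringMap", function(object) {
  cat(sprintf("ScatteringMap: %d x %d grid, averaged over %d configuration(s)\n",
              nrow(object@intensity), ncol(object@intensity),
              object@nConfigurations))
})

#' Read/write a scattering map as long-format CSV
#'
#' Columns qx, qz, I; one row per grid point, full double precision.
#'
#' @param map a [ScatteringMap-class]; @param file path
#' @param nConfigurations stored count on read (not in the CSV)
#' @export
writeScatteringMapCSV <- function(map, file) {
  g <- map@grid
  dt <- data.table::data.table(
    qx = rep(g@qx, each = length(g@qz)),
    qz = rep(g@qz, times = length(g@qx)),
    I = flattenMap(map))
  .writeExactCSV(dt, file)
  invisible(file)
}

#' @rdname writeScatteringMapCSV
#' @export
readScatteringMapCSV <- function(file, nConfigurations = 1) {
  dt <- .readNumericCSV(file)
  qx <- sort(unique(dt$qx)); qz <- sort(unique(dt$qz))
  g <- QGrid(qx, qz)
  o <- order(match(dt$qx, qx), match(dt$qz, qz))
  ScatteringMap(unflattenMap(dt$I[o], g), g, nConfigurations)
}
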