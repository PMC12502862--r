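# Singular value decomposition of the scattering matrix: spectrum,
# projections onto leading right singular vectors, feasibility diagnostics.

#' Decompose a scattering matrix
#'
#' Thin (economy-size) SVD `F = U diag(d) V^T` of the matrix of flattened
#' scattering maps. No mean-centering is applied: the matrix is decomposed
#' directly, and the squared singular values are proportional to the variance
#' of the data projected on the corresponding right singular vector (a
#' `center` flag exists for comparison). Each right singular vector's
#' largest-magnitude entry is made positive (the matching left vector is
#' flipped too) so projections are reproducible across linear-algebra
#' backends.
#'
#' @param F numeric matrix (n_samples x n_grid_points) or a
#'   [ScatteringDataset-class]
#' @param center subtract column means first (default `FALSE`)
#' @return an [SVDResult-class]
#' @examples
#' s <- decomposeScattering(diag(5))
#' singularValues(s)
#' @export
decomposeScattering <- function(F, center = FALSE) {
  if (is(F, "ScatteringDataset")) F <- scatteringMatrix(F)
  F <- as.matrix(F)
  if (length(F) == 0) stop("F must be non-empty")
  if (!all(is.finite(F))) stop("F must be finite")
  if (center) F <- sweep(F, 2, colMeans(F))
  s <- svd(F)
  # sign convention: largest-|entry| of each right vector positive
  for (k in seq_along(s$d)) {
    i <- which.max(abs(s$v[, k]))
    if (s$v[i, k] < 0) {
      s$v[, k] <- -s$v[, k]
      s$u[, k] <- -s$u[, k]
    }
  }
  new("SVDResult", d = s$d, u = s$u, v = s$v)
}

#' @rdname SVDResult-class
#' @param x,object an [SVDResult-class]
#' @export
setMethod("singularValues", "SVDResult", function(x) x@d)

#' @rdname SVDResult-class
#' @export
setMethod("rightVectors", "SVDResult", function(x) x@v)

setMethod("show", "SVDResult", function(object) {
  d <- object@d
  cat(sprintf("SVDResult: rank %d, leading values %s\n", length(d),
              paste(sprintf("%.4g", utils::head(d, 3)), collapse = ", ")))
})

#' Project maps onto leading right singular vectors
#'
#' Column j of the result is `F %*% V_j`: the coordinates of every map in
#' the basis of the first k right singular vectors (FV0, FV1, FV2, ... in
#' the feasibility analysis). With k equal to the full rank the projection
#' is an orthogonal change of basis and preserves row norms.
#'
#' @param F matrix of flattened maps or a [ScatteringDataset-class]
#' @param svdResult an [SVDResult-class] from [decomposeScattering()]
#' @param k number of leading vectors (default 3)
#' @return numeric matrix, n_samples x k, columns named FV0..FV(k-1)
#' @export
projectScattering <- function(F, svdResult, k = 3) {
  if (is(F, "ScatteringDataset")) F <- scatteringMatrix(F)
  if (k <= 0) stop("k must be positive")
  if (k > length(svdResult@d)) stop("k exceeds the decomposition rank")
  p <- as.matrix(F) %*% svdResult@v[, seq_len(k), drop = FALSE]
  colnames(p) <- paste0("FV", seq_len(k) - 1L)
  p
}

#' Singular spectrum report
#'
#' Table of the leading singular values with the cumulative variance
#' fraction computed from squared singular values.
#'
#' @param svdResult an [SVDResult-class]
#' @param topK number of ranks to report (default all)
#' @return data.frame with columns rank, value, cumulativeVarianceFraction
#' @export
spectrumReport <- function(svdResult, topK = length(svdResult@d)) {
  if (topK < 1) stop("topK must be >= 1")
  d <- svdResult@d
  topK <- min(topK, length(d))
  cum <- cumsum(d^2) / sum(d^2)
  data.frame(rank = seq_len(topK), value = d[seq_len(topK)],
             cumulativeVarianceFraction = cum[seq_len(topK)])
}
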