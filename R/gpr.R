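# Gaussian-process regression from flattened scattering maps to inversion
# targets: RBF + white-noise kernel, log-marginal-likelihood optimisation,
# posterior-mean prediction, r^2 scoring.

#' Construct a kernel specification
#'
#' @param l correlation length, > 0
#' @param sigma observational noise scale, >= 0 (sigma^2 enters the
#'   covariance diagonal; `sigma` is the reported hyperparameter)
#' @param constantMean constant prior mean of the regression function
#' @return a [KernelSpec-class]
#' @export
KernelSpec <- function(l = 1, sigma = 0.1, constantMean = 0) {
  new("KernelSpec", l = as.numeric(l), sigma = as.numeric(sigma),
      constantMean = as.numeric(constantMean))
}

setMethod("show", "KernelSpec", function(object) {
  cat(sprintf("KernelSpec: l = %.6g, sigma = %.6g, constant mean = %.6g\n",
              object@l, object@sigma, object@constantMean))
})

# Squared Euclidean distances between rows of A and rows of B.
.cross2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Kernel (covariance) matrix
#'
#' Entries `exp(-d(x, x')^2 / (2 l^2))` with d the Euclidean distance
#' between rows; when `Xprime` is omitted the training covariance is
#' returned, with `sigma^2` added on the diagonal (white observational
#' noise, applied only to same-index pairs of the same set).
#'
#' @param X,Xprime row matrices of inputs with matching column dimension
#' @param spec a [KernelSpec-class]
#' @return covariance matrix, nrow(X) x nrow(Xprime)
#' @export
kernelMatrix <- function(X, Xprime = NULL, spec = KernelSpec()) {
  X <- as.matrix(X)
  self <- is.null(Xprime)
  Xprime <- if (self) X else as.matrix(Xprime)
  if (ncol(X) != ncol(Xprime)) stop("input dimensions do not match")
  K <- exp(-.cross2(X, Xprime) / (2 * spec@l^2))
  if (self) K <- K + diag(spec@sigma^2, nrow(X))
  K
}

#' Log marginal likelihood of a GP prior
#'
#' \deqn{\log p(y \mid X, l, \sigma) = -\tfrac12 (y-m)^T K^{-1} (y-m)
#'   - \tfrac12 \log|K| - \tfrac n2 \log 2\pi}
#' with `K` the training covariance (RBF + sigma^2 I) and `m` the constant
#' prior mean. This is the cost function maximised during hyperparameter
#' training. A singular covariance (sigma = 0 with duplicate rows) surfaces
#' as a Cholesky error, not a masked value.
#'
#' @param X training inputs (rows); @param y training targets
#' @param spec a [KernelSpec-class]
#' @return scalar log marginal likelihood
#' @export
logMarginalLikelihood <- function(X, y, spec) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  K <- kernelMatrix(X, spec = spec)
  L <- chol(K)
  r <- y - spec@constantMean
  alpha <- backsolve(L, forwardsolve(t(L), r))
  -0.5 * sum(r * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
}

# Fixed diagonal jitter guaranteeing a stable Cholesky factorisation when
# the optimiser drives sigma toward its lower bound (same role as
# scikit-learn's GaussianProcessRegressor alpha).
.GP_JITTER <- 1e-10

# LML and its gradient wrt (log l, log sigma); shared by the optimiser.
.lmlGrad <- function(X, y, logl, logsigma, mean) {
  l <- exp(logl); sigma <- exp(logsigma)
  n <- length(y)
  D2 <- .cross2(X, X)
  Krbf <- exp(-D2 / (2 * l^2))
  K <- Krbf + diag(sigma^2 + .GP_JITTER, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = -Inf, grad = c(0, 0)))
  r <- y - mean
  alpha <- backsolve(L, forwardsolve(t(L), r))
  value <- -0.5 * sum(r * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  Kinv <- chol2inv(L)
  A <- tcrossprod(alpha) - Kinv        # (alpha alpha^T - K^{-1})
  dK_dlogl <- Krbf * D2 / l^2          # dK/dl * l
  gl <- 0.5 * sum(A * dK_dlogl)
  gs <- 0.5 * sum(diag(A)) * 2 * sigma^2
  list(value = value, grad = c(gl, gs))
}

#' Fit a Gaussian-process regressor for one target
#'
#' Maximises the log marginal likelihood over (l, sigma) in log space with
#' L-BFGS-B (analytic gradient) from `restarts` seeded random starts plus
#' one default start; the best optimum is kept. The constant prior mean is
#' fixed to the training-target mean. Bounds: l in `[1e-2, 1e3]`, sigma in
#' `[1e-8, 1]`.
#'
#' Because the RBF kernel has unit amplitude, targets are standardised
#' internally to unit variance about their mean before training (predictions
#' are mapped back to original units); the reported `sigma` is thus a noise
#' scale relative to the target standard deviation, one common scale for
#' every target. Set `scaleTargets = FALSE` to optimise on raw targets.
#'
#' @param train a [ScatteringDataset-class], or a bare input matrix
#' @param targetName one of the six target columns (when `train` is a
#'   dataset), e.g. `"kappa"`
#' @param y explicit target vector (when `train` is a bare matrix)
#' @param restarts number of random restarts (default 5)
#' @param seed seed for the restart draws
#' @param lBounds,sigmaBounds optimisation bounds
#' @param scaleTargets standardise targets internally (default `TRUE`)
#' @return a [GPRModel-class]
#' @export
fitGPR <- function(train, targetName = NULL, y = NULL, restarts = 5,
                   seed = 1, lBounds = c(1e-2, 1e3),
                   sigmaBounds = c(1e-8, 1), scaleTargets = TRUE) {
  if (is(train, "ScatteringDataset")) {
    X <- scatteringMatrix(train)
    tg <- targetTable(train)
    if (is.null(targetName) || !targetName %in% names(tg))
      stop("targetName must name a column of the target table")
    y <- tg[[targetName]]
    gsig <- gridSignature(qGrid(train))
  } else {
    X <- as.matrix(train)
    if (is.null(y)) stop("y is required when train is a bare matrix")
    if (is.null(targetName)) targetName <- "y"
    gsig <- ""
  }
  if (nrow(X) < 2) stop("at least two training rows are required")
  m <- mean(y)
  s <- if (scaleTargets) stats::sd(y) else 1
  if (!is.finite(s) || s < 1e-12) s <- 1  # constant targets: no scaling
  ys <- (y - m) / s

  lo <- log(c(lBounds[1], sigmaBounds[1]))
  hi <- log(c(lBounds[2], sigmaBounds[2]))
  set.seed(seed)
  starts <- rbind(c(log(1), log(1e-2)),
                  matrix(stats::runif(2 * restarts, lo, hi),
                         ncol = 2, byrow = TRUE))
  best <- NULL
  trace <- list()
  for (st in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(starts[st, ],
                   fn = function(p) -.lmlGrad(X, ys, p[1], p[2], 0)$value,
                   gr = function(p) -.lmlGrad(X, ys, p[1], p[2], 0)$grad,
                   method = "L-BFGS-B", lower = lo, upper = hi),
      error = function(e) NULL)
    if (is.null(opt)) next
    trace[[length(trace) + 1]] <- c(start = st, value = -opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("hyperparameter optimisation failed to converge from every start; ",
         "trace: ", paste(vapply(trace, function(t)
           sprintf("%g", t["value"]), ""), collapse = ", "))
  spec <- KernelSpec(l = exp(best$par[1]), sigma = exp(best$par[2]),
                     constantMean = m)
  K <- kernelMatrix(X, spec = spec) + diag(.GP_JITTER, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  new("GPRModel", kernel = spec, X = X, y = as.numeric(y), cholL = L,
      alpha = as.numeric(alpha), targetName = targetName,
      logMarginalLikelihood = -best$value, yScale = s, gridSignature = gsig)
}

setMethod("show", "GPRModel", function(object) {
  cat(sprintf(
    "GPRModel[%s]: l = %.4g, sigma = %.4g, LML = %.4g, %d training rows\n",
    object@targetName, object@kernel@l, object@kernel@sigma,
    object@logMarginalLikelihood, nrow(object@X)))
})

#' Predict inversion targets with a trained regressor
#'
#' Posterior mean `m + K*^T K^{-1} (y - m)` at the new inputs. When the new
#' input is a [ScatteringDataset-class] or [ScatteringMap-class], its Q grid
#' signature must match the one the model was trained on: a map sampled on a
#' different grid is refused rather than silently inverted.
#'
#' @param object a [GPRModel-class]
#' @param newdata matrix of flattened maps (rows), a
#'   [ScatteringDataset-class], or a single [ScatteringMap-class]
#' @param ... unused
#' @return numeric vector of posterior-mean predictions
#' @export
setMethod("predict", "GPRModel", function(object, newdata, ...) {
  if (is(newdata, "ScatteringMap")) {
    if (nzchar(object@gridSignature) &&
        !identical(gridSignature(qGrid(newdata)), object@gridSignature))
      stop("Q grid of the map does not match the training grid")
    Xnew <- matrix(flattenMap(newdata), nrow = 1)
  } else if (is(newdata, "ScatteringDataset")) {
    if (nzchar(object@gridSignature) &&
        !identical(gridSignature(qGrid(newdata)), object@gridSignature))
      stop("Q grid of the dataset does not match the training grid")
    Xnew <- scatteringMatrix(newdata)
  } else {
    Xnew <- as.matrix(newdata)
  }
  if (ncol(Xnew) != ncol(object@X))
    stop("new inputs must match the training dimension")
  Kstar <- kernelMatrix(Xnew, object@X, spec = object@kernel)
  as.numeric(object@kernel@constantMean +
             object@yScale * (Kstar %*% object@alpha))
})

#' Coefficient of determination
#'
#' `r2 = 1 - SS_res / SS_tot`; 1 for a perfect inversion, 0 for predicting
#' the reference mean.
#'
#' @param reference,predicted numeric vectors of equal length >= 2
#' @return scalar r^2 (at most 1; can be negative)
#' @export
r2Score <- function(reference, predicted) {
  if (length(reference) != length(predicted)) stop("length mismatch")
  if (length(reference) < 2) stop("need at least two values")
  sst <- sum((reference - mean(reference))^2)
  if (sst == 0) stop("reference variance is zero")
  1 - sum((reference - predicted)^2) / sst
}

#' All six inversion target names
#' @export
inversionTargets <- function() {
  c("kappa", "f", "gammaL", "r2_over_L2", "rg2_norm", "rxz_norm")
}

#' Train and score regressors for all targets
#'
#' Fits one independent GPR per requested target on the training set and
#' scores each on the held-out test set, producing the per-target table of
#' optimised hyperparameters, log marginal likelihood and r^2.
#'
#' @param train,test [ScatteringDataset-class] objects on the same grid
#' @param targets character vector of target columns (default all six)
#' @param restarts,seed passed to [fitGPR()]
#' @param verbose print per-target progress
#' @return an [InversionReport-class]
#' @export
invertDataset <- function(train, test, targets = inversionTargets(),
                          restarts = 5, seed = 1, verbose = FALSE) {
  stopifnot(is(train, "ScatteringDataset"), is(test, "ScatteringDataset"))
  if (!identical(gridSignature(qGrid(train)), gridSignature(qGrid(test))))
    stop("train and test sets are on different Q grids")
  models <- list()
  preds <- list()
  rows <- list()
  for (tn in targets) {
    mod <- fitGPR(train, tn, restarts = restarts, seed = seed)
    ref <- targetTable(test)[[tn]]
    pred <- predict(mod, test)
    models[[tn]] <- mod
    preds[[tn]] <- data.frame(reference = ref, predicted = pred)
    rows[[tn]] <- data.frame(target = tn, l = mod@kernel@l,
                             sigma = mod@kernel@sigma,
                             lml = mod@logMarginalLikelihood,
                             r2 = r2Score(ref, pred))
    if (verbose) message(sprintf("%s: r2 = %.4f", tn, rows[[tn]]$r2))
  }
  new("InversionReport", summary = do.call(rbind, c(rows, make.row.names = FALSE)),
      predictions = preds, models = models)
}

setMethod("show", "InversionReport", function(object) {
  cat("InversionReport:\n")
  print(object@summary, row.names = FALSE, digits = 4)
})

#' @rdname InversionReport-class
#' @param report an [InversionReport-class]
#' @export
inversionSummary <- function(report) report@summary

#' Write a trained model and its JSON sidecar
#'
#' Persists the kernel hyperparameters and training references as plain
#' text: `X.csv`, `y.csv` and `model.json` (target, l, sigma, constant
#' mean, log marginal likelihood, grid signature).
#'
#' @param model a [GPRModel-class]; @param dir output directory
#' @return `readGPRModel`: a [GPRModel-class] (covariance re-factorised on
#'   load)
#' @export
writeGPRModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeExactCSV(data.table::as.data.table(model@X), file.path(dir, "X.csv"))
  .writeExactCSV(data.table::data.table(y = model@y), file.path(dir, "y.csv"))
  jsonlite::write_json(
    list(target = model@targetName, l = model@kernel@l,
         sigma = model@kernel@sigma, constantMean = model@kernel@constantMean,
         logMarginalLikelihood = model@logMarginalLikelihood,
         yScale = model@yScale, gridSignature = model@gridSignature),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeGPRModel
#' @export
readGPRModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  X <- as.matrix(.readNumericCSV(file.path(dir, "X.csv")))
  dimnames(X) <- NULL
  y <- .readNumericCSV(file.path(dir, "y.csv"))$y
  spec <- KernelSpec(meta$l, meta$sigma, meta$constantMean)
  s <- if (is.null(meta$yScale)) 1 else meta$yScale
  K <- kernelMatrix(X, spec = spec) + diag(.GP_JITTER, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), (y - spec@constantMean) / s))
  new("GPRModel", kernel = spec, X = X, y = y, cholL = L,
      alpha = as.numeric(alpha), targetName = meta$target,
      logMarginalLikelihood = meta$logMarginalLikelihood, yScale = s,
      gridSignature = if (is.null(meta$gridSignature)) "" else meta$gridSignature)
}
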