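#' Build the augmented regression design [Z, X, X-tilde]
#'
#' Genotype and knockoff columns are standardized to mean 0 and variance 1,
#' and for every variant the original/knockoff pair is placed in a random
#' order (seeded), so that a solver breaking ties by column position cannot
#' systematically favor originals. Covariates are passed through unchanged.
#'
#' @param Z n x m covariate matrix (may be NULL or have zero columns).
#' @param X n x p genotype matrix.
#' @param Xt n x p knockoff genotype matrix.
#' @param seed integer seed for the pair-order randomization.
#' @return list with `design` (n x (m + 2p)), `map` (list recording `m`,
#'   `p`, the `swap` vector and indices of dropped zero-variance variants)
#'   and `penalty` (0 for covariates, 1 for genetic columns).
#' @export
build_design <- function(Z, X, Xt, seed = NULL) {
  X <- as.matrix(X)
  Xt <- as.matrix(Xt)
  stopifnot(identical(dim(X), dim(Xt)))
  if (is.null(Z)) Z <- matrix(nrow = nrow(X), ncol = 0)
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) == nrow(X))
  p <- ncol(X)
  m <- ncol(Z)
  sdx <- apply(X, 2, stats::sd)
  sdt <- apply(Xt, 2, stats::sd)
  drop <- which(sdx == 0 | sdt == 0)
  if (length(drop) > 0)
    warning(sprintf("%d zero-variance variant pair(s) dropped from the design",
                    length(drop)))
  keep <- setdiff(seq_len(p), drop)
  Xs <- scale(X[, keep, drop = FALSE])
  Xts <- scale(Xt[, keep, drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  swap <- runif(length(keep)) < 0.5
  A <- Xs
  B <- Xts
  A[, swap] <- Xts[, swap]
  B[, swap] <- Xs[, swap]
  design <- cbind(Z, A, B)
  colnames(design) <- NULL
  list(design = design,
       map = list(m = m, p = p, keep = keep, swap = swap),
       penalty = c(rep(0, m), rep(1, 2 * length(keep))))
}

#' Cross-validated sparse regression on the augmented design
#'
#' L1-penalized linear or logistic regression; the covariate columns are
#' unpenalized (penalty weight 0) and the regularization level is the one
#' minimizing the cross-validated deviance. Deterministic given the fold
#' seed.
#'
#' @param design_obj result of [build_design()].
#' @param y response vector (numeric, or 0/1 for `family = "binomial"`).
#' @param family `"gaussian"` or `"binomial"`.
#' @param nfolds number of CV folds (default 10).
#' @param nlambda size of the lambda grid (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @param fold_seed integer seed for the fold assignment.
#' @return list with `beta` (named by design column, intercept excluded),
#'   `lambda_cv` and the `cv.glmnet` fit.
#' @export
fit_sparse_regression <- function(design_obj, y, family = "gaussian",
                                  nfolds = 10, nlambda = 50,
                                  lambda_min_ratio = 0.01, fold_seed = 1) {
  design <- design_obj$design
  n <- nrow(design)
  if (n < nfolds) stop("need at least as many samples as folds")
  if (family == "binomial" && length(unique(y)) < 2)
    stop("binary phenotype with a single class")
  set.seed(fold_seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  penalty <- design_obj$penalty
  # glmnet requires at least one penalized column and no all-zero penalty
  cv <- glmnet::cv.glmnet(design, y, family = family, foldid = foldid,
                          penalty.factor = penalty, standardize = FALSE,
                          nlambda = nlambda,
                          lambda.min.ratio = lambda_min_ratio)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  list(beta = beta, lambda_cv = cv$lambda.min, cv = cv)
}

#' Per-group importance measures from fitted coefficients
#'
#' `T_g` is the sum of absolute fitted coefficients of the original variants
#' in group g, `T_tilde_g` the same over their knockoff copies; covariate
#' coefficients are ignored. The pair-order randomization recorded in the
#' design map is undone here, so `T` always refers to the true originals.
#'
#' @param beta coefficient vector aligned to the design columns.
#' @param map the `map` component of [build_design()].
#' @param partition a [new_partition()] or group index vector of length p.
#' @return list with numeric vectors `T` and `T_tilde` of length L.
#' @export
group_importance <- function(beta, map, partition) {
  g <- as_group_index(partition, map$p)
  pk <- length(map$keep)
  b1 <- beta[map$m + seq_len(pk)]           # first genetic slot
  b2 <- beta[map$m + pk + seq_len(pk)]      # second genetic slot
  borig <- ifelse(map$swap, b2, b1)
  bknock <- ifelse(map$swap, b1, b2)
  To <- rep(0, length(g))
  Tk <- rep(0, length(g))
  To[map$keep] <- abs(borig)
  Tk[map$keep] <- abs(bknock)
  L <- max(g)
  list(T = as.numeric(rowsum(To, g, reorder = TRUE)),
       T_tilde = as.numeric(rowsum(Tk, g, reorder = TRUE)))
}

#' Antisymmetric test statistics
#'
#' Default contrast `W = T - T_tilde`; any antisymmetric combination of the
#' two importance vectors may be plugged in.
#'
#' @param T,T_tilde importance vectors of equal length.
#' @param fun antisymmetric function of `(T, T_tilde)`; the default is the
#'   difference.
#' @return numeric vector `W`.
#' @export
compute_W <- function(T, T_tilde, fun = `-`) {
  stopifnot(length(T) == length(T_tilde))
  fun(T, T_tilde)
}

#' Importance statistics for one resolution
#'
#' Convenience wrapper chaining [build_design()], [fit_sparse_regression()],
#' [group_importance()] and [compute_W()].
#'
#' @inheritParams build_design
#' @inheritParams fit_sparse_regression
#' @param partition a [new_partition()].
#' @return list with `T`, `T_tilde`, `W`, `lambda_cv` and `beta`.
#' @export
importance_stats <- function(Z, X, Xt, y, partition, family = "gaussian",
                             nfolds = 10, fold_seed = 1, seed = 1) {
  dsg <- build_design(Z, X, Xt, seed = seed)
  fit <- fit_sparse_regression(dsg, y, family = family, nfolds = nfolds,
                               fold_seed = fold_seed)
  gi <- group_importance(fit$beta, dsg$map, partition)
  W <- compute_W(gi$T, gi$T_tilde)
  list(T = gi$T, T_tilde = gi$T_tilde, W = W, lambda_cv = fit$lambda_cv,
       beta = fit$beta)
}
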