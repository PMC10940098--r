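#' Z-score normalization fitted on training data
#'
#' Centers and scales every feature column to mean 0, SD 1 (population SD)
#' on the training matrix and applies the same transform to `apply_to`.
#' Constant columns carry no information and break scale-sensitive selection
#' (LASSO, SVM), so they are dropped with a warning.
#'
#' @param train numeric matrix/data.frame with named columns, >= 2 rows.
#' @param apply_to optional matrix with the same columns.
#' @return list with `train`, `apply` (or NULL), `center`, `scale`,
#'   `dropped` (names of constant columns).
#' @export
zscore_fit_apply <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need >= 2 training rows")
  ctr <- colMeans(train)
  scl <- sqrt(colMeans(sweep(train, 2, ctr)^2))
  dropped <- colnames(train)[scl == 0]
  if (length(dropped)) {
    warning("dropping ", length(dropped), " constant feature(s)")
    keep <- scl > 0
    train <- train[, keep, drop = FALSE]
    ctr <- ctr[keep]; scl <- scl[keep]
    if (!is.null(apply_to)) apply_to <- as.matrix(apply_to)[, keep, drop = FALSE]
  }
  zt <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  za <- if (!is.null(apply_to))
    sweep(sweep(as.matrix(apply_to)[, colnames(train), drop = FALSE], 2, ctr), 2, scl, "/")
  list(train = zt, apply = za, center = ctr, scale = scl, dropped = dropped)
}

# plug-in mutual information between two discrete vectors
mi_discrete <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  idx <- tab > 0
  sum(tab[idx] * log(tab[idx] / outer(pa, pb)[idx]))
}

# equal-frequency binning into (at most) `bins` levels; features with few
# distinct values keep their own levels (quantile breaks would collapse them)
ef_bin <- function(x, bins = 3) {
  ux <- sort(unique(x))
  if (length(ux) <= bins) return(match(x, ux))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1), names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  .bincode(x, br, include.lowest = TRUE)
}

#' Greedy mRMR feature ranking
#'
#' Maximum-relevance minimum-redundancy ranking with the quotient criterion:
#' the first feature maximizes MI(feature; label); each subsequent pick
#' maximizes MI(feature; label) / mean MI(feature; already-selected). Mutual
#' information is the plug-in estimate after 3-bin equal-frequency
#' discretization of the features, which makes the ranking deterministic.
#'
#' @param features numeric matrix with named columns.
#' @param labels binary vector (both classes present).
#' @param k number of features to rank.
#' @return Character vector of `k` feature names in rank order.
#' @export
mrmr_rank <- function(features, labels, k = 30) {
  features <- as.matrix(features)
  if (length(unique(labels)) < 2) stop("labels must contain both classes")
  k <- min(k, ncol(features))
  binned <- apply(features, 2, ef_bin)
  rel <- apply(binned, 2, mi_discrete, b = labels)
  nm <- colnames(features)
  selected <- character(0)
  remaining <- nm
  # pairwise feature MI cached lazily
  mi_cache <- matrix(NA_real_, ncol(features), ncol(features),
                     dimnames = list(nm, nm))
  for (step in seq_len(k)) {
    if (step == 1) {
      pick <- remaining[which.max(rel[remaining])]
    } else {
      score <- vapply(remaining, function(f) {
        red <- vapply(selected, function(s) {
          if (is.na(mi_cache[f, s])) {
            v <- mi_discrete(binned[, f], binned[, s])
            mi_cache[f, s] <<- v; mi_cache[s, f] <<- v
          }
          mi_cache[f, s]
        }, numeric(1))
        rel[f] / max(mean(red), 1e-12)
      }, numeric(1))
      pick <- remaining[which.max(score)]
    }
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Rank-ordered collinearity pruning
#'
#' Traverses the features in rank order and drops any feature whose absolute
#' Pearson correlation with an already-kept feature exceeds `r_max`.
#'
#' @param features numeric matrix with named columns.
#' @param ranked character vector of feature names (subset of columns), in
#'   priority order.
#' @param r_max correlation threshold (default 0.9).
#' @return Surviving feature names, in rank order.
#' @export
collinearity_filter <- function(features, ranked, r_max = 0.9) {
  features <- as.matrix(features)
  stopifnot(all(ranked %in% colnames(features)))
  kept <- character(0)
  for (f in ranked) {
    if (length(kept) == 0) { kept <- f; next }
    r <- abs(cor(features[, f], features[, kept, drop = FALSE]))
    if (all(r <= r_max, na.rm = TRUE)) kept <- c(kept, f)
  }
  kept
}

# stratified fold ids, seeded
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

#' LASSO-penalized logistic feature selection
#'
#' L1-penalized logistic regression over a 100-point log-spaced penalty
#' path; the penalty is chosen to maximize the mean cross-validated AUC over
#' seeded stratified folds, and the nonzero-coefficient features at that
#' penalty are returned. With `lambda` supplied the model is fitted at that
#' fixed penalty without cross-validation.
#'
#' @param features numeric matrix with named columns (already normalized).
#' @param labels binary vector; each class needs at least `folds` members.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param lambda optional fixed penalty.
#' @return Character vector of selected feature names (possibly empty, with
#'   a warning).
#' @export
lasso_select <- function(features, labels, folds = 5, seed = 1, lambda = NULL) {
  x <- as.matrix(features)
  y <- as.numeric(labels)
  if (min(table(y)) < folds) stop("need >= `folds` samples per class")
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "binomial", standardize = FALSE,
                          lambda = lambda)
    cf <- as.matrix(coef(fit))[-1, 1]
    return(names(cf)[cf != 0])
  }
  foldid <- stratified_folds(y, folds, seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", type.measure = "auc",
                          foldid = foldid, standardize = FALSE, nlambda = 100)
  cf <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
  sel <- names(cf)[cf != 0]
  if (length(sel) == 0) warning("LASSO selected no features")
  sel
}

# AUC of linear-SVM decision values for the positive class
svm_cv_auc <- function(x, y, feats, foldid) {
  aucs <- vapply(sort(unique(foldid)), function(f) {
    tr <- foldid != f
    fit <- e1071::svm(x[tr, feats, drop = FALSE], y[tr], kernel = "linear",
                      cost = 1, scale = FALSE)
    dv <- attr(predict(fit, x[!tr, feats, drop = FALSE],
                       decision.values = TRUE), "decision.values")
    sc <- if (startsWith(colnames(dv)[1], "1/")) dv[, 1] else -dv[, 1]
    roc_auc(sc, as.numeric(as.character(y[!tr])))$auc
  }, numeric(1))
  mean(aucs)
}

#' SVM-RFE feature selection
#'
#' Recursive feature elimination with a linear-kernel SVM (cost 1): at each
#' step the 10% of features with smallest squared weight are removed. The
#' elimination order is computed on the full training data; the final subset
#' size is the one maximizing the mean cross-validated AUC over seeded
#' stratified folds (smallest size on ties).
#'
#' @inheritParams lasso_select
#' @return Character vector of selected feature names.
#' @export
svmrfe_select <- function(features, labels, folds = 5, seed = 1) {
  x <- as.matrix(features)
  yf <- factor(labels, levels = sort(unique(labels)))
  if (ncol(x) == 1) return(colnames(x))
  if (min(table(yf)) < folds) stop("need >= `folds` samples per class")

  feats <- colnames(x)
  subsets <- list(feats)
  while (length(feats) > 1) {
    fit <- e1071::svm(x[, feats, drop = FALSE], yf, kernel = "linear",
                      cost = 1, scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)[1, ]
    ndrop <- max(1L, floor(0.1 * length(feats)))
    feats <- feats[order(w[feats]^2, decreasing = TRUE)][seq_len(length(feats) - ndrop)]
    subsets <- c(subsets, list(feats))
  }
  foldid <- stratified_folds(as.numeric(as.character(yf)), folds, seed)
  aucs <- vapply(subsets, svm_cv_auc, numeric(1), x = x, y = yf, foldid = foldid)
  best <- max(aucs)
  sizes <- lengths(subsets)
  cand <- which(aucs >= best - 1e-12)
  subsets[[cand[which.min(sizes[cand])]]]
}
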