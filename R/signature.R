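#' Fit a radiomics signature by multivariate logistic regression
#'
#' Unpenalized logistic regression of the immune-status label on the overlap
#' features; the signature score is the linear predictor (log-odds,
#' intercept included -- a pure location shift that the Youden cutoff later
#' absorbs). Perfect separation is detected and the model refitted with a
#' small ridge stabilizer (1e-6), flagged in the result.
#'
#' @param features numeric matrix with named columns (normalized scale).
#' @param labels binary vector.
#' @param overlap character vector of feature names to use.
#' @param target `"lymphoid"` or `"myeloid"` (metadata only).
#' @return A `signature_model`: list with `features`, `coef`, `intercept`,
#'   `target`, `flags`; normalization and cutoff are attached by
#'   [train_signature()].
#' @export
fit_signature <- function(features, labels, overlap, target = "lymphoid") {
  x <- as.matrix(features)[, overlap, drop = FALSE]
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("both classes required")
  if (length(overlap) == 0) stop("empty feature set")
  flags <- character(0)
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  # separation: IRLS walks the coefficients out until fitted probabilities
  # saturate; on normalized features legitimate log-odds slopes stay small
  sep <- !fit$converged || anyNA(coef(fit)) ||
    any(abs(coef(fit)) > 15, na.rm = TRUE)
  if (sep) {
    flags <- "ridge_stabilized"
    cf <- ridge_logistic(x, y, lambda = 1e-6)
  } else {
    cf <- coef(fit)
  }
  structure(list(target = target, features = overlap,
                 coef = setNames(cf[-1], overlap), intercept = unname(cf[1]),
                 center = NULL, scale = NULL, cutoff = NULL,
                 flags = flags),
            class = "signature_model")
}

# Newton-Raphson logistic regression with an L2 penalty on the slopes
ridge_logistic <- function(x, y, lambda = 1e-6, maxit = 100, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(x))))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    g <- crossprod(X, y - p) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Score new data with a signature model
#'
#' @param model a `signature_model`.
#' @param features matrix/data.frame containing the model's feature columns
#'   on the raw (unnormalized) scale.
#' @return data.frame with `score` and, when the model has a cutoff,
#'   `status` (`"high"` iff score >= cutoff).
#' @export
predict_signature <- function(model, features) {
  stopifnot(inherits(model, "signature_model"))
  x <- as.matrix(as.data.frame(features)[, model$features, drop = FALSE])
  if (!is.null(model$center))
    x <- sweep(sweep(x, 2, model$center[model$features]), 2,
               model$scale[model$features], "/")
  score <- drop(model$intercept + x %*% model$coef)
  out <- data.frame(score = score)
  if (!is.null(model$cutoff))
    out$status <- ifelse(score >= model$cutoff, "high", "low")
  out
}

#' Youden-index score cutoff
#'
#' The observed score threshold maximizing sensitivity + specificity - 1
#' under the classification rule "high iff score >= cutoff"; ties are broken
#' toward the smallest maximizing threshold.
#'
#' @param scores numeric vector.
#' @param labels binary vector; both classes required.
#' @return list with `cutoff` and `j` (the attained Youden index).
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) stop("both classes required")
  thr <- sort(unique(scores))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  j <- vapply(thr, function(t) {
    pred <- scores >= t
    sum(pred & labels == 1) / npos + sum(!pred & labels == 0) / nneg - 1
  }, numeric(1))
  best <- max(j)
  list(cutoff = thr[which(j >= best - 1e-12)[1]], j = best)
}

#' Quantile-based alternative cutoffs
#'
#' Median, upper-quartile and lower-quartile cutoffs (linear-interpolation
#' empirical quantiles), reported alongside the Youden cutoff for
#' sensitivity analyses of the dichotomization rule.
#'
#' @param scores numeric vector.
#' @export
alternative_cutoffs <- function(scores) {
  if (length(scores) == 0) stop("empty scores")
  q <- quantile(scores, c(0.5, 0.75, 0.25), names = FALSE)
  c(median = q[1], upper_quartile = q[2], lower_quartile = q[3])
}

#' Radiomics immune subtype from the status pair
#'
#' Combines the dichotomized lymphoid (LRS) and myeloid (MRS) radiomics
#' statuses into the four immune subtypes: 1 = (-/-), 2 = (+/-), 3 = (-/+),
#' 4 = (+/+), with LRS first and MRS second.
#'
#' @param lrs_status,mrs_status character vectors `"low"`/`"high"`.
#' @return Integer vector in 1-4.
#' @export
assign_subtype <- function(lrs_status, mrs_status) {
  if (length(lrs_status) != length(mrs_status)) stop("status lengths differ")
  ok <- c("low", "high")
  if (anyNA(lrs_status) || anyNA(mrs_status) ||
      !all(lrs_status %in% ok) || !all(mrs_status %in% ok))
    stop("undefined status")
  1L + (lrs_status == "high") + 2L * (mrs_status == "high")
}

#' Train a radiomics signature through the full selection cascade
#'
#' The construction pipeline for one imaging biomarker (LRS or MRS):
#' optional ICC reproducibility filter, z-score normalization, greedy mRMR
#' ranking (top `k_mrmr`), rank-ordered collinearity pruning, LASSO and
#' SVM-RFE selection (both with seeded stratified 5-fold CV) whose overlap
#' feeds a multivariate logistic model, and a Youden cutoff on the training
#' scores. If the overlap holds fewer than 2 features the LASSO set is used
#' instead (flagged).
#'
#' @param features data.frame or matrix of radiomics features (raw scale),
#'   named columns.
#' @param labels binary immune-status vector (1 = high).
#' @param target `"lymphoid"` or `"myeloid"`.
#' @param icc_pass optional character vector of reproducible feature names.
#' @param k_mrmr number of features retained by mRMR (default 30).
#' @param r_max collinearity threshold (default 0.9).
#' @param folds,seed CV geometry.
#' @return list with `model` (a `signature_model` carrying normalization and
#'   cutoff) and `selection` (stage-by-stage surviving feature names:
#'   `icc_pass`, `mrmr_top`, `decorrelated`, `lasso_set`, `svmrfe_set`,
#'   `overlap_set`).
#' @export
train_signature <- function(features, labels, target = c("lymphoid", "myeloid"),
                            icc_pass = NULL, k_mrmr = 30, r_max = 0.9,
                            folds = 5, seed = 1) {
  target <- match.arg(target)
  features <- as.data.frame(features)
  num <- vapply(features, is.numeric, logical(1))
  X <- as.matrix(features[, num, drop = FALSE])
  y <- as.numeric(labels)
  if (!is.null(icc_pass)) X <- X[, intersect(colnames(X), icc_pass), drop = FALSE]
  z <- suppressWarnings(zscore_fit_apply(X))
  Xz <- z$train

  mrmr_top <- mrmr_rank(Xz, y, k = k_mrmr)
  decor <- collinearity_filter(Xz, mrmr_top, r_max = r_max)
  lasso_set <- lasso_select(Xz[, decor, drop = FALSE], y, folds = folds, seed = seed)
  svm_set <- svmrfe_select(Xz[, decor, drop = FALSE], y, folds = folds, seed = seed)
  overlap <- intersect(lasso_set, svm_set)
  flags <- character(0)
  if (length(overlap) < 2) {
    flags <- c(flags, "overlap_fallback_lasso")
    overlap <- lasso_set
  }
  if (length(overlap) < 1) {
    flags <- c(flags, "fallback_mrmr_top2")
    overlap <- head(decor, 2)
  }
  model <- fit_signature(Xz, y, overlap, target = target)
  model$flags <- c(model$flags, flags)
  model$center <- z$center
  model$scale <- z$scale
  sc <- predict_signature(model,
                          as.data.frame(X)[, model$features, drop = FALSE])$score
  yj <- youden_cutoff(sc, y)
  model$cutoff <- yj$cutoff
  model$seed <- seed
  model$folds <- folds
  list(model = model,
       selection = list(icc_pass = if (is.null(icc_pass)) colnames(X) else icc_pass,
                        mrmr_top = mrmr_top, decorrelated = decor,
                        lasso_set = lasso_set, svmrfe_set = svm_set,
                        overlap_set = intersect(lasso_set, svm_set)))
}

#' Serialize a signature model to JSON (and back)
#'
#' @param model a `signature_model`.
#' @param path file path.
#' @export
write_signature_json <- function(model, path) {
  obj <- model
  class(obj) <- NULL
  obj$center <- as.list(obj$center)
  obj$scale <- as.list(obj$scale)
  obj$coef <- as.list(obj$coef)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coef <- unlist(obj$coef)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  class(obj) <- "signature_model"
  obj
}
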