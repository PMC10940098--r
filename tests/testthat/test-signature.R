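test_that("z-scoring uses population SD and freezes training parameters", {
  z <- zscore_fit_apply(matrix(c(1, 2, 3), ncol = 1,
                               dimnames = list(NULL, "f")))
  expect_equal(z$train[, "f"], c(-1.224745, 0, 1.224745), tolerance = 1e-6)

  tr <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  z2 <- zscore_fit_apply(tr, apply_to = tr)
  expect_equal(z2$train, z2$apply)

  tr3 <- cbind(tr, const = 5)
  expect_warning(z3 <- zscore_fit_apply(tr3), "constant")
  expect_false("const" %in% colnames(z3$train))
  expect_equal(z3$dropped, "const")
})

test_that("mRMR ranks a label-identical feature first and penalizes duplicates", {
  set.seed(51)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X1 <- cbind(exact = y + 0, noise1 = rnorm(n), weak = y + rnorm(n, 0, 2),
              noise2 = rnorm(n))
  expect_equal(mrmr_rank(X1, y, k = 4)[1], "exact")

  # a duplicate of the top informative feature scores relevance/H(top) < 1
  # under the quotient criterion and is pushed behind other informative
  # features
  set.seed(151)
  f1 <- y + rnorm(n, 0, 0.3)
  X2 <- cbind(best = f1, dup = f1 + rnorm(n, 0, 1e-6),
              second = y + rnorm(n, 0, 0.6), noise = rnorm(n))
  r2 <- mrmr_rank(X2, y, k = 4)
  expect_true(r2[1] %in% c("best", "dup"))
  expect_false(r2[2] %in% c("best", "dup"))
})

test_that("mRMR equals an exhaustive greedy evaluation of the quotient criterion", {
  set.seed(52)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(f1 = y + rnorm(n, 0, 0.5), f2 = y + rnorm(n, 0, 0.5),
             f3 = rnorm(n), f4 = rnorm(n), f5 = y + rnorm(n, 0, 0.3))
  X[, "f2"] <- X[, "f5"] + rnorm(n, 0, 0.01)  # near-duplicate

  # independent oracle: same criterion evaluated by direct exhaustive search
  bin3 <- function(x) {
    br <- unique(quantile(x, c(0, 1/3, 2/3, 1), names = FALSE))
    if (length(br) < 2) rep(1L, length(x)) else .bincode(x, br, include.lowest = TRUE)
  }
  mi <- function(a, b) {
    tt <- table(a, b) / length(a)
    pa <- rowSums(tt); pb <- colSums(tt)
    s <- 0
    for (i in seq_along(pa)) for (j in seq_along(pb))
      if (tt[i, j] > 0) s <- s + tt[i, j] * log(tt[i, j] / (pa[i] * pb[j]))
    s
  }
  B <- apply(X, 2, bin3)
  rel <- apply(B, 2, mi, b = y)
  sel <- names(which.max(rel))
  remaining <- setdiff(colnames(X), sel)
  while (length(remaining)) {
    sc <- sapply(remaining, function(f)
      rel[[f]] / max(mean(sapply(sel, function(s) mi(B[, f], B[, s]))), 1e-12))
    sel <- c(sel, names(which.max(sc)))
    remaining <- setdiff(remaining, sel)
  }
  expect_equal(mrmr_rank(X, y, k = 5), sel)
})

test_that("collinearity pruning drops exactly the lower-ranked correlated member", {
  set.seed(53)
  n <- 50
  a <- rnorm(n)
  X <- cbind(a = a, b = rnorm(n), c = a + rnorm(n, 0, 0.1), d = rnorm(n))
  stopifnot(abs(cor(X[, "a"], X[, "c"])) > 0.95)
  kept <- collinearity_filter(X, c("a", "b", "c", "d"), r_max = 0.9)
  expect_equal(kept, c("a", "b", "d"))

  # identical columns: lower-ranked dropped
  X2 <- cbind(p = a, q = a)
  expect_equal(collinearity_filter(X2, c("p", "q")), "p")

  # all weakly correlated: all kept
  X3 <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  expect_equal(sort(collinearity_filter(X3, letters[1:4])), letters[1:4])
})

test_that("LASSO respects the null-gradient entry threshold and full shrinkage", {
  set.seed(54)
  n <- 200
  X <- scale(matrix(rnorm(n * 4), n, 4))
  colnames(X) <- paste0("f", 1:4)
  eta <- 1.5 * X[, 1] + 0.7 * X[, 2]
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  g <- abs(crossprod(X, y - mean(y))) / n  # KKT entry gradients at the null
  ord <- order(g, decreasing = TRUE)
  # penalty above the largest gradient: empty selection
  expect_length(lasso_select(X, y, lambda = 1.05 * max(g)), 0)
  # penalty just below the largest gradient: exactly the top feature enters
  sel <- lasso_select(X, y, lambda = 0.97 * max(g))
  expect_equal(sel, colnames(X)[ord[1]])
})

test_that("CV LASSO recovers a planted signal and is seed-deterministic", {
  set.seed(55)
  n <- 300
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, sprintf("f%02d", 1:30)))
  eta <- X[, 1] + X[, 2] + X[, 3]
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  s1 <- lasso_select(X, y, seed = 7)
  s2 <- lasso_select(X, y, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(c("f01", "f02", "f03") %in% s1))
})

test_that("SVM-RFE keeps a separating feature, is deterministic, and matches a re-fit oracle", {
  set.seed(56)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sep = y + rnorm(n, 0, 0.05), n1 = rnorm(n), n2 = rnorm(n),
             n3 = rnorm(n))
  s1 <- svmrfe_select(X, y, seed = 3)
  s2 <- svmrfe_select(X, y, seed = 3)
  expect_identical(s1, s2)
  expect_true("sep" %in% s1)

  # elimination order oracle: full e1071 re-fit dropping the smallest weight
  feats <- colnames(X)
  order_oracle <- character(0)
  yf <- factor(y)
  while (length(feats) > 1) {
    fit <- e1071::svm(X[, feats, drop = FALSE], yf, kernel = "linear",
                      cost = 1, scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)[1, feats]
    drop_f <- feats[which.min(w^2)]
    order_oracle <- c(order_oracle, drop_f)
    feats <- setdiff(feats, drop_f)
  }
  # the last feature standing must agree with a 1-feature-subset run
  expect_equal(feats, "sep")
  expect_identical(svmrfe_select(X[, "sep", drop = FALSE], y), "sep")
})

test_that("logistic signature fit matches an independent Newton-Raphson oracle", {
  x <- matrix(rep(c(-1, 1), each = 50), ncol = 1, dimnames = list(NULL, "f"))
  y <- rep(c(0, 1), each = 50)
  # add a little overlap so the MLE exists
  y[c(1, 51)] <- c(1, 0)
  m <- fit_signature(x, y, "f")

  # hand IRLS
  beta <- c(0, 0)
  X <- cbind(1, x[, 1])
  for (it in 1:50) {
    p <- 1 / (1 + exp(-X %*% beta))
    W <- as.numeric(p * (1 - p))
    beta <- beta + solve(t(X) %*% (X * W), t(X) %*% (y - p))[, 1]
  }
  expect_lt(max(abs(c(m$intercept, m$coef) - beta)), 1e-6)

  # perfect separation triggers the ridge-stabilized path
  y2 <- rep(c(0, 1), each = 50)
  m2 <- fit_signature(x, y2, "f")
  expect_true("ridge_stabilized" %in% m2$flags)
  expect_true(all(is.finite(c(m2$intercept, m2$coef))))
})

test_that("Youden cutoff equals the exhaustive scan and breaks ties low", {
  y1 <- youden_cutoff(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(y1$j, 1)
  expect_equal(y1$cutoff, 1)

  sc <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  lb <- c(0, 0, 1, 0, 1, 1)
  y2 <- youden_cutoff(sc, lb)
  o2 <- oracle_youden(sc, lb)
  expect_equal(y2$cutoff, o2$cutoff)
  expect_equal(y2$cutoff, 0.3)

  set.seed(57)
  for (rep in 1:20) {
    s <- round(rnorm(40), 1)  # force ties
    l <- rbinom(40, 1, 0.5)
    if (length(unique(l)) < 2) next
    got <- youden_cutoff(s, l)
    want <- oracle_youden(s, l)
    expect_equal(got$j, want$j, tolerance = 1e-12)
    expect_equal(got$cutoff, want$cutoff)
  }
})

test_that("subtype mapping follows the (LRS, MRS) convention", {
  expect_equal(assign_subtype("low", "low"), 1L)
  expect_equal(assign_subtype("high", "low"), 2L)
  expect_equal(assign_subtype("low", "high"), 3L)
  expect_equal(assign_subtype("high", "high"), 4L)
  expect_equal(assign_subtype(c("low", "high"), c("high", "high")), c(3L, 4L))
  expect_error(assign_subtype("hi", "low"), "undefined")
  expect_error(assign_subtype(NA_character_, "low"), "undefined")
})

test_that("rank-formulation AUC matches pair enumeration and the null", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1)
  set.seed(58)
  sc <- rnorm(2000)
  lb <- sample(rep(0:1, 1000))
  expect_lt(abs(roc_auc(sc, lb)$auc - 0.5), 0.03)
})

test_that("DeLong AUC machinery agrees with pROC", {
  set.seed(59)
  y <- rbinom(150, 1, 0.4)
  s <- y + rnorm(150)
  got <- roc_auc(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(got$ci, ci[c(1, 3)], tolerance = 1e-6)

  s2 <- y + rnorm(150, 0, 2)
  gotc <- compare_auc(s, s2, y)
  refc <- pROC::roc.test(pROC::roc(y, s, quiet = TRUE, direction = "<"),
                         pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                         method = "delong", paired = TRUE)
  expect_equal(gotc$p, refc$p.value, tolerance = 1e-9)
})

test_that("alternative cutoffs are linear-interpolation quantiles", {
  expect_equal(unname(alternative_cutoffs(c(1, 2, 3, 4, 5))["median"]), 3)
  expect_equal(unname(alternative_cutoffs(c(1, 2, 3, 4))["upper_quartile"]), 3.25)
  cc <- alternative_cutoffs(rep(2, 10))
  expect_true(all(cc == 2))
})

test_that("the cascade is contained, deterministic, and round-trips through JSON", {
  set.seed(60)
  n <- 80
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, sprintf("g%02d", 1:12)))
  eta <- 1.2 * X[, 1] - 1.2 * X[, 2]
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  tr1 <- suppressWarnings(train_signature(X, y, target = "lymphoid", seed = 4))
  tr2 <- suppressWarnings(train_signature(X, y, target = "lymphoid", seed = 4))
  expect_identical(tr1$model$coef, tr2$model$coef)
  expect_identical(tr1$selection, tr2$selection)

  sel <- tr1$selection
  expect_true(all(sel$decorrelated %in% sel$mrmr_top))
  expect_true(all(sel$lasso_set %in% sel$decorrelated))
  expect_true(all(sel$svmrfe_set %in% sel$decorrelated))
  expect_setequal(sel$overlap_set, intersect(sel$lasso_set, sel$svmrfe_set))

  sc <- predict_signature(tr1$model, X)
  expect_true(all(sc$status == ifelse(sc$score >= tr1$model$cutoff, "high", "low")))

  # signature beats every single feature on training data
  sig_auc <- roc_auc(sc$score, y)$auc
  single <- apply(X, 2, function(col) roc_auc(col, y)$auc)
  expect_gte(sig_auc, max(pmax(single, 1 - single)) - 1e-9)

  path <- tempfile(fileext = ".json")
  write_signature_json(tr1$model, path)
  back <- read_signature_json(path)
  expect_equal(predict_signature(back, X)$score, sc$score, tolerance = 1e-12)
  unlink(path)
})
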