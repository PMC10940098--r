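test_that("product-limit estimator matches hand lifetables", {
  # no events: survival stays at 1
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_equal(km0$surv_at(c(1, 5, 10)), c(1, 1, 1))

  # all events: empirical survival
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$steps$surv, c(2 / 3, 1 / 3, 0))

  # worked 5-subject table with censoring
  km2 <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0))
  expect_equal(km2$surv_at(3), (4 / 5) * (2 / 3), tolerance = 1e-12)
  expect_equal(km2$surv_at(3), oracle_km(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0), 3))

  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank matches the hypergeometric bookkeeping oracle", {
  # identical groups: statistic 0
  lr0 <- logrank_test(rep(c(1, 2, 3, 4, 5), 2), rep(c(1, 0, 1, 1, 0), 2),
                      rep(1:2, each = 5))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  time <- c(1, 3, 4, 6, 8, 2, 5, 7, 9, 10)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  group <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chisq, oracle_logrank(time, event, group), tolerance = 1e-10)
  expect_equal(lr$df, 1)
})

test_that("Cox coefficient matches a brute-force partial-likelihood scan", {
  d <- data.frame(time = c(2, 4, 5, 7, 9, 11),
                  event = c(1, 1, 1, 1, 1, 1),
                  x = c(1, 0, 1, 0, 1, 0))
  cf <- cox_fit(survival::Surv(time, event) ~ x, d)
  b_hat <- oracle_cox_grid(d$x, d$time, d$event)
  expect_lt(abs(cf$table$coef - b_hat), 2e-4)

  # null covariate at n = 1000 keeps the HR near 1
  d2 <- sim_surv(1000, 0, seed = 71)
  cf2 <- cox_fit(survival::Surv(time, event) ~ x, d2)
  expect_gt(cf2$table$hr, 0.85)
  expect_lt(cf2$table$hr, 1.18)

  expect_error(cox_fit(survival::Surv(c(1, 2), c(0, 0)) ~ c(1, 0),
                       data.frame()), class = "error")
})

test_that("PH verdict follows the printed decision rule and detects crossing hazards", {
  d <- sim_surv(300, log(2), seed = 72)
  ph <- ph_test(cox_fit(survival::Surv(time, event) ~ x, d))
  expect_equal(ph$verdict, if (ph$global_p < 0.05) "violated" else "valid")

  # crossing hazards: effect reverses sign at the median time
  set.seed(73)
  rej <- 0
  nrep <- 30
  for (r in seq_len(nrep)) {
    n <- 500
    x <- rbinom(n, 1, 0.5)
    # piecewise exponential: hazard ratio e^b before t0, e^-b after
    b <- 0.9; t0 <- log(2)
    u <- runif(n)
    rate1 <- exp(b * x)
    t1 <- -log(u) / rate1
    flip <- t1 > t0
    t1[flip] <- t0 - log(runif(sum(flip))) / exp(-b * x[flip])
    cens <- runif(n, 0, 4)
    d3 <- data.frame(time = pmin(t1, cens), event = as.integer(t1 <= cens), x = x)
    p <- ph_test(survival::coxph(survival::Surv(time, event) ~ x, d3))$global_p
    rej <- rej + (p < 0.05)
  }
  expect_gt(rej / nrep, 0.5)
})

test_that("Harrell's C matches the all-pairs audit and its limits", {
  time <- c(5, 4, 3, 2, 1)
  event <- rep(1, 5)
  risk <- c(1, 2, 3, 4, 5)  # higher risk -> earlier event
  expect_equal(concordance_index(risk, time, event), 1)
  expect_equal(concordance_index(-risk, time, event), 0)

  time2 <- c(1, 2, 3, 4, 5)
  event2 <- c(1, 0, 1, 1, 0)
  lp2 <- c(0.9, 0.1, 0.5, 0.5, 0.2)
  expect_equal(concordance_index(lp2, time2, event2),
               oracle_cindex(lp2, time2, event2))

  # binary no-censoring limit: C equals the ROC AUC
  set.seed(74)
  y <- rbinom(60, 1, 0.5)
  lp <- y + rnorm(60)
  expect_equal(concordance_index(lp, 2 - y, rep(1, 60)),
               roc_auc(lp, y)$auc, tolerance = 1e-12)

  expect_error(concordance_index(c(1, 2), c(5, 5), c(1, 1)), "usable")
})

test_that("nomogram points are an affine, rank-preserving transform of the risk", {
  d <- sim_surv(300, log(2), seed = 75)
  cf <- cox_fit(survival::Surv(time, event) ~ x, d)
  nm <- nomogram_model(cf, d)
  expect_equal(unname(nm$mapping$points_span), 100)
  expect_equal(concordance_index(nm$total_points(d), d$time, d$event),
               concordance_index(nm$lp(d), d$time, d$event))

  # two covariates with beta = (log 2, log 4) on unit ranges: 50 vs 100 points
  set.seed(76)
  n <- 400
  d2 <- data.frame(a = runif(n), b = runif(n))
  u <- runif(n)
  t_ev <- -log(u) / exp(log(2) * d2$a + log(4) * d2$b)
  d2$time <- pmin(t_ev, 3)
  d2$event <- as.integer(t_ev <= 3)
  fit2 <- survival::coxph(survival::Surv(time, event) ~ a + b, d2)
  fit2$coefficients <- c(a = log(2), b = log(4))  # exact betas, unit ranges
  d2r <- d2; d2r$a <- c(0, 1, rep(0.5, n - 2)); d2r$b <- c(0, 1, rep(0.5, n - 2))
  nm2 <- nomogram_model(fit2, d2r)
  spans <- setNames(nm2$mapping$points_span, nm2$mapping$term)
  expect_equal(unname(spans["b"]), 100)
  expect_equal(unname(spans["a"]), 50)
})

test_that("ORR tables reproduce printed-style rates and the chi-square oracle", {
  # 64 responders of 198 prints as 32.3%
  resp <- c(rep("PR", 50), rep("CR", 14), rep("SD", 70), rep("PD", 64))
  o <- orr_table(resp, rep("cohort1", 198))
  expect_equal(round(o$table$orr_pct, 1), 32.3)
  expect_equal(o$table$responders, 64)

  # zero responders
  o0 <- orr_table(rep("PD", 10), rep("g", 10))
  expect_equal(o0$table$orr_pct, 0)

  # 2x2 chi-square against the textbook expected-count formula
  resp2 <- c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 15))
  grp2 <- rep(c("a", "b"), each = 20)
  o2 <- orr_table(resp2, grp2)
  O <- matrix(c(10, 10, 15, 5), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(o2$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(o2$test, "chisq")

  # small table switches to Fisher
  o3 <- orr_table(c(rep(TRUE, 2), rep(FALSE, 4), rep(TRUE, 1), rep(FALSE, 5)),
                  rep(c("a", "b"), each = 6))
  expect_equal(o3$test, "fisher")
  expect_error(orr_table(c("CR", "XX"), c("a", "a")), "unknown")
})

test_that("paired DeLong comparison matches hand structural components", {
  # 8-point worked set
  y <- c(1, 1, 1, 0, 0, 0, 1, 0)
  a <- c(0.9, 0.8, 0.6, 0.55, 0.4, 0.3, 0.7, 0.65)
  b <- c(0.7, 0.9, 0.5, 0.6, 0.35, 0.45, 0.55, 0.8)
  got <- compare_auc(a, b, y)

  psi <- function(x, yv) (x > yv) + 0.5 * (x == yv)
  comp <- function(sc) {
    pos <- sc[y == 1]; neg <- sc[y == 0]
    v10 <- sapply(pos, function(x) mean(psi(x, neg)))
    v01 <- sapply(neg, function(x) mean(psi(pos, x)))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  ca <- comp(a); cb <- comp(b)
  m <- sum(y == 1); n <- sum(y == 0)
  v <- var(ca$v10 - cb$v10) / m + var(ca$v01 - cb$v01) / n
  z <- (ca$auc - cb$auc) / sqrt(v)
  expect_equal(got$delta, ca$auc - cb$auc, tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)

  # identical scores: no difference
  same <- compare_auc(a, a, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
})

test_that("nested logistic response models cannot lose training AUC", {
  set.seed(78)
  n <- 200
  cps <- exp(rnorm(n))
  lrs <- rnorm(n)
  mrs <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.3 * log(cps + 1) + 0.8 * lrs - 0.8 * mrs))
  base <- glm(y ~ cps, family = binomial())
  full <- glm(y ~ cps + lrs + mrs, family = binomial())
  auc_base <- roc_auc(predict(base), y)$auc
  auc_full <- roc_auc(predict(full), y)$auc
  expect_gte(auc_full, auc_base - 1e-9)
})

test_that("exact Shapley equals the linear closed form and obeys efficiency", {
  set.seed(79)
  X <- matrix(rnorm(60), 12, 5,
              dimnames = list(NULL, c("lrs", "mrs", "age", "sex", "stage")))
  beta <- c(2.1, -1.8, 0.3, 0, 0.1)
  pf <- function(M) drop(0.4 + M %*% beta)
  sh <- shapley_importance(pf, X)
  closed <- sweep(X, 2, colMeans(X)) %*% diag(beta)
  expect_lt(max(abs(sh$phi - closed)), 1e-10)
  # zero-coefficient feature gets zero attribution
  expect_true(all(abs(sh$phi[, "sex"]) < 1e-12))
  # efficiency: rows sum to f(x) - f(background mean)
  expect_lt(max(abs(rowSums(sh$phi) - (pf(X) - sh$base_value))), 1e-10)
  # global importance ranks the strong features first
  expect_equal(names(sort(sh$mean_abs, decreasing = TRUE))[1:2],
               c("lrs", "mrs"))

  big <- matrix(rnorm(32), 2, 16)
  expect_error(shapley_importance(function(M) rowSums(M), big), "sampling")

  # the seeded permutation estimator approximates the closed form
  sh2 <- shapley_importance(pf, X[1:3, ], background = X, mode = "sampling",
                            n_perm = 100, seed = 2)
  expect_lt(max(abs(sh2$phi - closed[1:3, ])), 0.2)
  sh3 <- shapley_importance(pf, X[1:3, ], background = X, mode = "sampling",
                            n_perm = 100, seed = 2)
  expect_identical(sh2$phi, sh3$phi)
})
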