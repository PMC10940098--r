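#' Kaplan-Meier estimate with Greenwood bands
#'
#' Product-limit estimator with right censoring via `survival::survfit`;
#' the 95% bands use the Greenwood variance. `surv_at` evaluates the step
#' function at arbitrary times.
#'
#' @param time positive event/censoring times (months).
#' @param event 0/1 event indicators.
#' @return list with `fit` (the survfit object), a tidy `steps` data.frame
#'   (`time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`) and the
#'   function `surv_at(t)`.
#' @export
km_estimate <- function(time, event) {
  if (any(time <= 0)) stop("survival times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "log")
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      lower = fit$lower, upper = fit$upper)
  surv_at <- function(t) {
    vapply(t, function(tt) {
      idx <- which(fit$time <= tt)
      if (length(idx) == 0) 1 else fit$surv[max(idx)]
    }, numeric(1))
  }
  list(fit = fit, steps = steps, surv_at = surv_at)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected log-rank statistic over the pooled event
#' times (`survival::survdiff`), df = number of groups - 1.
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels (>= 2 nonempty groups).
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need >= 2 nonempty groups")
  if (sum(event) == 0) stop("no events")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd_$n) - 1
  list(chisq = sd_$chisq, df = df, p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Breslow tie handling (Efron
#' available as an option), Wald confidence intervals, and a global
#' Schoenfeld proportional-hazards p value.
#'
#' @param formula a formula with a `survival::Surv` left side.
#' @param data data.frame.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list with `fit`, `table` (term, coef, hr, lower, upper, p),
#'   `loglik`, and `global_ph_p`.
#' @export
cox_fit <- function(formula, data, ties = "breslow") {
  fit <- survival::coxph(formula, data = data, ties = ties)
  fit$call$data <- data  # so downstream cox.zph/model.matrix re-evaluation works
  if (is.null(fit$coefficients) || anyNA(fit$coefficients))
    stop("Cox model did not produce finite coefficients")
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    lower = s$conf.int[, "lower .95"],
                    upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  gph <- tryCatch(ph_test(fit)$global_p, error = function(e) NA_real_)
  list(fit = fit, table = tab, loglik = fit$loglik[2], global_ph_p = gph)
}

#' Schoenfeld-residual proportional-hazards test
#'
#' Correlation test of the scaled Schoenfeld residuals against the
#' Kaplan-Meier transform of the event times (`survival::cox.zph`,
#' `transform = "km"`), with the printed decision rule: the PH assumption is
#' "violated" when the global p < 0.05 and "valid" otherwise.
#'
#' @param fit a `coxph` fit (or the list from [cox_fit()]).
#' @return list with `per_covariate` (data.frame of chisq/df/p), `global_p`
#'   and `verdict`.
#' @export
ph_test <- function(fit) {
  if (is.list(fit) && !inherits(fit, "coxph") && !is.null(fit$fit)) fit <- fit$fit
  zp <- survival::cox.zph(fit, transform = "km", global = TRUE)
  tab <- as.data.frame(zp$table)
  has_global <- "GLOBAL" %in% rownames(tab)  # absent for single-covariate fits
  global_p <- tab[if (has_global) "GLOBAL" else 1, "p"]
  list(per_covariate = tab[rownames(tab) != "GLOBAL", , drop = FALSE],
       global_p = global_p,
       verdict = if (global_p < 0.05) "violated" else "valid")
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs (the member with the earlier observed event time
#' must be an event) in which the higher-risk prediction had the earlier
#' event; predictor ties count 0.5. Computed by direct pair enumeration.
#'
#' @param lp linear predictor (higher = higher risk).
#' @param time,event survival data.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(lp, time, event) {
  n <- length(lp)
  stopifnot(length(time) == n, length(event) == n)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    cmp <- which(time > time[i] | (time == time[i] & event == 0))
    if (!length(cmp)) next
    den <- den + length(cmp)
    num <- num + sum(lp[i] > lp[cmp]) + 0.5 * sum(lp[i] == lp[cmp])
  }
  if (den == 0) stop("no usable pairs")
  num / den
}

#' Nomogram point mapping from a Cox model
#'
#' Converts a fitted multivariate Cox model into the usual 0-100 point
#' scale: each covariate's points are `100 * beta * (x - x_min) /
#' max_j(beta_j * range_j)`, so the covariate with the largest absolute
#' log-hazard span covers 0-100 and the total points are an affine,
#' rank-preserving transform of the linear predictor (identical C-index).
#'
#' @param fit a `coxph` fit (or [cox_fit()] result) on numeric covariates.
#' @param data the data.frame used for the fit.
#' @return list with `points_per_unit` table, `total_points(newdata)`
#'   function, and `lp(newdata)`.
#' @export
nomogram_model <- function(fit, data) {
  if (is.list(fit) && !inherits(fit, "coxph") && !is.null(fit$fit)) fit <- fit$fit
  beta <- coef(fit)
  cox_design <- function(d) {
    mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)), data = d)
    mm[, names(beta), drop = FALSE]
  }
  X <- cox_design(data)
  rng <- apply(X, 2, function(col) range(col))
  span <- abs(beta) * (rng[2, ] - rng[1, ])
  keep <- span > 0
  if (!any(keep)) stop("all covariates degenerate")
  scale_pts <- 100 / max(span[keep])
  ref <- ifelse(beta >= 0, rng[1, ], rng[2, ])  # point 0 at the lowest-risk end
  mapping <- data.frame(term = names(beta)[keep], beta = beta[keep],
                        ref = ref[keep],
                        points_span = (span * scale_pts)[keep], row.names = NULL)
  total_points <- function(newdata) {
    Xn <- cox_design(newdata)[, keep, drop = FALSE]
    drop(sweep(Xn, 2, ref[keep]) %*% (beta[keep] * scale_pts))
  }
  lp <- function(newdata) {
    drop(cox_design(newdata) %*% beta)
  }
  list(mapping = mapping, total_points = total_points, lp = lp,
       scale = scale_pts)
}
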