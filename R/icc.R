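#' Intraclass correlation for feature reproducibility
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC -- ICC(2,1)
#' in the Shrout-Fleiss taxonomy -- computed from the ANOVA mean squares of a
#' patients x raters rating matrix. This is the model used to screen features
#' for segmentation reproducibility; features are conventionally retained
#' when both inter- and intra-observer ICC reach `0.75`.
#'
#' @param ratings numeric matrix, patients in rows, raters/repeats in columns
#'   (>= 3 patients, >= 2 raters).
#' @return list with `icc` (estimate, possibly negative) and `flag`
#'   (`"zero_between_patient_variance"` when the estimate is degenerate).
#' @export
icc_single <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need >= 3 patients and >= 2 raters")
  grand <- mean(ratings)
  rmean <- rowMeans(ratings)
  cmean <- colMeans(ratings)
  msr <- k * sum((rmean - grand)^2) / (n - 1)
  msc <- n * sum((cmean - grand)^2) / (k - 1)
  mse <- sum((ratings - outer(rmean, rep(1, k)) -
                outer(rep(1, n), cmean) + grand)^2) / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (den <= 0 || (msr == 0 && mse == 0)) {
    return(list(icc = 0, flag = "zero_between_patient_variance"))
  }
  list(icc = (msr - mse) / den, flag = NULL)
}

#' ICC table over a feature set
#'
#' @param inter 3D array patients x raters x features (dimnames on the third
#'   margin name the features), ratings by different observers.
#' @param intra optional array of the same shape for repeat ratings by one
#'   observer.
#' @return data.frame with `feature`, `inter_observer_icc`,
#'   `intra_observer_icc` (NA when `intra` is absent) and `flag`.
#' @export
compute_icc <- function(inter, intra = NULL) {
  stopifnot(length(dim(inter)) == 3)
  nf <- dim(inter)[3]
  fnames <- dimnames(inter)[[3]]
  if (is.null(fnames)) fnames <- sprintf("feature%03d", seq_len(nf))
  one <- function(arr, f) icc_single(arr[, , f])
  inter_res <- lapply(seq_len(nf), one, arr = inter)
  intra_icc <- rep(NA_real_, nf)
  if (!is.null(intra)) {
    stopifnot(identical(dim(intra)[3], dim(inter)[3]))
    intra_icc <- vapply(seq_len(nf), function(f) icc_single(intra[, , f])$icc,
                        numeric(1))
  }
  data.frame(
    feature = fnames,
    inter_observer_icc = vapply(inter_res, `[[`, numeric(1), "icc"),
    intra_observer_icc = intra_icc,
    flag = vapply(inter_res, function(r) ifelse(is.null(r$flag), "", r$flag),
                  character(1)),
    stringsAsFactors = FALSE
  )
}

#' Names of features passing an ICC threshold
#'
#' @param icc_table output of [compute_icc()].
#' @param threshold minimum acceptable ICC (default 0.75).
#' @export
icc_filter <- function(icc_table, threshold = 0.75) {
  ok <- icc_table$inter_observer_icc >= threshold
  if (!all(is.na(icc_table$intra_observer_icc)))
    ok <- ok & icc_table$intra_observer_icc >= threshold
  icc_table$feature[ok]
}
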