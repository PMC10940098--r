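#' Median thresholds for IHC counts
#'
#' Fits the per marker-region median cell counts on a training cohort. The
#' medians are frozen after fitting and applied unchanged to validation
#' data: scoring never refits them. The median of an even-sized sample is
#' the midpoint of the two central values; counts are compared as reals so
#' fractional medians are handled.
#'
#' @param counts data.frame (or matrix) with columns `cd3_intra`, `cd3_peri`,
#'   `cd8_intra`, `cd8_peri`, `cd66b_intra`, `cd66b_peri`.
#' @return Named numeric vector of six medians, class `median_thresholds`.
#' @export
fit_medians <- function(counts) {
  counts <- as.data.frame(counts)
  need <- ihc_markers()
  if (!all(need %in% names(counts))) stop("missing count columns")
  if (nrow(counts) < 1) stop("need at least one training patient")
  structure(vapply(need, function(cn) median(as.numeric(counts[[cn]])),
                   numeric(1)),
            class = "median_thresholds")
}

ihc_markers <- function() {
  c("cd3_intra", "cd3_peri", "cd8_intra", "cd8_peri", "cd66b_intra", "cd66b_peri")
}

#' Score the lymphoid and myeloid immune context of one patient
#'
#' Each of the four lymphoid marker-region counts (CD3/CD8 x intra/peri)
#' contributes 1 point iff the count is greater than or equal to its
#' training median, giving the lymphoid immune score LIS in 0-4; the two
#' CD66b counts likewise give the myeloid immune score MIS in 0-2. Status
#' groups follow the printed rule: LIS low = 0-1, LIS high = 2-4; MIS low =
#' 0, MIS high = 1-2.
#'
#' @param counts named vector or one-row data.frame of the six counts.
#' @param thresholds a `median_thresholds` from [fit_medians()].
#' @return list with `lis`, `mis`, `lis_status`, `mis_status`.
#' @export
score_patient <- function(counts, thresholds) {
  stopifnot(inherits(thresholds, "median_thresholds"))
  counts <- unlist(counts)
  need <- ihc_markers()
  if (!all(need %in% names(counts)) || anyNA(counts[need]))
    stop("missing count")
  pts <- as.numeric(counts[need]) >= as.numeric(thresholds[need])
  lis <- sum(pts[1:4])
  mis <- sum(pts[5:6])
  list(lis = lis, mis = mis,
       lis_status = ifelse(lis <= 1, "low", "high"),
       mis_status = ifelse(mis == 0, "low", "high"))
}

#' Score a whole cohort
#'
#' Vectorized [score_patient()] over a data.frame of counts.
#'
#' @inheritParams fit_medians
#' @param thresholds a `median_thresholds` from [fit_medians()].
#' @return data.frame with `lis`, `mis`, `lis_status`, `mis_status`.
#' @export
score_cohort <- function(counts, thresholds) {
  stopifnot(inherits(thresholds, "median_thresholds"))
  counts <- as.data.frame(counts)
  need <- ihc_markers()
  if (!all(need %in% names(counts))) stop("missing count columns")
  if (anyNA(counts[need])) stop("missing count")
  pts <- sapply(need, function(cn) as.numeric(counts[[cn]]) >= thresholds[[cn]])
  pts <- matrix(pts, ncol = 6)
  lis <- rowSums(pts[, 1:4, drop = FALSE])
  mis <- rowSums(pts[, 5:6, drop = FALSE])
  data.frame(lis = lis, mis = mis,
             lis_status = ifelse(lis <= 1, "low", "high"),
             mis_status = ifelse(mis == 0, "low", "high"),
             stringsAsFactors = FALSE)
}
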