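#' Objective response rates by group
#'
#' ORR = (CR + PR) / n per group, with a Pearson chi-square test across the
#' groups; Fisher's exact test is substituted when any expected cell count
#' is below 5.
#'
#' @param response character vector of RECIST categories (`CR`, `PR`, `SD`,
#'   `PD`) or logical responder flags.
#' @param group group labels.
#' @return list with `table` (group, n, responders, orr_pct), `test`
#'   (`"chisq"` or `"fisher"`), `statistic` (chi-square, NA for Fisher) and
#'   `p`.
#' @export
orr_table <- function(response, group) {
  group <- as.factor(group)
  if (any(table(group) == 0)) stop("empty group")
  responder <- if (is.logical(response) || is.numeric(response)) {
    as.logical(response)
  } else {
    if (!all(response %in% c("CR", "PR", "SD", "PD"))) stop("unknown response category")
    response %in% c("CR", "PR")
  }
  tab <- table(group, factor(responder, levels = c(FALSE, TRUE)))
  out <- data.frame(group = rownames(tab),
                    n = as.integer(rowSums(tab)),
                    responders = as.integer(tab[, "TRUE"]),
                    row.names = NULL)
  out$orr_pct <- 100 * out$responders / out$n

  if (nrow(tab) < 2)
    return(list(table = out, test = NA_character_, statistic = NA_real_,
                p = NA_real_))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- fisher.test(tab, workspace = 2e6)
    list(table = out, test = "fisher", statistic = NA_real_, p = ft$p.value)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(table = out, test = "chisq",
         statistic = unname(ct$statistic), p = ct$p.value)
  }
}
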