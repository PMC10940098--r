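#!/usr/bin/env Rscript
# Step 4: prognostic value of the immune context and imaging biomarkers.
#
# Kaplan-Meier curves and log-rank tests by LIS/MIS status and by the four
# radiomics immune subtypes; multivariate Cox models adjusting for the
# clinicopathologic covariates, with Schoenfeld PH checks; and the nomogram
# point model (LRS + MRS + stage) with its C-index.

library(radioimmune)

tab <- read.csv("results/cohort_train.csv")
scores <- read.csv("results/scores_train.csv")
d <- merge(tab, scores, by = "patient_id")
d$stage_num <- match(d$stage, c("I", "II", "III", "IV"))

surv_obj <- survival::Surv(d$survival_time, d$event)

km_rows <- list()
for (grp in c("lis_status", "mis_status", "lrs_status", "mrs_status",
              "subtype_img")) {
  lr <- logrank_test(d$survival_time, d$event, d[[grp]])
  for (lev in sort(unique(d[[grp]]))) {
    idx <- d[[grp]] == lev
    km <- km_estimate(d$survival_time[idx], d$event[idx])
    km_rows[[length(km_rows) + 1]] <- data.frame(
      group = grp, level = lev, n = sum(idx),
      surv_36m = km$surv_at(36), surv_60m = km$surv_at(60),
      logrank_p = lr$p)
  }
  message(sprintf("%s: log-rank chisq = %.2f (df %d), p = %.2g",
                  grp, lr$chisq, lr$df, lr$p))
}
km_tab <- do.call(rbind, km_rows)
write.csv(km_tab, "results/km_by_group.csv", row.names = FALSE)

# multivariate Cox: imaging biomarkers adjusted for covariates
d$lrs_high <- as.numeric(d$lrs_status == "high")
d$mrs_high <- as.numeric(d$mrs_status == "high")
d$male <- as.numeric(d$sex == "male")
form <- survival::Surv(survival_time, event) ~ lrs_high + mrs_high + age +
  male + size_cm + cea_elevated + ca199_elevated + chemotherapy + stage_num
cf <- cox_fit(form, d)
write.csv(cf$table, "results/cox_multivariate.csv", row.names = FALSE)
ph <- ph_test(cf)
message(sprintf("multivariate Cox: LRS-high HR %.3f, MRS-high HR %.3f; PH %s (global p = %.2f)",
                cf$table$hr[cf$table$term == "lrs_high"],
                cf$table$hr[cf$table$term == "mrs_high"],
                ph$verdict, ph$global_p))

# nomogram: imaging biomarkers + stage
cf_nom <- cox_fit(survival::Surv(survival_time, event) ~ lrs + mrs + stage_num, d)
nm <- nomogram_model(cf_nom, d)
cidx <- concordance_index(nm$total_points(d), d$survival_time, d$event)
write.csv(nm$mapping, "results/nomogram_points.csv", row.names = FALSE)
message(sprintf("nomogram (LRS + MRS + stage): C-index %.3f", cidx))
cat(sprintf("%.4f\n", cidx), file = "results/nomogram_cindex.txt")
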