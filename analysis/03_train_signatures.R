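#!/usr/bin/env Rscript
# Step 3: construct the LRS and MRS imaging biomarkers.
#
# Runs the selection cascade (ICC filter -> mRMR top-30 -> collinearity
# pruning -> LASSO and SVM-RFE overlap -> multivariate logistic regression)
# against the IHC-derived LIS/MIS statuses of the training cohort, derives
# the Youden cutoffs (plus quantile alternatives), and reports training and
# immunotherapy-cohort AUCs.

library(radioimmune)

fm_train <- read.csv("results/features_train.csv", check.names = FALSE)
fm_io <- read.csv("results/features_immunotherapy.csv", check.names = FALSE)
tab_train <- read.csv("results/cohort_train.csv")
tab_io <- read.csv("results/cohort_immunotherapy.csv")
icc_pass <- readLines("results/icc_pass.txt")

train_one <- function(target, status) {
  y <- as.numeric(status == "high")
  tr <- suppressWarnings(train_signature(fm_train[, -1], y, target = target,
                                         icc_pass = icc_pass, seed = 42))
  sc_train <- predict_signature(tr$model, fm_train[, -1])
  sc_io <- predict_signature(tr$model, fm_io[, -1])
  auc_train <- roc_auc(sc_train$score, y)
  message(sprintf(
    "%s signature: %d features (%s), training AUC %.3f [%.3f, %.3f], Youden cutoff %.4f",
    target, length(tr$model$features),
    paste(tr$model$features, collapse = ", "),
    auc_train$auc, auc_train$ci[1], auc_train$ci[2], tr$model$cutoff))
  alt <- alternative_cutoffs(sc_train$score)
  message("  alternative cutoffs: median ", round(alt["median"], 4),
          ", quartiles ", round(alt["lower_quartile"], 4), " / ",
          round(alt["upper_quartile"], 4))
  list(tr = tr, sc_train = sc_train, sc_io = sc_io, auc = auc_train, alt = alt)
}

lrs <- train_one("lymphoid", tab_train$lis_status)
mrs <- train_one("myeloid", tab_train$mis_status)

write_signature_json(lrs$tr$model, "results/model_lrs.json")
write_signature_json(mrs$tr$model, "results/model_mrs.json")

scores <- data.frame(
  patient_id = fm_train$patient_id,
  lrs = lrs$sc_train$score, lrs_status = lrs$sc_train$status,
  mrs = mrs$sc_train$score, mrs_status = mrs$sc_train$status)
scores$subtype_img <- assign_subtype(scores$lrs_status, scores$mrs_status)
write.csv(scores, "results/scores_train.csv", row.names = FALSE)

scores_io <- data.frame(
  patient_id = fm_io$patient_id,
  lrs = lrs$sc_io$score, lrs_status = lrs$sc_io$status,
  mrs = mrs$sc_io$score, mrs_status = mrs$sc_io$status)
scores_io$subtype_img <- assign_subtype(scores_io$lrs_status, scores_io$mrs_status)
write.csv(scores_io, "results/scores_immunotherapy.csv", row.names = FALSE)

# selection audit trail
sel <- rbind(
  data.frame(target = "lymphoid", stage = names(lrs$tr$selection),
             n = lengths(lrs$tr$selection)),
  data.frame(target = "myeloid", stage = names(mrs$tr$selection),
             n = lengths(mrs$tr$selection)))
write.csv(sel, "results/selection_stages.csv", row.names = FALSE)
message("subtype distribution (training): ",
        paste(table(scores$subtype_img), collapse = " / "))
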