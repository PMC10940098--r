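#!/usr/bin/env Rscript
# Step 2: radiomics feature extraction.
#
# Resamples each phantom to 1 mm isotropic voxels, builds the 3 mm
# peritumoral band (2 mm dilation + 1 mm shrinkage), and extracts the
# 584-feature inventory (292 intratumoral + 292 peritumoral) per patient.
# A small repeat-segmentation experiment perturbs the masks to produce the
# ICC reproducibility table used to pre-filter features.

library(radioimmune)

train <- readRDS("scratch/patients_train.rds")
io <- readRDS("scratch/patients_io.rds")

message("extracting training cohort features ...")
fm_train <- extract_cohort_features(train, verbose = TRUE)
message("extracting immunotherapy cohort features ...")
fm_io <- extract_cohort_features(io, verbose = TRUE)
write.csv(fm_train, "results/features_train.csv", row.names = FALSE)
write.csv(fm_io, "results/features_immunotherapy.csv", row.names = FALSE)

# repeat-"segmentation" on a 20-patient subsample: a second rater is
# emulated by a one-voxel erosion/dilation jitter of the tumor mask
message("ICC reproducibility experiment ...")
set.seed(99)
sub <- train[1:20]
perturb_mask <- function(mask, grow) {
  d <- radioimmune:::distance_to_mask(mask)
  if (grow) {
    voxel_mask(mask$values | (d <= 1), mask$spacing, mask$origin)
  } else {
    bg <- voxel_mask(!mask$values, mask$spacing, mask$origin)
    din <- radioimmune:::distance_to_mask(bg)
    voxel_mask(mask$values & din > 1, mask$spacing, mask$origin)
  }
}
rater2 <- lapply(seq_along(sub), function(k) {
  p <- sub[[k]]
  p$tumor_mask <- perturb_mask(p$tumor_mask, grow = k %% 2 == 0)
  p
})
f1 <- as.matrix(extract_cohort_features(sub)[, -1])
f2 <- as.matrix(extract_cohort_features(rater2)[, -1])
ratings <- array(c(f1, f2), c(nrow(f1), ncol(f1), 2))
ratings <- aperm(ratings, c(1, 3, 2))
dimnames(ratings)[[3]] <- colnames(f1)
icc_tab <- compute_icc(ratings)
write.csv(icc_tab, "results/icc_table.csv", row.names = FALSE)
pass <- icc_filter(icc_tab, threshold = 0.75)
writeLines(pass, "results/icc_pass.txt")
message(length(pass), " of ", ncol(f1),
        " features pass the 0.75 ICC reproducibility threshold")
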