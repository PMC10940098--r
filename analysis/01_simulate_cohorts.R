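#!/usr/bin/env Rscript
# Step 1: simulate the study cohorts.
#
# Two synthetic cohorts stand in for the clinical data: a surgical training
# cohort (n = 242, survival follow-up, no RECIST response) and an
# immunotherapy cohort (n = 198, RECIST response + CPS). Phantom CT volumes
# are generated for both so the whole imaging pipeline can run. Cohort
# tables go to results/; the full patient objects (with image volumes) are
# cached under scratch/ for the later steps.

library(radioimmune)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg_train <- synthetic_config(n_patients = 242, seed = 20240101)
cfg_io <- synthetic_config(n_patients = 198, seed = 20240202,
                           immunotherapy_flag = TRUE)

message("simulating training cohort (n = ", cfg_train$n_patients, ") ...")
train <- generate_cohort(cfg_train)
message("simulating immunotherapy cohort (n = ", cfg_io$n_patients, ") ...")
io <- generate_cohort(cfg_io)

tab_train <- cohort_table(train)
tab_io <- cohort_table(io)
write.csv(tab_train, "results/cohort_train.csv", row.names = FALSE)
write.csv(tab_io, "results/cohort_immunotherapy.csv", row.names = FALSE)
saveRDS(train, "scratch/patients_train.rds")
saveRDS(io, "scratch/patients_io.rds")
saveRDS(list(train = cfg_train, io = cfg_io), "scratch/configs.rds")

message("training cohort: ",
        round(100 * mean(tab_train$lis_status == "high"), 1), "% LIS-high, ",
        round(100 * mean(tab_train$mis_status == "high"), 1), "% MIS-high, ",
        round(100 * mean(tab_train$event), 1), "% events")
message("immunotherapy cohort ORR: ",
        round(100 * mean(tab_io$response %in% c("CR", "PR")), 1), "%")
message("wrote results/cohort_train.csv and results/cohort_immunotherapy.csv")
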