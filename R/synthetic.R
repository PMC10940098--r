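#' Configuration for the synthetic phantom cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a latent bivariate-normal lymphoid/myeloid immune context per
#' patient, phantom CT tumors whose interior texture depends on the latents,
#' overdispersed IHC cell counts correlated with the latents, a
#' proportional-hazards survival process driven by the dichotomized immune
#' scores, and subtype-dependent Bernoulli immunotherapy responses.
#'
#' Defaults encode the study conditions the pipeline targets: training-cohort
#' size 242; multivariate hazard ratios 0.26 for LIS-high and 3.40 for
#' MIS-high (mid-range of the reported 0.183-0.362 and 1.971-6.014 bands);
#' objective-response probabilities (0.273, 0.533, 0.102, 0.300) for the four
#' immune subtypes; uniform censoring over a 60-month follow-up horizon;
#' Weibull event times with mild aging hazard (shape 1.2). The latent
#' correlation `rho = 0.2` is a configuration choice, not a reported
#' quantity. `count_effect` and `texture_effect` are scaled so that a perfect
#' readout of the latent context discriminates LIS status with AUC in the
#' high 0.7s, the operating regime the imaging biomarkers work in.
#'
#' @param n_patients cohort size (>= 2).
#' @param seed integer seed; together with the config it fully determines the
#'   cohort.
#' @param rho correlation of the lymphoid and myeloid latents, in `[-1, 1]`.
#' @param texture_effect slope (intensity units per latent SD) of the in-mask
#'   noise SD on the lymphoid latent.
#' @param noise_sd baseline in-mask noise SD (intensity units).
#' @param smooth_base,smooth_effect baseline noise correlation length
#'   (voxels) and its slope on the myeloid latent.
#' @param count_effect log-mean units per latent SD for the IHC counts.
#' @param nb_dispersion negative-binomial size parameter; larger is closer to
#'   Poisson.
#' @param hr_lis_high,hr_mis_high hazard ratios of LIS-high and MIS-high.
#' @param weibull_shape,weibull_scale baseline event-time distribution
#'   (months).
#' @param censor_horizon upper bound of the uniform censoring time (months).
#' @param subtype_response_probs objective-response probability per immune
#'   subtype 1-4.
#' @param cr_fraction fraction of responders scored CR (rest PR).
#' @param sd_fraction fraction of non-responders scored SD (rest PD).
#' @param cps_effect slope of log-CPS on the (lymphoid - myeloid) contrast.
#' @param semi_axes_range range (mm) of the ellipsoid semi-axes.
#' @param spacing voxel spacing (mm) of the generated grids.
#' @param immunotherapy_flag whether patients are immunotherapy-treated (and
#'   thus have a RECIST response).
#' @param generate_images set `FALSE` to skip phantom image synthesis when
#'   only tabular structure is needed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 242, seed = 1, rho = 0.2,
                             texture_effect = 3, noise_sd = 10,
                             smooth_base = 1.0, smooth_effect = 0.25,
                             count_effect = 0.5, nb_dispersion = 2,
                             hr_lis_high = 0.26, hr_mis_high = 3.40,
                             weibull_shape = 1.2, weibull_scale = 48,
                             censor_horizon = 60,
                             subtype_response_probs = c(0.273, 0.533, 0.102, 0.300),
                             cr_fraction = 0.15, sd_fraction = 0.5,
                             cps_effect = 0.5,
                             semi_axes_range = c(8, 14),
                             spacing = c(1, 1, 1),
                             immunotherapy_flag = FALSE,
                             generate_images = TRUE) {
  if (!is.numeric(n_patients) || n_patients < 2) stop("n_patients must be >= 2")
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  probs <- c(subtype_response_probs, cr_fraction, sd_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (length(subtype_response_probs) != 4) stop("need 4 subtype response probabilities")
  if (hr_lis_high <= 0 || hr_mis_high <= 0) stop("hazard ratios must be positive")
  if (texture_effect < 0) stop("texture_effect must be >= 0")
  if (censor_horizon <= 0) stop("censor_horizon must be positive")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic phantom cohort
#'
#' Draws latent immune contexts from a bivariate normal with correlation
#' `rho`, then per patient a phantom tumor (optional), six IHC counts,
#' clinicopathologic covariates (independent of the latents by default),
#' survival driven by the true LIS/MIS statuses (scored against the cohort's
#' own medians), and a RECIST response when the cohort is immunotherapy
#' flagged. Identical config and seed reproduce the cohort bitwise.
#'
#' @param config a [synthetic_config()].
#' @return list of patients; see [cohort_table()] for the tabular view.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- as.integer(config$n_patients)
  set.seed(config$seed)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  lymphoid <- z1
  myeloid <- config$rho * z1 + sqrt(1 - config$rho^2) * z2
  patient_seeds <- sample.int(.Machine$integer.max - 1L, 3L * n)
  covars <- simulate_covariates(n)

  patients <- vector("list", n)
  for (k in seq_len(n)) {
    latent <- list(lymphoid_latent = lymphoid[k], myeloid_latent = myeloid[k])
    ph <- NULL
    if (config$generate_images) {
      set.seed(patient_seeds[k])
      axes <- runif(3, config$semi_axes_range[1], config$semi_axes_range[2])
      ph <- generate_phantom(latent,
                             geometry = list(semi_axes = axes,
                                             spacing = config$spacing),
                             seed = patient_seeds[n + k],
                             config = config)
    }
    counts <- simulate_ihc_counts(latent, config, seed = patient_seeds[2L * n + k])
    patients[[k]] <- c(list(patient_id = sprintf("P%04d", k)), latent,
                       list(volume = ph$volume, tumor_mask = ph$mask,
                            ihc_counts = counts),
                       covars[k, , drop = TRUE])
  }

  # true immune scores against the cohort's own medians
  counts_df <- as.data.frame(do.call(rbind, lapply(patients, `[[`, "ihc_counts")))
  med <- fit_medians(counts_df)
  sc <- score_cohort(counts_df, med)

  set.seed(config$seed + 1L)
  subtype <- assign_subtype(sc$lis_status, sc$mis_status)
  out <- simulate_outcomes(sc$lis_status, sc$mis_status, subtype, config,
                           seed = config$seed + 2L)
  cps <- exp(1.0 + config$cps_effect * (lymphoid - myeloid) / 2 + rnorm(n, 0, 1))
  for (k in seq_len(n)) {
    patients[[k]]$lis <- sc$lis[k]
    patients[[k]]$mis <- sc$mis[k]
    patients[[k]]$lis_status <- sc$lis_status[k]
    patients[[k]]$mis_status <- sc$mis_status[k]
    patients[[k]]$subtype <- subtype[k]
    patients[[k]]$survival_time <- out$survival_time[k]
    patients[[k]]$event <- out$event[k]
    patients[[k]]$response <- if (config$immunotherapy_flag) out$response[k] else NA_character_
    patients[[k]]$cps <- cps[k]
  }
  attr(patients, "medians") <- med
  patients
}

simulate_covariates <- function(n) {
  data.frame(
    age = round(pmin(pmax(rnorm(n, 58, 10), 25), 85)),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.685, 0.315)),
    location = sample(c("proximal", "middle", "distal"), n, replace = TRUE,
                      prob = c(0.3, 0.25, 0.45)),
    differentiation = sample(c("well", "moderate", "poor"), n, replace = TRUE,
                             prob = c(0.1, 0.4, 0.5)),
    size_cm = round(exp(rnorm(n, log(4), 0.4)), 1),
    lauren = sample(c("intestinal", "diffuse", "mixed"), n, replace = TRUE,
                    prob = c(0.45, 0.4, 0.15)),
    cea_elevated = rbinom(n, 1, 0.25),
    ca199_elevated = rbinom(n, 1, 0.20),
    chemotherapy = rbinom(n, 1, 0.6),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.14, 0.33, 0.39, 0.14)),
    stringsAsFactors = FALSE
  )
}

#' Generate one phantom tumor
#'
#' Ellipsoidal mask in a padded grid; interior intensity = baseline plus a
#' stationary correlated noise field. The field is white noise smoothed with
#' a Gaussian kernel whose width grows with the myeloid latent (correlation
#' length), then rescaled so the within-mask SD is exactly
#' `noise_sd + texture_effect * lymphoid_latent` (floored at 0.5 intensity
#' units). Background is constant.
#'
#' @param latent list with `lymphoid_latent`, `myeloid_latent`.
#' @param geometry list with `semi_axes` (mm, length 3) and `spacing`.
#' @param seed integer seed.
#' @param config a [synthetic_config()] supplying the texture parameters.
#' @return list with `volume` and `mask`.
#' @export
generate_phantom <- function(latent, geometry, seed,
                             config = synthetic_config()) {
  mask <- ellipsoid_mask(geometry$semi_axes, spacing = geometry$spacing,
                         margin_mm = 6)
  dims <- dim(mask$values)
  baseline <- 60
  vals <- array(0, dims)
  vals[mask$values] <- baseline

  sd_target <- config$noise_sd + config$texture_effect * latent$lymphoid_latent
  if (config$noise_sd > 0 || config$texture_effect > 0) {
    sd_target <- max(sd_target, 0.5)
    sigma <- min(max(config$smooth_base +
                       config$smooth_effect * latent$myeloid_latent, 0.3), 2.5)
    set.seed(seed)
    noise <- gauss_smooth3d(array(rnorm(prod(dims)), dims),
                            sigma_vox = rep(sigma, 3))
    inm <- noise[mask$values]
    inm <- (inm - mean(inm)) / sd(inm) * sd_target
    vals[mask$values] <- baseline + inm
  }
  list(volume = image_volume(vals, spacing = geometry$spacing), mask = mask)
}

#' Simulate the six IHC counts of one patient
#'
#' CD3 and CD8 counts (intratumoral and peritumoral) are negative binomial
#' with log-mean `log(base) + count_effect * lymphoid_latent`; CD66b counts
#' use the myeloid latent. Dispersion is the NB `size`; large values recover
#' the Poisson special case.
#'
#' @inheritParams generate_phantom
#' @return Named integer vector: `cd3_intra`, `cd3_peri`, `cd8_intra`,
#'   `cd8_peri`, `cd66b_intra`, `cd66b_peri`.
#' @export
simulate_ihc_counts <- function(latent, config = synthetic_config(), seed = 1) {
  set.seed(seed)
  mu_l <- exp(log(c(cd3 = 50, cd8 = 30)) + config$count_effect * latent$lymphoid_latent)
  mu_m <- exp(log(40) + config$count_effect * latent$myeloid_latent)
  c(cd3_intra = rnbinom(1, size = config$nb_dispersion, mu = mu_l["cd3"]),
    cd3_peri = rnbinom(1, size = config$nb_dispersion, mu = mu_l["cd3"]),
    cd8_intra = rnbinom(1, size = config$nb_dispersion, mu = mu_l["cd8"]),
    cd8_peri = rnbinom(1, size = config$nb_dispersion, mu = mu_l["cd8"]),
    cd66b_intra = rnbinom(1, size = config$nb_dispersion, mu = mu_m),
    cd66b_peri = rnbinom(1, size = config$nb_dispersion, mu = mu_m))
}

#' Simulate survival and immunotherapy response from immune statuses
#'
#' Event times follow a Weibull proportional-hazards model with log-hazard
#' `log(hr_lis_high) * [LIS high] + log(hr_mis_high) * [MIS high]`;
#' censoring is independent uniform on `(0, censor_horizon]`. The objective
#' response is Bernoulli with the configured per-subtype probability;
#' responders are split CR/PR and non-responders SD/PD by the configured
#' fractions.
#'
#' @param lis_status,mis_status character vectors `"low"`/`"high"`.
#' @param subtype integer vector 1-4 (see [assign_subtype()]).
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `survival_time`, `event`, `response`.
#' @export
simulate_outcomes <- function(lis_status, mis_status, subtype,
                              config = synthetic_config(), seed = 1) {
  n <- length(lis_status)
  stopifnot(length(mis_status) == n, length(subtype) == n)
  if (!all(subtype %in% 1:4)) stop("unknown subtype")
  if (!all(c(lis_status, mis_status) %in% c("low", "high")))
    stop("statuses must be 'low'/'high'")
  set.seed(seed)
  lp <- log(config$hr_lis_high) * (lis_status == "high") +
    log(config$hr_mis_high) * (mis_status == "high")
  u <- runif(n)
  t_event <- config$weibull_scale * (-log(u) * exp(-lp))^(1 / config$weibull_shape)
  cens <- runif(n, 0, config$censor_horizon)
  survival_time <- pmin(t_event, cens)
  event <- as.integer(t_event <= cens)

  p <- config$subtype_response_probs[subtype]
  responder <- rbinom(n, 1, p) == 1
  cr <- runif(n) < config$cr_fraction
  sd_ <- runif(n) < config$sd_fraction
  response <- ifelse(responder, ifelse(cr, "CR", "PR"), ifelse(sd_, "SD", "PD"))
  list(survival_time = survival_time, event = event, response = response)
}

#' Tabular view of a synthetic cohort
#'
#' @param patients output of [generate_cohort()].
#' @return data.frame, one row per patient, with documented columns: latents,
#'   the six IHC counts, covariates, LIS/MIS scores and statuses, subtype,
#'   survival time (months) and event indicator, response category and CPS.
#' @export
cohort_table <- function(patients) {
  cols <- c("patient_id", "lymphoid_latent", "myeloid_latent",
            "cd3_intra", "cd3_peri", "cd8_intra", "cd8_peri",
            "cd66b_intra", "cd66b_peri",
            "age", "sex", "location", "differentiation", "size_cm", "lauren",
            "cea_elevated", "ca199_elevated", "chemotherapy", "stage",
            "lis", "mis", "lis_status", "mis_status", "subtype",
            "survival_time", "event", "response", "cps")
  rows <- lapply(patients, function(p) {
    v <- c(p[c("patient_id", "lymphoid_latent", "myeloid_latent")],
           as.list(p$ihc_counts),
           p[c("age", "sex", "location", "differentiation", "size_cm",
               "lauren", "cea_elevated", "ca199_elevated", "chemotherapy",
               "stage", "lis", "mis", "lis_status", "mis_status", "subtype",
               "survival_time", "event", "response", "cps")])
    setNames(v, cols)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write a synthetic cohort to disk
#'
#' Volumes and masks as NIfTI (`.nii.gz`), the cohort table as CSV, and the
#' configuration as JSON.
#'
#' @param patients output of [generate_cohort()].
#' @param config the [synthetic_config()] that produced it.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(patients, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cohort_table(patients)
  write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  for (p in patients) {
    if (!is.null(p$volume)) {
      write_volume_nifti(p$volume, file.path(dir, paste0(p$patient_id, "_img.nii.gz")))
      write_volume_nifti(p$tumor_mask, file.path(dir, paste0(p$patient_id, "_mask.nii.gz")))
    }
  }
  invisible(dir)
}
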