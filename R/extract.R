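#' Extraction configuration
#'
#' Defines the reference feature inventory: 8 shape + 14 first-order + 90
#' texture statistics at each of the quantization levels in `texture_bins`,
#' per region. The reference configuration (bins 16, 32, 64) yields
#' 8 + 14 + 3 x 90 = 292 features per region and 584 for an
#' intratumoral/peritumoral pair.
#'
#' @param texture_bins integer vector of gray-level counts for texture
#'   quantization.
#' @param entropy_bins bin count for the first-order entropy/uniformity.
#' @export
extraction_config <- function(texture_bins = c(16, 32, 64), entropy_bins = 32) {
  stopifnot(all(texture_bins >= 2), entropy_bins >= 2)
  structure(list(texture_bins = as.integer(texture_bins),
                 entropy_bins = as.integer(entropy_bins)),
            class = "extraction_config")
}

#' Extract the full radiomics feature vector for a region pair
#'
#' Runs the whole inventory over the intratumoral and peritumoral regions of
#' one patient: shape features of each mask, first-order statistics of the
#' in-region intensities, and the 90 texture statistics at each configured
#' quantization. Feature names encode region, family, statistic and bin
#' count (e.g. `intra_b16_glcm_contrast_mean`); order and values are
#' deterministic.
#'
#' @param volume an [image_volume()].
#' @param pair a `region_pair` from [build_peritumoral_ring()].
#' @param config an [extraction_config()].
#' @return Named numeric vector (584 entries under the reference config).
#' @export
extract_feature_vector <- function(volume, pair, config = extraction_config()) {
  stopifnot(inherits(pair, "region_pair"))
  validate_region_pair(pair, volume)
  regions <- list(intra = pair$intratumoral, peri = pair$peritumoral)
  out <- lapply(names(regions), function(rg) {
    mask <- regions[[rg]]
    if (!any(mask$values)) stop("empty ", rg, " region")
    fv <- c(shape_features(mask),
            first_order_features(volume, mask, config$entropy_bins))
    tex <- lapply(config$texture_bins, function(b) {
      tf <- texture_features(discretize(volume, mask, b))
      setNames(tf, paste0("b", b, "_", names(tf)))
    })
    fv <- c(fv, unlist(tex))
    setNames(fv, paste0(rg, "_", names(fv)))
  })
  unlist(out)
}

#' Extract a feature matrix for a cohort of patients
#'
#' @param patients list of synthetic patients (or any list with `volume` and
#'   `tumor_mask` fields).
#' @param config an [extraction_config()].
#' @param target_mm isotropic resampling pitch applied before morphology.
#' @param outer_mm,inner_mm peritumoral band geometry in mm.
#' @param verbose print progress every 25 patients.
#' @return data.frame with `patient_id` and one named column per feature.
#' @export
extract_cohort_features <- function(patients, config = extraction_config(),
                                    target_mm = 1, outer_mm = 2, inner_mm = 1,
                                    verbose = FALSE) {
  rows <- vector("list", length(patients))
  for (k in seq_along(patients)) {
    p <- patients[[k]]
    rs <- resample_isotropic(p$volume, p$tumor_mask, target_mm)
    pair <- build_peritumoral_ring(rs$mask, outer_mm = outer_mm,
                                   inner_mm = inner_mm)
    rows[[k]] <- extract_feature_vector(rs$volume, pair, config)
    if (verbose && k %% 25 == 0) message("extracted ", k, "/", length(patients))
  }
  fm <- as.data.frame(do.call(rbind, rows))
  ids <- vapply(patients, function(p) if (!is.null(p$patient_id)) p$patient_id
                else NA_character_, character(1))
  if (all(is.na(ids))) ids <- sprintf("P%03d", seq_along(patients))
  cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE), fm)
}
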