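#' Extract the full 27-feature vector from one patient
#'
#' Runs every extractor on a patient's images and masks: shape
#' descriptors and T2 statistics on the T2-weighted volume, perfusion
#' quantification on the ASL pair, the five diffusion model fits on the
#' DWI series, plus the clinical T-/N-stage. Voxels flagged in the
#' patient's `necrosis` masks (per-sequence list with elements `t2`,
#' `dwi`, `asl`) are excluded from every ROI statistic. Any extractor
#' failure is rethrown with the failing stage named; no NAs are
#' produced.
#'
#' @param patient A `synthetic_patient` (or any list with the same
#'   elements: `t2`, `t2_tumor_mask`, `t2_muscle_mask`, `dwi`,
#'   `dwi_tumor_mask`, `asl_control`, `asl_label`, `asl_tumor_mask`,
#'   `asl_muscle_mask`, `clinical`, optional `necrosis`).
#' @param glcm_levels GLCM quantization depth.
#' @param asl_cfg [asl_config()] used for perfusion quantification.
#' @return Named numeric vector of the 27 features (see
#'   [feature_names()]).
#' @export
extract_features <- function(patient, glcm_levels = 64L,
                             asl_cfg = asl_config()) {
  need <- c("t2", "t2_tumor_mask", "t2_muscle_mask", "dwi",
            "dwi_tumor_mask", "asl_control", "asl_label",
            "asl_tumor_mask", "asl_muscle_mask", "clinical")
  miss <- need[!vapply(need, function(f) !is.null(patient[[f]]), logical(1))]
  if (length(miss))
    stop("patient is missing required elements: ",
         paste(miss, collapse = ", "))
  nec <- patient$necrosis
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("feature extraction failed at stage '%s': %s", what,
                   conditionMessage(e)), call. = FALSE))
  }
  mo <- stage("morphology",
              measure_morphology(mask_without(patient$t2_tumor_mask,
                                              nec$t2)))
  t2s <- stage("t2-intensity",
               relative_mean_and_cv(patient$t2, patient$t2_tumor_mask,
                                    patient$t2_muscle_mask,
                                    exclude = nec$t2))
  gl <- stage("glcm",
              glcm_features(patient$t2, patient$t2_tumor_mask,
                            levels = glcm_levels, exclude = nec$t2))
  pf <- stage("asl", {
    dm <- asl_subtract(patient$asl_control, patient$asl_label)
    tumor <- quantify_tbf(dm, patient$asl_control, patient$asl_tumor_mask,
                          asl_cfg, exclude = nec$asl)
    muscle <- quantify_tbf(dm, patient$asl_control,
                           patient$asl_muscle_mask, asl_cfg)
    list(tbf_abs = tumor, tbf_rel = relative_tbf(tumor, muscle))
  })
  df <- stage("diffusion",
              extract_diffusion_features(patient$dwi,
                                         patient$dwi_tumor_mask,
                                         exclude = nec$dwi))
  out <- c(t_stage = as.numeric(patient$clinical$t_stage),
           n_stage = as.numeric(patient$clinical$n_stage),
           volume_mL = mo$volume_mL, surface_cm2 = mo$surface_cm2,
           sphericity = mo$sphericity,
           rel_mean_signal = t2s$rel_mean_signal, cv = t2s$cv,
           glcm_contrast = gl[["contrast"]],
           glcm_correlation = gl[["correlation"]],
           glcm_energy = gl[["energy"]],
           glcm_homogeneity = gl[["homogeneity"]],
           tbf_abs = pf$tbf_abs, tbf_rel = pf$tbf_rel, df)
  stopifnot(identical(names(out), feature_names()))
  if (any(!is.finite(out)))
    stop("feature extraction produced non-finite values: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

mask_without <- function(mask, exclude) {
  if (is.null(exclude)) return(mask)
  roi_mask(mask$data & !exclude$data, mask$spacing)
}

#' Extract the feature table for a whole cohort
#'
#' @param patients List of patients (see [extract_features()]).
#' @param ... Passed to [extract_features()].
#' @return `data.frame` with `id`, the 27 features, and `outcome`.
#' @export
extract_cohort_features <- function(patients, ...) {
  rows <- lapply(patients, function(p) {
    fv <- extract_features(p, ...)
    cbind(data.frame(id = p$id %||% NA_character_),
          as.data.frame(as.list(fv)),
          data.frame(outcome = p$outcome %||% NA_character_))
  })
  out <- do.call(rbind, rows)
  out$outcome <- factor(out$outcome, levels = c("control", "failure"))
  rownames(out) <- NULL
  out
}

#' Z-score standardization fitted on training rows only
#'
#' Centers and scales every feature column using the mean and SD of the
#' training rows, then applies that scaler to all rows — held-out rows
#' never influence the scaler (no leakage). Ordinal stage columns are
#' scaled like any other feature. A zero-variance feature keeps unit
#' scale with a warning.
#'
#' @param table Feature `data.frame` (as from
#'   [extract_cohort_features()]) or plain matrix of features.
#' @param fit_rows Integer indices of the rows used to fit the scaler.
#' @return List with `table` (standardized copy), `center`, `scale`.
#' @export
standardize_features <- function(table, fit_rows) {
  if (!length(fit_rows)) stop("fit_rows must be non-empty")
  cols <- intersect(feature_names(), colnames(table))
  if (!length(cols)) cols <- colnames(table)
  x <- as.matrix(table[, cols, drop = FALSE])
  ctr <- colMeans(x[fit_rows, , drop = FALSE])
  scl <- apply(x[fit_rows, , drop = FALSE], 2, stats::sd)
  zero <- !is.finite(scl) | scl == 0
  if (any(zero)) {
    warning("zero-variance feature(s) kept at unit scale: ",
            paste(cols[zero], collapse = ", "))
    scl[zero] <- 1
  }
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  out <- table
  out[, cols] <- xs
  list(table = out, center = ctr, scale = scl)
}
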