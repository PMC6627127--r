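#' Write a synthetic cohort to disk
#'
#' One subdirectory per patient containing NIfTI volumes (T2, 4D DWI,
#' ASL control/label) and masks, a JSON ground-truth sidecar per
#' patient, a cohort-level clinical CSV (`id`, `t_stage`, `n_stage`,
#' `outcome`) and a JSON manifest listing every file.
#'
#' @param patients List of `synthetic_patient`s.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
write_cohort <- function(patients, dir) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  write_vol <- function(data, spacing, path) {
    nii <- RNifti::asNifti(data + 0)
    RNifti::pixdim(nii) <- spacing
    RNifti::writeNifti(nii, path)
    basename(path)
  }
  entries <- lapply(patients, function(p) {
    pdir <- file.path(dir, p$id)
    dir.create(pdir, showWarnings = FALSE)
    files <- c(
      write_vol(p$t2$data, p$t2$spacing, file.path(pdir, "t2.nii.gz")),
      write_vol(p$t2_tumor_mask$data, p$t2$spacing,
                file.path(pdir, "tumor_mask_t2.nii.gz")),
      write_vol(p$t2_muscle_mask$data, p$t2$spacing,
                file.path(pdir, "muscle_mask_t2.nii.gz")),
      write_vol(p$dwi$data, p$dwi$spacing, file.path(pdir, "dwi.nii.gz")),
      write_vol(p$dwi_tumor_mask$data, p$dwi$spacing,
                file.path(pdir, "tumor_mask_dwi.nii.gz")),
      write_vol(p$asl_control$data, p$asl_control$spacing,
                file.path(pdir, "asl_control.nii.gz")),
      write_vol(p$asl_label$data, p$asl_label$spacing,
                file.path(pdir, "asl_label.nii.gz")),
      write_vol(p$asl_tumor_mask$data, p$asl_tumor_mask$spacing,
                file.path(pdir, "tumor_mask_asl.nii.gz")),
      write_vol(p$asl_muscle_mask$data, p$asl_muscle_mask$spacing,
                file.path(pdir, "muscle_mask_asl.nii.gz")))
    truth <- list(id = p$id, outcome = p$outcome, clinical = p$clinical,
                  truth = p$truth, truth_realized = p$truth_realized,
                  b_values = p$dwi$b_values)
    jsonlite::write_json(truth, file.path(pdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    list(id = p$id, files = c(files, "truth.json"))
  })
  clinical <- data.frame(
    id = vapply(patients, function(p) p$id, character(1)),
    t_stage = vapply(patients, function(p) p$clinical$t_stage, numeric(1)),
    n_stage = vapply(patients, function(p) p$clinical$n_stage, numeric(1)),
    outcome = vapply(patients, function(p) p$outcome, character(1)))
  utils::write.csv(clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  manifest <- list(format = "qmripredict-cohort", version = 1L,
                   n_patients = length(patients),
                   clinical_table = "clinical.csv", patients = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates the manifest (declared patient count and presence of every
#' listed file) and reconstructs the patient objects.
#'
#' @param dir Cohort directory.
#' @return List of `synthetic_patient`s.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath)
  if (!identical(manifest$format, "qmripredict-cohort"))
    stop("not a cohort directory (unexpected manifest format)")
  if (length(manifest$patients) != manifest$n_patients)
    stop("manifest is inconsistent: patient count mismatch")
  clinical <- utils::read.csv(file.path(dir, manifest$clinical_table))
  read_vol <- function(path) {
    nii <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(nii)
    list(data = array(as.numeric(nii), dim(nii)), spacing = sp[1:3])
  }
  lapply(manifest$patients, function(e) {
    pdir <- file.path(dir, e$id)
    for (f in e$files)
      if (!file.exists(file.path(pdir, f)))
        stop("manifest lists missing file: ", file.path(e$id, f))
    truth <- jsonlite::read_json(file.path(pdir, "truth.json"),
                                 simplifyVector = TRUE)
    v <- function(name) read_vol(file.path(pdir, name))
    t2 <- v("t2.nii.gz")
    tm <- v("tumor_mask_t2.nii.gz"); mm <- v("muscle_mask_t2.nii.gz")
    dw <- v("dwi.nii.gz"); dm <- v("tumor_mask_dwi.nii.gz")
    ac <- v("asl_control.nii.gz"); al <- v("asl_label.nii.gz")
    at <- v("tumor_mask_asl.nii.gz"); am <- v("muscle_mask_asl.nii.gz")
    structure(list(
      id = truth$id, outcome = truth$outcome,
      clinical = truth$clinical, truth = truth$truth,
      truth_realized = truth$truth_realized,
      t2 = image_volume(t2$data, t2$spacing),
      t2_tumor_mask = roi_mask(tm$data > 0.5, tm$spacing),
      t2_muscle_mask = roi_mask(mm$data > 0.5, mm$spacing),
      dwi = dwi_series(truth$b_values, dw$data, dw$spacing),
      dwi_tumor_mask = roi_mask(dm$data > 0.5, dm$spacing),
      asl_control = image_volume(ac$data, ac$spacing),
      asl_label = image_volume(al$data, al$spacing),
      asl_tumor_mask = roi_mask(at$data > 0.5, at$spacing),
      asl_muscle_mask = roi_mask(am$data > 0.5, am$spacing),
      necrosis = NULL), class = "synthetic_patient")
  })
}
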