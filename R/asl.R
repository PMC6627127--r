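#' pCASL quantification configuration
#'
#' Constants of the single-compartment pseudo-continuous ASL
#' quantification model. Labeling duration and post-label delay follow
#' the acquisition protocol; partition coefficient, blood T1 and labeling
#' efficiency use standard 3T values and are fully configurable.
#'
#' @param labeling_duration Label duration tau, ms.
#' @param post_label_delay Post-label delay, ms.
#' @param lambda Blood-tissue partition coefficient, mL/g.
#' @param t1_blood Longitudinal relaxation time of arterial blood, ms.
#' @param efficiency Labeling efficiency (0, 1].
#' @return A list of class `asl_config`.
#' @export
asl_config <- function(labeling_duration = 1650, post_label_delay = 1280,
                       lambda = 0.9, t1_blood = 1650, efficiency = 0.85) {
  vals <- c(labeling_duration, post_label_delay, lambda, t1_blood,
            efficiency)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all ASL constants must be positive")
  if (efficiency > 1) stop("labeling efficiency cannot exceed 1")
  structure(list(labeling_duration = labeling_duration,
                 post_label_delay = post_label_delay, lambda = lambda,
                 t1_blood = t1_blood, efficiency = efficiency),
            class = "asl_config")
}

# dM / (M0 * flow) for flow in mL/100g/min; the single-compartment pCASL
# model: TBF = 6000 lambda dM exp(PLD/T1b) / (2 eta M0 T1b_s (1 - exp(-tau/T1b)))
asl_scale_factor <- function(cfg) {
  t1s <- cfg$t1_blood / 1000
  (2 * cfg$efficiency * t1s * (1 - exp(-cfg$labeling_duration / cfg$t1_blood)) *
     exp(-cfg$post_label_delay / cfg$t1_blood)) / (6000 * cfg$lambda)
}

#' Forward ASL subtraction signal
#'
#' Generates the control-minus-label difference signal `dM` produced by a
#' given blood flow under the same quantification equation that
#' [quantify_tbf()] inverts (forward/inverse closure).
#'
#' @param flow Blood flow in mL/100g/min (scalar or array).
#' @param m0 Equilibrium magnetization (scalar or array).
#' @param cfg An [asl_config()].
#' @return dM on the scale of `m0`.
#' @export
asl_forward_dm <- function(flow, m0, cfg = asl_config()) {
  if (any(flow < 0)) stop("flow must be non-negative")
  m0 * flow * asl_scale_factor(cfg)
}

#' Subtract label from control image
#'
#' @param control,label Aligned `image_volume`s.
#' @return An `image_volume` holding the perfusion-weighted difference
#'   control - label.
#' @export
asl_subtract <- function(control, label) {
  check_same_geometry(control, label, "control and label")
  image_volume(control$data - label$data, control$spacing)
}

#' Quantify absolute tissue blood flow from an ASL difference image
#'
#' Single-compartment pCASL quantification on the ROI mean. The control
#' image serves as the M0 proxy (no separate M0 scan is assumed).
#'
#' @param dm Difference `image_volume` (control - label).
#' @param m0 M0 `image_volume` (typically the control image).
#' @param mask Tumor or muscle `roi_mask`.
#' @param cfg An [asl_config()].
#' @param exclude Optional exclusion `roi_mask` (necrosis).
#' @return ROI-mean blood flow in mL/100g/min.
#' @export
quantify_tbf <- function(dm, m0, mask, cfg = asl_config(), exclude = NULL) {
  check_same_geometry(dm, m0, "dM and M0")
  dmv <- mask_values(dm, mask, exclude)
  m0v <- mask_values(m0, mask, exclude)
  ok <- m0v > 0
  if (!any(ok)) stop("all M0 voxels in the ROI are non-positive")
  if (!all(ok))
    warning(sprintf("%d ROI voxels with non-positive M0 excluded",
                    sum(!ok)))
  mean(dmv[ok] / m0v[ok]) / asl_scale_factor(cfg)
}

#' Relative tumor blood flow
#'
#' @param tumor_tbf Absolute tumor blood flow, mL/100g/min.
#' @param muscle_tbf Reference medial pterygoid muscle flow, mL/100g/min.
#' @return Dimensionless ratio tumor / muscle.
#' @export
relative_tbf <- function(tumor_tbf, muscle_tbf) {
  if (any(muscle_tbf <= 0)) stop("muscle flow must be positive")
  tumor_tbf / muscle_tbf
}
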