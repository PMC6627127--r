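#' Acquisition configuration for the synthetic scanner
#'
#' Geometry, b-value schedule, signal averaging and noise levels of the
#' simulated multiparametric acquisition. The DWI schedule, its
#' per-b-value signal averaging (1 average for b <= 100, 2 for 200-800,
#' 3 for 1000-2000 s/mm^2), the DWI voxel size and the ASL labeling
#' timing follow the clinical protocol the pipeline targets; grid
#' extents are kept tumor-centric so that a full cohort can be simulated
#' quickly at desk scale.
#'
#' @param b_values DWI b-value schedule, s/mm^2 (strictly increasing,
#'   non-negative; default the 12-value clinical schedule).
#' @param t2_spacing,t2_dim Voxel size (mm) and grid size of the
#'   T2-weighted volume.
#' @param dwi_spacing,dwi_dim Geometry of the DWI frames.
#' @param asl_spacing,asl_dim Geometry of the ASL control/label pair.
#' @param snr_b0 DWI signal-to-noise ratio at b = 0 (Rician noise).
#' @param asl_snr Effective control-image SNR of the ASL pair after
#'   repetition averaging (Gaussian noise; the subtraction signal is
#'   only ~1-3% of M0, so the effective SNR must be high enough for
#'   ROI-level flow quantification, as it is clinically).
#' @param t2_noise_frac Gaussian noise SD on T2 as a fraction of the
#'   muscle signal.
#' @param asl Quantification constants, an [asl_config()].
#' @param m0 Equilibrium magnetization of tissue in the ASL control
#'   image (arbitrary units).
#' @param s0_dwi Tumor signal at b = 0 (arbitrary units).
#' @return Object of class `acquisition_config`.
#' @export
acquisition_config <- function(b_values = b_schedule_full(),
                               t2_spacing = c(1.5, 1.5, 1.5),
                               t2_dim = c(48, 48, 32),
                               dwi_spacing = c(3.59, 3.59, 5),
                               dwi_dim = c(22, 22, 12),
                               asl_spacing = c(2.875, 2.875, 5),
                               asl_dim = c(26, 26, 12),
                               snr_b0 = 50, asl_snr = 500,
                               t2_noise_frac = 0.02,
                               asl = asl_config(), m0 = 1000,
                               s0_dwi = 100) {
  b_values <- as.numeric(b_values)
  if (any(b_values < 0) || any(diff(b_values) <= 0))
    stop("b-values must be non-negative and strictly increasing")
  structure(list(b_values = b_values, t2_spacing = t2_spacing,
                 t2_dim = as.integer(t2_dim), dwi_spacing = dwi_spacing,
                 dwi_dim = as.integer(dwi_dim), asl_spacing = asl_spacing,
                 asl_dim = as.integer(asl_dim), snr_b0 = snr_b0,
                 asl_snr = asl_snr, t2_noise_frac = t2_noise_frac,
                 asl = asl, m0 = m0, s0_dwi = s0_dwi),
            class = "acquisition_config")
}

#' Number of signal averages per b-value
#'
#' @param b b-values in s/mm^2.
#' @return Integer vector: 1 for b <= 100, 2 for b <= 800, 3 above.
#' @export
signal_averages <- function(b) {
  ifelse(b <= 100, 1L, ifelse(b <= 800, 2L, 3L))
}

# ---------------------------------------------------------------------
# star-shaped tumor blob: deformed ellipsoid with smooth random surface
# bumps; deformation amplitude is calibrated by root finding against the
# continuum sphericity computed on an angular quadrature grid.

blob_quadrature <- function(n_theta = 80L, n_phi = 160L) {
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
  list(theta = theta, phi = phi,
       u = cbind(
         sin(rep(theta, times = n_phi)) * cos(rep(phi, each = n_theta)),
         sin(rep(theta, times = n_phi)) * sin(rep(phi, each = n_theta)),
         cos(rep(theta, times = n_phi))))
}

blob_shape_fn <- function(seed, n_bumps = 32L, kappa = 30,
                          eps_max = 1.8, axis_spread = 0.4) {
  pars <- withr::with_seed(seed, {
    dirs <- matrix(stats::rnorm(3 * n_bumps), n_bumps, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    list(dirs = dirs, w = stats::rnorm(n_bumps),
         la = stats::runif(3, -axis_spread, axis_spread))
  })
  quad <- blob_quadrature()
  bump_raw <- function(u) {
    as.vector(exp(kappa * (u %*% t(pars$dirs) - 1)) %*% pars$w)
  }
  h <- bump_raw(quad$u)
  h_mean <- mean(h); h_sd <- stats::sd(h)
  if (h_sd == 0) h_sd <- 1
  la <- pars$la - mean(pars$la)
  # bounded radial deformation: strong enough at d = 1 to reach the
  # irregular end of the observed sphericities, but clipped so no spike
  # or dent exceeds the [0.3, 1.9] radial band (keeps the blob inside
  # realistic grids and the voxelization faithful)
  function(u, d) {
    ax <- exp(d * la)
    ell <- 1 / sqrt((u[, 1] / ax[1])^2 + (u[, 2] / ax[2])^2 +
                      (u[, 3] / ax[3])^2)
    bump <- (bump_raw(u) - h_mean) / h_sd
    ell * pmin(pmax(1 + d * eps_max * bump, 0.3), 1.9)
  }
}

# continuum volume, area, sphericity of r(theta, phi) by quadrature
blob_measure <- function(shape_fn, d, quad = blob_quadrature()) {
  nt <- length(quad$theta); np <- length(quad$phi)
  r <- matrix(shape_fn(quad$u, d), nt, np)
  st <- sin(quad$theta)
  dth <- pi / nt; dph <- 2 * pi / np
  v <- sum(r^3 / 3 * st) * dth * dph
  r_th <- r
  r_th[2:(nt - 1), ] <- (r[3:nt, ] - r[1:(nt - 2), ]) / (2 * dth)
  r_th[1, ] <- (r[2, ] - r[1, ]) / dth
  r_th[nt, ] <- (r[nt, ] - r[nt - 1, ]) / dth
  r_ph <- (r[, c(2:np, 1)] - r[, c(np, 1:(np - 1))]) / (2 * dph)
  integ <- sqrt(r^4 * st^2 + r^2 * r_th^2 * st^2 + r^2 * r_ph^2)
  a <- sum(integ) * dth * dph
  list(volume = v, area = a,
       sphericity = pi^(1 / 3) * (6 * v)^(2 / 3) / a)
}

#' Synthesize a tumor mask with target volume and sphericity
#'
#' Generates a star-shaped blob (randomly oriented ellipsoid with smooth
#' random surface bumps), calibrates the deformation amplitude by root
#' finding so that the continuum sphericity matches the target, scales
#' it to the target volume and voxelizes it at the grid center.
#'
#' @param target_volume_mL Target volume, mL.
#' @param target_sphericity Target sphericity in (0, 1].
#' @param spacing Voxel spacing, mm.
#' @param dim Grid size (3 integers).
#' @param seed RNG seed controlling the blob shape.
#' @param center Blob center in voxel units (defaults to grid center).
#' @param clamp If `TRUE`, a target sphericity below the reachable
#'   minimum of the sampled shape family is clamped to that minimum
#'   instead of raising an infeasible-shape error (used by the cohort
#'   synthesizer, where the realized value becomes the ground truth).
#' @return A `roi_mask`; attribute `blob` stores the analytic shape
#'   (shape function, amplitude, radius scale, center in mm) so the same
#'   object can be re-voxelized on other grids.
#' @export
synthesize_tumor_mask <- function(target_volume_mL, target_sphericity,
                                  spacing, dim, seed = 1L,
                                  center = NULL, clamp = FALSE) {
  if (target_volume_mL <= 0) stop("target volume must be positive")
  if (target_sphericity <= 0 || target_sphericity > 1)
    stop("target sphericity must lie in (0, 1]")
  vox <- prod(spacing)
  if (target_volume_mL * 1000 / vox < 50)
    stop("target volume not representable: fewer than 50 voxels on this grid")
  shape_fn <- blob_shape_fn(seed)
  quad <- blob_quadrature()
  psi_of <- function(d) blob_measure(shape_fn, d, quad)$sphericity
  psi_min <- psi_of(1)
  if (target_sphericity < psi_min - 0.02) {
    if (!clamp)
      stop(sprintf(
        "infeasible shape: sphericity %.2f below the reachable minimum %.2f",
        target_sphericity, psi_min))
    target_sphericity <- psi_min
  }
  d <- if (target_sphericity >= psi_of(0)) 0 else if
    (target_sphericity <= psi_min) 1 else
      stats::uniroot(function(x) psi_of(x) - target_sphericity,
                     c(0, 1), tol = 1e-4)$root
  mb <- blob_measure(shape_fn, d, quad)
  r0 <- (target_volume_mL * 1000 / mb$volume)^(1 / 3)
  if (is.null(center)) center <- (dim + 1) / 2
  center_mm <- center * spacing
  blob <- list(shape_fn = shape_fn, d = d, r0 = r0, center_mm = center_mm,
               target_volume_mL = target_volume_mL,
               target_sphericity = target_sphericity)
  m <- voxelize_blob(blob, spacing, dim)
  if (sum(m$data) < 50)
    stop("voxelized blob has fewer than 50 voxels")
  attr(m, "blob") <- blob
  m
}

voxelize_blob <- function(blob, spacing, dim, center_mm = NULL) {
  if (is.null(center_mm)) center_mm <- blob$center_mm
  cx <- (seq_len(dim[1]) * spacing[1]) - center_mm[1]
  cy <- (seq_len(dim[2]) * spacing[2]) - center_mm[2]
  cz <- (seq_len(dim[3]) * spacing[3]) - center_mm[3]
  X <- array(cx, dim); Y <- array(rep(cy, each = dim[1]), dim)
  Z <- array(rep(cz, each = dim[1] * dim[2]), dim)
  rr <- sqrt(X^2 + Y^2 + Z^2)
  u <- cbind(as.vector(X), as.vector(Y), as.vector(Z)) /
    ifelse(as.vector(rr) > 0, as.vector(rr), 1)
  rdir <- blob$shape_fn(u, blob$d) * blob$r0
  inside <- as.vector(rr) <= rdir
  roi_mask(array(inside, dim), spacing)
}

# reference-muscle ROI: a small box near the grid edge, guaranteed
# disjoint from the tumor blob
muscle_box_mask <- function(spacing, dim, size_mm = c(16, 16, 12)) {
  n <- pmax(2L, pmin(round(size_mm / spacing), dim %/% 3))
  m <- array(FALSE, dim)
  m[(dim[1] - n[1]):(dim[1] - 1L), 2:(1 + n[2]), 2:(1 + n[3])] <- TRUE
  roi_mask(m, spacing)
}

# ---------------------------------------------------------------------

#' Synthesize a multi-b-value DWI series
#'
#' Tumor voxels follow the tri-exponential forward model with the
#' patient's true compartment parameters (the richest of the five
#' models, so that the simpler models are exercised on realistically
#' mis-specified decays); background tissue follows a mono-exponential.
#' Rician magnitude noise at the configured b0 SNR is applied per signal
#' average and the averages per b-value follow [signal_averages()].
#'
#' @param truth Named list/vector with `f1`, `f2`, `f3`, `d1`, `d2`,
#'   `d3` (fractions sum to 1; coefficients x 1e-3 mm^2/s).
#' @param mask Tumor `roi_mask` on the DWI grid.
#' @param cfg An [acquisition_config()].
#' @param seed RNG seed.
#' @param noise Logical; `FALSE` produces the exact noiseless forward
#'   signals.
#' @return A `dwi_series`.
#' @export
synthesize_dwi <- function(truth, mask, cfg = acquisition_config(),
                           seed = 1L, noise = TRUE) {
  truth <- as.list(truth)
  d <- dim(mask$data)
  if (!identical(d, as.integer(cfg$dwi_dim)) &&
      !identical(as.integer(d), as.integer(cfg$dwi_dim)))
    stop("mask does not match the DWI grid of the configuration")
  b <- cfg$b_values
  tpar <- list(S0 = cfg$s0_dwi, f1 = truth$f1, f2 = truth$f2,
               f3 = truth$f3, d1 = truth$d1, d2 = truth$d2,
               d3 = truth$d3)
  s_tumor <- dwi_signal("triexp", tpar, b)
  s_bg <- dwi_signal("mono", list(S0 = 0.6 * cfg$s0_dwi, adc = 1.3), b)
  arr <- array(0, c(d, length(b)))
  tum <- mask$data
  navg <- signal_averages(b)
  sigma <- cfg$s0_dwi / cfg$snr_b0
  gen <- function() {
    for (i in seq_along(b)) {
      s <- array(s_bg[i], d)
      s[tum] <- s_tumor[i]
      if (noise) {
        acc <- array(0, d)
        for (a in seq_len(navg[i])) {
          e1 <- array(stats::rnorm(length(s), 0, sigma), d)
          e2 <- array(stats::rnorm(length(s), 0, sigma), d)
          acc <- acc + sqrt((s + e1)^2 + e2^2)
        }
        s <- acc / navg[i]
      }
      arr[, , , i] <<- s
    }
  }
  if (noise) withr::with_seed(seed, gen()) else gen()
  dwi_series(b, arr, mask$spacing)
}

#' Synthesize an ASL control/label pair
#'
#' The subtraction signal is generated by the same single-compartment
#' pCASL forward equation that [quantify_tbf()] inverts (round-trip
#' closure); the control image carries the tissue equilibrium
#' magnetization. Gaussian noise is added to both frames.
#'
#' @param tumor_flow,muscle_flow Blood flow in mL/100g/min.
#' @param tumor_mask,muscle_mask Disjoint `roi_mask`s on the ASL grid.
#' @param cfg An [acquisition_config()].
#' @param seed RNG seed.
#' @param noise Logical noise switch.
#' @return List with `control` and `label` `image_volume`s.
#' @export
synthesize_asl <- function(tumor_flow, muscle_flow, tumor_mask,
                           muscle_mask, cfg = acquisition_config(),
                           seed = 1L, noise = TRUE) {
  if (tumor_flow < 0 || muscle_flow < 0) stop("flows must be non-negative")
  check_same_geometry(tumor_mask, muscle_mask, "tumor and muscle masks")
  d <- dim(tumor_mask$data)
  flow <- array(10, d)  # unremarkable background tissue
  flow[muscle_mask$data] <- muscle_flow
  flow[tumor_mask$data] <- tumor_flow
  m0 <- array(cfg$m0, d)
  dm <- asl_forward_dm(flow, m0, cfg$asl)
  control <- m0
  label <- control - dm
  if (noise) {
    sigma <- cfg$m0 / cfg$asl_snr
    withr::with_seed(seed, {
      control <- control + array(stats::rnorm(length(control), 0, sigma), d)
      label <- label + array(stats::rnorm(length(label), 0, sigma), d)
    })
  }
  list(control = image_volume(control, tumor_mask$spacing),
       label = image_volume(label, tumor_mask$spacing))
}

# correlated Gaussian random field, standardized exactly within the mask
correlated_field <- function(dim, corr_len_vox, white) {
  f <- smooth_gaussian3d(white, corr_len_vox)
  f
}

#' Synthesize a fat-suppressed T2-weighted volume
#'
#' Tumor voxels are drawn from a spatially correlated Gaussian field
#' whose correlation length controls GLCM contrast; the field is
#' standardized exactly within the tumor ROI so the relative mean signal
#' and coefficient of variation targets are met exactly in the
#' noiseless image. The reference muscle box is constant (plus
#' acquisition noise); when `contrast_target` is given, the correlation
#' length is calibrated by bisection against the measured GLCM contrast.
#'
#' @param tumor_mask,muscle_mask `roi_mask`s on the T2 grid.
#' @param rel_mean_signal Target tumor/muscle mean-signal ratio (> 0).
#' @param cv Target coefficient of variation within the tumor (>= 0).
#' @param contrast_target Optional GLCM contrast target (G = 64,
#'   distance 1); `NULL` uses `corr_len_vox` directly.
#' @param corr_len_vox Field correlation length in voxels when no
#'   contrast target is given.
#' @param cfg An [acquisition_config()].
#' @param seed RNG seed.
#' @param noise Logical noise switch.
#' @param glcm_levels Quantization depth used during calibration.
#' @return An `image_volume`; attribute `corr_len_vox` records the
#'   (calibrated) correlation length.
#' @export
synthesize_t2 <- function(tumor_mask, muscle_mask, rel_mean_signal, cv,
                          contrast_target = NULL, corr_len_vox = 1,
                          cfg = acquisition_config(), seed = 1L,
                          noise = TRUE, glcm_levels = 64L) {
  if (rel_mean_signal <= 0) stop("relative mean signal must be positive")
  if (cv < 0) stop("CV must be non-negative")
  check_same_geometry(tumor_mask, muscle_mask, "tumor and muscle masks")
  d <- dim(tumor_mask$data)
  muscle_val <- 100
  tumor_mean <- rel_mean_signal * muscle_val
  base <- array(30, d)
  base[muscle_mask$data] <- muscle_val
  tum <- tumor_mask$data
  assemble <- function(corr_len, white) {
    img <- base
    if (cv == 0 || sum(tum) < 2) {
      img[tum] <- tumor_mean
    } else {
      f <- correlated_field(d, corr_len, white)
      fv <- f[tum]
      fv <- (fv - mean(fv)) / stats::sd(fv)
      img[tum] <- tumor_mean + cv * tumor_mean * fv
    }
    img
  }
  white <- withr::with_seed(seed, array(stats::rnorm(prod(d)), d))
  if (!is.null(contrast_target) && cv > 0 && sum(tum) >= 2) {
    measure <- function(lc) {
      img <- assemble(lc, white)
      glcm_features(image_volume(img, tumor_mask$spacing), tumor_mask,
                    levels = glcm_levels)[["contrast"]]
    }
    lo <- 0.25; hi <- 5
    c_lo <- measure(lo); c_hi <- measure(hi)  # contrast decreasing in length
    if (contrast_target >= c_lo) corr_len <- lo
    else if (contrast_target <= c_hi) corr_len <- hi
    else {
      for (i in 1:9) {
        mid <- sqrt(lo * hi)
        if (measure(mid) > contrast_target) lo <- mid else hi <- mid
      }
      corr_len <- sqrt(lo * hi)
    }
  } else corr_len <- corr_len_vox
  img <- assemble(corr_len, white)
  if (noise) {
    img <- img + withr::with_seed(seed + 1L,
      array(stats::rnorm(prod(d), 0, cfg$t2_noise_frac * muscle_val), d))
  }
  out <- image_volume(img, tumor_mask$spacing)
  attr(out, "corr_len_vox") <- corr_len
  out
}

# ---------------------------------------------------------------------

#' Synthesize one complete patient
#'
#' Builds the tumor blob, voxelizes it independently on the T2, DWI and
#' ASL grids (mirroring per-sequence ROI delineation), synthesizes the
#' three acquisitions from the sampled ground-truth record and computes
#' the realized ground truth: features that the image generation can
#' only realize indirectly (surface area, which follows from volume and
#' sphericity; the emergent GLCM statistics; the projections of the
#' tri-exponential decay onto the simpler diffusion models) are replaced
#' by their noiseless image-level values, so that a noiseless
#' extraction round-trip is exact by construction.
#'
#' @param record One row of [sample_cohort()] (list or data.frame row).
#' @param cfg An [acquisition_config()].
#' @param seed RNG seed.
#' @param noise Logical noise switch.
#' @return Object of class `synthetic_patient`.
#' @export
synthesize_patient <- function(record, cfg = acquisition_config(),
                               seed = 1L, noise = TRUE) {
  rec <- as.list(record)
  # order tri-exponential compartments by decreasing coefficient; the
  # compartment labels of the fitted model are magnitude-ordered
  dvals <- c(rec$d1, rec$d2, rec$d3)
  fvals <- c(rec$f1, rec$f2, rec$f3)
  o <- order(dvals, decreasing = TRUE)
  rec[c("d1", "d2", "d3")] <- as.list(dvals[o])
  rec[c("f1", "f2", "f3")] <- as.list(fvals[o])

  # grids are enlarged automatically for tumors too big for the default
  # field of view (the blob must stay clear of the borders and of the
  # reference-muscle box)
  ctr_of <- function(dim, spacing) ((dim + 1) / 2) * spacing
  touches_border <- function(m) {
    d <- dim(m$data)
    any(m$data[c(1, d[1]), , ]) || any(m$data[, c(1, d[2]), ]) ||
      any(m$data[, , c(1, d[3])])
  }
  for (attempt in 1:4) {
    grow <- 1.3^(attempt - 1)
    t2_dim <- as.integer(round(cfg$t2_dim * grow))
    dwi_dim <- as.integer(round(cfg$dwi_dim * grow))
    asl_dim <- as.integer(round(cfg$asl_dim * grow))
    tumor_t2 <- synthesize_tumor_mask(rec$volume_mL, rec$sphericity,
                                      cfg$t2_spacing, t2_dim,
                                      seed = seed, clamp = TRUE)
    blob <- attr(tumor_t2, "blob")
    tumor_dwi <- voxelize_blob(blob, cfg$dwi_spacing, dwi_dim,
                               center_mm = ctr_of(dwi_dim, cfg$dwi_spacing))
    tumor_asl <- voxelize_blob(blob, cfg$asl_spacing, asl_dim,
                               center_mm = ctr_of(asl_dim, cfg$asl_spacing))
    muscle_t2 <- muscle_box_mask(cfg$t2_spacing, t2_dim)
    muscle_asl <- muscle_box_mask(cfg$asl_spacing, asl_dim)
    ok <- !any(muscle_t2$data & tumor_t2$data) &&
      !any(muscle_asl$data & tumor_asl$data) &&
      !touches_border(tumor_t2) && !touches_border(tumor_asl) &&
      abs(sum(tumor_t2$data) * prod(cfg$t2_spacing) / 1000 -
            rec$volume_mL) / rec$volume_mL < 0.1
    if (ok) break
    if (attempt == 4)
      stop("tumor does not fit the acquisition grid even after enlargement")
  }
  cfg <- utils::modifyList(cfg, list(t2_dim = t2_dim, dwi_dim = dwi_dim,
                                     asl_dim = asl_dim))

  t2 <- synthesize_t2(tumor_t2, muscle_t2, rec$rel_mean_signal, rec$cv,
                      contrast_target = rec$glcm_contrast, cfg = cfg,
                      seed = seed + 11L, noise = noise)
  t2_noiseless <- synthesize_t2(tumor_t2, muscle_t2, rec$rel_mean_signal,
                                rec$cv, contrast_target = rec$glcm_contrast,
                                cfg = cfg, seed = seed + 11L, noise = FALSE)
  muscle_flow <- rec$tbf_abs / rec$tbf_rel
  asl <- synthesize_asl(rec$tbf_abs, muscle_flow, tumor_asl, muscle_asl,
                        cfg = cfg, seed = seed + 23L, noise = noise)
  dwi <- synthesize_dwi(rec, tumor_dwi, cfg = cfg, seed = seed + 37L,
                        noise = noise)

  realized <- rec[feature_names()]
  mo <- measure_morphology(tumor_t2)
  realized$volume_mL <- mo$volume_mL
  realized$surface_cm2 <- mo$surface_cm2
  realized$sphericity <- mo$sphericity
  gl <- glcm_features(t2_noiseless, tumor_t2)
  realized$glcm_contrast <- gl[["contrast"]]
  realized$glcm_correlation <- gl[["correlation"]]
  realized$glcm_energy <- gl[["energy"]]
  realized$glcm_homogeneity <- gl[["homogeneity"]]
  s_true <- dwi_signal("triexp",
                       list(S0 = cfg$s0_dwi, f1 = rec$f1, f2 = rec$f2,
                            f3 = rec$f3, d1 = rec$d1, d2 = rec$d2,
                            d3 = rec$d3), cfg$b_values)
  proj <- diffusion_features_from_signal(cfg$b_values, s_true)
  # all 14 diffusion features become the model projections of the true
  # decay: the simpler models are deliberately mis-specified, and even
  # the matched tri-exponential fit is only identifiable when the
  # compartments are well separated (nearby D2/D3 pairs produce decays
  # that differ below any practical precision)
  for (f in names(proj))
    realized[[f]] <- proj[[f]]

  structure(list(
    id = rec$id %||% "patient",
    outcome = as.character(rec$outcome %||% NA_character_),
    clinical = list(t_stage = rec$t_stage, n_stage = rec$n_stage),
    truth = rec, truth_realized = realized,
    t2 = t2, t2_tumor_mask = tumor_t2, t2_muscle_mask = muscle_t2,
    dwi = dwi, dwi_tumor_mask = tumor_dwi,
    asl_control = asl$control, asl_label = asl$label,
    asl_tumor_mask = tumor_asl, asl_muscle_mask = muscle_asl,
    necrosis = NULL), class = "synthetic_patient")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient %s (%s), tumor %d T2 voxels>\n",
              x$id, x$outcome, sum(x$t2_tumor_mask$data)))
  invisible(x)
}

#' Synthesize a full cohort
#'
#' @param records Output of [sample_cohort()].
#' @param cfg An [acquisition_config()].
#' @param seed Master seed; per-patient seeds are derived from it.
#' @param noise Logical noise switch.
#' @param progress Print one dot per patient.
#' @return List of `synthetic_patient`s.
#' @export
synthesize_cohort <- function(records, cfg = acquisition_config(),
                              seed = 1L, noise = TRUE, progress = FALSE) {
  n <- nrow(records)
  seeds <- withr::with_seed(seed, sample.int(1e7, n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- synthesize_patient(records[i, ], cfg, seed = seeds[i],
                                   noise = noise)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  out
}
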