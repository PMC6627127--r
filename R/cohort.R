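#' The 27-feature roster
#'
#' Fixed, versioned order of the feature columns used throughout the
#' pipeline: 2 clinical (ordinal T- and N-stage), 3 morphological,
#' 6 intratumoral T2, 2 perfusion and 14 diffusion features.
#'
#' @return Character vector of the 27 feature names.
#' @export
feature_names <- function() {
  c("t_stage", "n_stage",
    "volume_mL", "surface_cm2", "sphericity",
    "rel_mean_signal", "cv", "glcm_contrast", "glcm_correlation",
    "glcm_energy", "glcm_homogeneity",
    "tbf_abs", "tbf_rel",
    "adc", "ivim_f", "ivim_dstar", "ivim_d", "dki_k", "dki_dk",
    "sem_alpha", "sem_ddc", "f1", "f2", "f3", "d1", "d2", "d3")
}

cont_features <- function() setdiff(feature_names(), c("t_stage", "n_stage"))

#' Group-conditional feature distribution
#'
#' Per-feature mean and SD of the 25 continuous features plus the T- and
#' N-stage contingency counts for one outcome group, used to calibrate
#' the synthetic cohort. [default_group_spec()] returns the published
#' calibration for the local-control and local-failure groups of the
#' study cohort (36 sinonasal squamous cell carcinoma patients treated
#' with superselective intra-arterial cisplatin plus radiotherapy).
#'
#' Units: volume mL; surface cm^2; TBF mL/100g/min; diffusion
#' coefficients x 1e-3 mm^2/s; fractions dimensionless.
#'
#' @param group `"control"` or `"failure"`.
#' @param mean,sd Named numeric vectors over [cont_features()].
#' @param t_stage_counts,n_stage_counts Integer contingency counts for
#'   T1-T4 and N0-N3.
#' @param correlation Optional feature correlation matrix (Gaussian
#'   copula over the continuous features); default `NULL` samples each
#'   feature independently, which reflects that only marginal
#'   distributions are published.
#' @return Object of class `group_spec`.
#' @export
group_spec <- function(group, mean, sd, t_stage_counts, n_stage_counts,
                       correlation = NULL) {
  feats <- cont_features()
  stopifnot(all(feats %in% names(mean)), all(feats %in% names(sd)))
  mean <- mean[feats]; sd <- sd[feats]
  if (any(sd < 0)) stop("feature SDs must be non-negative")
  dcoef <- c("adc", "ivim_dstar", "ivim_d", "dki_dk", "sem_ddc",
             "d1", "d2", "d3")
  if (any(mean[dcoef] <= 0))
    stop("all diffusion coefficient means must be positive")
  if (abs(sum(mean[c("f1", "f2", "f3")]) - 1) > 0.02)
    stop("tri-exponential fraction means must sum to 1 within 0.02")
  if (length(t_stage_counts) != 4L || length(n_stage_counts) != 4L ||
      any(c(t_stage_counts, n_stage_counts) < 0))
    stop("stage counts must be 4 non-negative values each")
  if (!is.null(correlation)) {
    if (!isSymmetric(unname(correlation)) ||
        nrow(correlation) != length(feats))
      stop("correlation must be a symmetric matrix over the continuous features")
  }
  structure(list(group = match.arg(group, c("control", "failure")),
                 mean = mean, sd = sd,
                 t_stage_counts = stats::setNames(t_stage_counts,
                                                  paste0("T", 1:4)),
                 n_stage_counts = stats::setNames(n_stage_counts,
                                                  paste0("N", 0:3)),
                 correlation = correlation),
            class = "group_spec")
}

#' @rdname group_spec
#' @export
default_group_spec <- function(group = c("control", "failure")) {
  group <- match.arg(group)
  ctrl_mean <- c(
    volume_mL = 25.3, surface_cm2 = 50.4, sphericity = 0.71,
    rel_mean_signal = 3.8, cv = 0.12, glcm_contrast = 35.1,
    glcm_correlation = 0.84, glcm_energy = 1.5e-3,
    glcm_homogeneity = 0.28, tbf_abs = 156.7, tbf_rel = 7.47,
    adc = 0.91, ivim_f = 0.16, ivim_dstar = 19.5, ivim_d = 0.75,
    dki_k = 0.73, dki_dk = 1.24, sem_alpha = 0.69, sem_ddc = 1.14,
    f1 = 0.14, f2 = 0.23, f3 = 0.62, d1 = 32.9, d2 = 1.03, d3 = 0.64)
  ctrl_sd <- c(
    volume_mL = 16.5, surface_cm2 = 18.7, sphericity = 0.08,
    rel_mean_signal = 0.6, cv = 0.02, glcm_contrast = 6,
    glcm_correlation = 0.02, glcm_energy = 0.3e-3,
    glcm_homogeneity = 0.03, tbf_abs = 32.9, tbf_rel = 0.83,
    adc = 0.1, ivim_f = 0.05, ivim_dstar = 7.5, ivim_d = 0.06,
    dki_k = 0.07, dki_dk = 0.14, sem_alpha = 0.07, sem_ddc = 0.12,
    f1 = 0.04, f2 = 0.04, f3 = 0.06, d1 = 7.8, d2 = 0.16, d3 = 0.07)
  fail_mean <- c(
    volume_mL = 34.3, surface_cm2 = 69.6, sphericity = 0.61,
    rel_mean_signal = 3.4, cv = 0.14, glcm_contrast = 41.3,
    glcm_correlation = 0.86, glcm_energy = 1.2e-3,
    glcm_homogeneity = 0.26, tbf_abs = 133.7, tbf_rel = 6.25,
    adc = 0.87, ivim_f = 0.16, ivim_dstar = 16.7, ivim_d = 0.73,
    dki_k = 0.76, dki_dk = 1.22, sem_alpha = 0.67, sem_ddc = 1.12,
    f1 = 0.13, f2 = 0.25, f3 = 0.61, d1 = 28.1, d2 = 0.92, d3 = 0.62)
  fail_sd <- c(
    volume_mL = 28.6, surface_cm2 = 29.7, sphericity = 0.11,
    rel_mean_signal = 0.6, cv = 0.04, glcm_contrast = 8.6,
    glcm_correlation = 0.03, glcm_energy = 0.4e-3,
    glcm_homogeneity = 0.03, tbf_abs = 29.3, tbf_rel = 1.22,
    adc = 0.13, ivim_f = 0.07, ivim_dstar = 5.7, ivim_d = 0.09,
    dki_k = 0.08, dki_dk = 0.19, sem_alpha = 0.08, sem_ddc = 0.17,
    f1 = 0.04, f2 = 0.05, f3 = 0.08, d1 = 6.5, d2 = 0.15, d3 = 0.1)
  if (group == "control")
    group_spec("control", ctrl_mean, ctrl_sd,
               t_stage_counts = c(0, 1, 10, 11),
               n_stage_counts = c(18, 2, 2, 0))
  else
    group_spec("failure", fail_mean, fail_sd,
               t_stage_counts = c(0, 0, 3, 11),
               n_stage_counts = c(12, 0, 2, 0))
}

# physical truncation applied after Gaussian sampling
truncate_features <- function(df) {
  clip <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)
  floor_c <- 1e-5  # x 1e-3 mm^2/s
  for (f in c("adc", "ivim_dstar", "ivim_d", "dki_dk", "sem_ddc",
              "d1", "d2", "d3"))
    df[[f]] <- clip(df[[f]], floor_c)
  for (f in c("ivim_f", "f1", "f2", "f3"))
    df[[f]] <- clip(df[[f]], 0.01, 0.97)
  fsum <- df$f1 + df$f2 + df$f3
  df$f1 <- df$f1 / fsum; df$f2 <- df$f2 / fsum; df$f3 <- df$f3 / fsum
  df$volume_mL <- clip(df$volume_mL, 2)
  df$surface_cm2 <- clip(df$surface_cm2, 5)
  df$sphericity <- clip(df$sphericity, 0.05, 0.995)
  df$rel_mean_signal <- clip(df$rel_mean_signal, 0.2)
  df$cv <- clip(df$cv, 0, 1)
  df$glcm_contrast <- clip(df$glcm_contrast, 0.01)
  df$glcm_correlation <- clip(df$glcm_correlation, -0.99, 0.99)
  df$glcm_energy <- clip(df$glcm_energy, 1e-4, 1)
  df$glcm_homogeneity <- clip(df$glcm_homogeneity, 0.02, 1)
  df$tbf_abs <- clip(df$tbf_abs, 1)
  df$tbf_rel <- clip(df$tbf_rel, 0.1)
  df$sem_alpha <- clip(df$sem_alpha, 0.3, 1)
  df$dki_k <- clip(df$dki_k, 0, 3)
  df
}

sample_group <- function(spec, n, prefix) {
  feats <- cont_features()
  p <- length(feats)
  if (is.null(spec$correlation)) {
    z <- matrix(stats::rnorm(n * p), n, p)
  } else {
    L <- chol(spec$correlation)
    z <- matrix(stats::rnorm(n * p), n, p) %*% L
  }
  x <- sweep(sweep(z, 2, spec$sd[feats], "*"), 2, spec$mean[feats], "+")
  colnames(x) <- feats
  df <- as.data.frame(x)
  df <- truncate_features(df)
  tp <- spec$t_stage_counts / sum(spec$t_stage_counts)
  np <- spec$n_stage_counts / sum(spec$n_stage_counts)
  df$t_stage <- sample(1:4, n, replace = TRUE, prob = tp)
  df$n_stage <- sample(0:3, n, replace = TRUE, prob = np)
  df$outcome <- spec$group
  df$id <- sprintf("%s%04d", prefix, seq_len(n))
  df[, c("id", "outcome", feature_names())]
}

#' Sample ground-truth feature records for a synthetic cohort
#'
#' Draws per-patient true feature values from the group-conditional
#' Gaussian distributions of the two [group_spec()]s, truncated to
#' physical ranges (tri-exponential fractions are clipped to
#' `[0.01, 0.97]` and renormalised to sum to 1; diffusion coefficients
#' are floored at 1e-5 x 1e-3 mm^2/s). T- and N-stages are sampled from
#' the group contingency counts. Deterministic under a fixed seed.
#'
#' @param control,failure [group_spec()]s for the two outcome groups.
#' @param n_per_group Named or length-2 vector `c(control, failure)`;
#'   the default 22/14 reproduces the study's outcome split.
#' @param seed Integer RNG seed.
#' @return `data.frame` with columns `id`, `outcome` and the 27 features.
#' @export
sample_cohort <- function(control = default_group_spec("control"),
                          failure = default_group_spec("failure"),
                          n_per_group = c(control = 22, failure = 14),
                          seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 2L || any(n_per_group < 1L))
    stop("n_per_group must give at least one patient per group")
  withr::with_seed(seed, {
    dc <- sample_group(control, n_per_group[1], "C")
    df <- sample_group(failure, n_per_group[2], "F")
    out <- rbind(dc, df)
    out$outcome <- factor(out$outcome, levels = c("control", "failure"))
    rownames(out) <- NULL
    out
  })
}
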