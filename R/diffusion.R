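#' Multi-b-value diffusion signal models
#'
#' Forward signal equations and ROI-level fitting for the five diffusion
#' models used throughout the pipeline: mono-exponential (ADC),
#' intravoxel incoherent motion (IVIM, bi-exponential), tri-exponential,
#' stretched-exponential (SEM) and diffusion kurtosis (DKI).
#'
#' All diffusion coefficients are expressed in the conventional
#' `x 1e-3 mm^2/s` units and b-values in s/mm^2; the unit conversion is
#' handled internally. The signal forms are
#' \itemize{
#'   \item mono: `S0 * exp(-b * ADC)`
#'   \item IVIM: `S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D))`
#'   \item tri-exponential: `S0 * (f1 exp(-b D1) + f2 exp(-b D2) + f3 exp(-b D3))`
#'     with `f1 + f2 + f3 = 1`
#'   \item SEM: `S0 * exp(-(b * DDC)^alpha)`
#'   \item DKI: `S0 * exp(-b * Dk + b^2 * Dk^2 * K / 6)`
#' }
#'
#' @name diffusion_models
NULL

DC <- 1e-3  # coefficients are carried as x 1e-3 mm^2/s

#' Acquisition b-value schedules
#'
#' The full 12-b-value schedule used for IVIM and tri-exponential fitting
#' and the reduced 6-value subset (b >= 200 plus b = 0, which suppresses
#' perfusion contamination) used for ADC, SEM and DKI.
#'
#' @return Numeric vector of b-values in s/mm^2.
#' @export
b_schedule_full <- function() {
  c(0, 10, 20, 30, 50, 80, 100, 200, 400, 800, 1000, 2000)
}

#' @rdname b_schedule_full
#' @export
b_schedule_reduced <- function() {
  c(0, 200, 400, 800, 1000, 2000)
}

#' Which b-value subset each model fits
#'
#' @param model One of `"mono"`, `"ivim"`, `"triexp"`, `"sem"`, `"dki"`.
#' @return Numeric vector of b-values the model is fitted on.
#' @export
b_policy <- function(model) {
  model <- match.arg(model, c("mono", "ivim", "triexp", "sem", "dki"))
  if (model %in% c("ivim", "triexp")) b_schedule_full() else
    b_schedule_reduced()
}

validate_dwi_params <- function(model, p) {
  bad <- function(msg) stop(sprintf("invalid %s parameters: %s", model, msg))
  if (any(!is.finite(unlist(p)))) bad("non-finite value")
  if (p[["S0"]] <= 0) bad("S0 must be positive")
  switch(model,
    mono = if (p[["adc"]] <= 0) bad("ADC must be positive"),
    ivim = {
      if (p[["f"]] < 0 || p[["f"]] > 1) bad("f must lie in [0, 1]")
      if (p[["d"]] <= 0) bad("D must be positive")
      if (p[["dstar"]] < p[["d"]]) bad("D* must be >= D")
    },
    triexp = {
      f <- c(p[["f1"]], p[["f2"]], p[["f3"]])
      if (any(f < 0)) bad("fractions must be non-negative")
      if (abs(sum(f) - 1) > 1e-6) bad("fractions must sum to 1")
      d <- c(p[["d1"]], p[["d2"]], p[["d3"]])
      if (any(d <= 0)) bad("coefficients must be positive")
      if (!(d[1] > d[2] && d[2] > d[3])) bad("need D1 > D2 > D3")
    },
    sem = {
      if (p[["alpha"]] <= 0 || p[["alpha"]] > 1) bad("alpha must be in (0, 1]")
      if (p[["ddc"]] <= 0) bad("DDC must be positive")
    },
    dki = {
      if (p[["k"]] < 0) bad("K must be non-negative")
      if (p[["dk"]] <= 0) bad("Dk must be positive")
    })
  invisible(TRUE)
}

#' Forward diffusion signal
#'
#' @param model Model name (see [b_policy()]).
#' @param params Named list/vector of model parameters (see
#'   [diffusion_models]); coefficients in x 1e-3 mm^2/s.
#' @param b b-values in s/mm^2.
#' @return Signal vector, same length as `b`.
#' @examples
#' dwi_signal("mono", list(S0 = 100, adc = 0.91), b_schedule_reduced())
#' @export
dwi_signal <- function(model, params, b) {
  model <- match.arg(model, c("mono", "ivim", "triexp", "sem", "dki"))
  p <- as.list(params)
  validate_dwi_params(model, p)
  S0 <- p$S0
  switch(model,
    mono = S0 * exp(-b * p$adc * DC),
    ivim = S0 * (p$f * exp(-b * p$dstar * DC) +
                   (1 - p$f) * exp(-b * p$d * DC)),
    triexp = S0 * (p$f1 * exp(-b * p$d1 * DC) + p$f2 * exp(-b * p$d2 * DC) +
                     p$f3 * exp(-b * p$d3 * DC)),
    sem = S0 * exp(-(b * p$ddc * DC)^p$alpha),
    dki = S0 * exp(-b * p$dk * DC + b^2 * (p$dk * DC)^2 * p$k / 6))
}

fit_result <- function(model, params, b, signal) {
  pred <- dwi_signal(model, params, b)
  structure(list(model = model, params = params,
                 rss = sum((signal - pred)^2),
                 converged = TRUE, b_values = b),
            class = "dwi_fit")
}

#' @export
print.dwi_fit <- function(x, ...) {
  cat(sprintf("<%s fit, rss %.3g, %s>\n", x$model, x$rss,
              paste(sprintf("%s=%.4g", names(x$params),
                            unlist(x$params)), collapse = " ")))
  invisible(x)
}

# log-linear ADC fit (closed form)
fit_mono <- function(b, s) {
  co <- stats::lm.fit(cbind(1, b), log(s))$coefficients
  params <- list(S0 = exp(co[[1]]), adc = max(-co[[2]] / DC, 1e-5))
  fit_result("mono", params, b, s)
}

# DKI is linear in (b, b^2) on the log scale, so solved in closed form;
# the quadratic coefficient maps to K = 6 c2 / Dk^2.
fit_dki <- function(b, s) {
  co <- stats::lm.fit(cbind(1, b, b^2), log(s))$coefficients
  dk <- max(-co[[2]], 1e-8)
  k <- max(6 * co[[3]] / dk^2, 0)
  params <- list(S0 = exp(co[[1]]), k = min(k, 3), dk = dk / DC)
  fit_result("dki", params, b, s)
}

# Bounded Levenberg-Marquardt with a fall-back that never throws: on
# failure the initial (segmented) estimate is returned flagged as
# non-converged.
nls_refine <- function(resid_fn, start, lower, upper, jitter_starts = 2L,
                       seed = 7L) {
  eval_rss <- function(p) sum(resid_fn(p)^2)
  starts <- list(unlist(start))
  if (jitter_starts > 0) {
    jit <- withr::with_seed(seed, {
      lapply(seq_len(jitter_starts), function(i)
        unlist(start) * exp(stats::rnorm(length(start), 0, 0.08)))
    })
    starts <- c(starts, lapply(jit, function(p) pmin(pmax(p, lower), upper)))
  }
  best <- list(par = unlist(start), rss = eval_rss(unlist(start)),
               converged = FALSE)
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(res)) {
      rss <- sum(res$fvec^2)
      if (rss < best$rss) {
        best <- list(par = res$par, rss = rss,
                     converged = res$info %in% 1:4)
      }
    }
  }
  best
}

ivim_bounds <- list(lower = c(S0 = 1e-8, f = 0, dstar = 3, d = 0.05),
                    upper = c(S0 = Inf, f = 1, dstar = 300, d = 3))

fit_ivim <- function(b, s, seed = 7L) {
  # segmented initialisation: tissue compartment from b >= 200, perfusion
  # from the low-b excess signal
  hi <- b >= 200
  co <- stats::lm.fit(cbind(1, b[hi]), log(s[hi]))$coefficients
  d0 <- min(max(-co[[2]] / DC, 0.06), 2.9)
  s0t <- exp(co[[1]])
  S0 <- s[b == 0][1]
  if (!length(S0) || is.na(S0)) S0 <- max(s)
  f0 <- min(max(1 - s0t / S0, 1e-3), 0.6)
  excess <- s - s0t * exp(-b * d0 * DC)
  lo <- b <= 100 & b > 0 & excess > 0
  dstar0 <- if (sum(lo) >= 2) {
    co2 <- stats::lm.fit(cbind(1, b[lo]), log(excess[lo]))$coefficients
    min(max(-co2[[2]] / DC, 3.5), 290)
  } else 20
  start <- c(S0 = S0, f = f0, dstar = dstar0, d = d0)
  resid_fn <- function(p) {
    dwi_signal("ivim", list(S0 = p[["S0"]], f = p[["f"]],
                            dstar = max(p[["dstar"]], p[["d"]]),
                            d = p[["d"]]), b) - s
  }
  ref <- nls_refine(resid_fn, start, ivim_bounds$lower, ivim_bounds$upper,
                    seed = seed)
  p <- ref$par
  params <- list(S0 = p[["S0"]], f = p[["f"]],
                 dstar = max(p[["dstar"]], p[["d"]]), d = p[["d"]])
  out <- fit_result("ivim", params, b, s)
  out$converged <- ref$converged
  out
}

# Tri-exponential fit, cascaded: the two slow compartments are estimated
# from b >= 200 (perfusion has decayed), the perfusion compartment from
# the remaining low-b signal, then everything is refined jointly. The
# fractions are parameterised as (f1, q) with f2 = q (1 - f1),
# f3 = (1 - q)(1 - f1) so the simplex constraint is a box, and D3 as a
# ratio of D2 so the ordering D2 > D3 is structural.
fit_triexp <- function(b, s, seed = 7L) {
  S0 <- s[b == 0][1]
  if (!length(S0) || is.na(S0)) S0 <- max(s)
  # stage 1: bounded bi-exponential fit of the tissue compartments on
  # b >= 200 (perfusion has decayed there), itself multi-started from a
  # crude log-linear split
  hb <- b >= 200
  co <- stats::lm.fit(cbind(1, b[hb & b >= 800]),
                      log(s[hb & b >= 800]))$coefficients
  d3_0 <- min(max(-co[[2]] / DC, 0.06), 1.15)
  a3_0 <- exp(co[[1]])
  bi_resid <- function(p) {
    p[["a2"]] * exp(-b[hb] * p[["d2"]] * DC) +
      p[["a3"]] * exp(-b[hb] * p[["d3"]] * DC) - s[hb]
  }
  bi_best <- NULL
  for (ratio in c(1.8, 3, 6)) {
    st <- c(a2 = max(0.25 * a3_0, 1e-6), d2 = min(ratio * d3_0, 2.9),
            a3 = a3_0, d3 = d3_0)
    r <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = bi_resid,
                         lower = c(1e-8, 0.3, 1e-8, 0.05),
                         upper = c(Inf, 3, Inf, 1.2),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 150, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(r) && (is.null(bi_best) || sum(r$fvec^2) < bi_best$rss))
      bi_best <- list(par = r$par, rss = sum(r$fvec^2))
  }
  if (!is.null(bi_best)) {
    pp <- bi_best$par
    if (pp[["d2"]] < pp[["d3"]])  # keep magnitude order
      pp <- c(a2 = pp[["a3"]], d2 = pp[["d3"]], a3 = pp[["a2"]],
              d3 = pp[["d2"]])
    a2_0 <- pp[["a2"]]; d2_0 <- pp[["d2"]]
    a3_0 <- pp[["a3"]]; d3_0 <- pp[["d3"]]
  } else {
    a2_0 <- 0.3 * a3_0; d2_0 <- 1.5 * d3_0
  }
  # stage 2: perfusion compartment from the low-b excess
  f1_0 <- min(max(1 - (a2_0 + a3_0) / S0, 0.02), 0.5)
  excess <- s - a2_0 * exp(-b * d2_0 * DC) - a3_0 * exp(-b * d3_0 * DC)
  lo <- b <= 100 & b > 0 & excess > 0
  d1_0 <- if (sum(lo) >= 2) {
    co1 <- stats::lm.fit(cbind(1, b[lo]), log(excess[lo]))$coefficients
    min(max(-co1[[2]] / DC, 3.5), 290)
  } else 30
  f2_0 <- min(max(a2_0 / S0, 0.02), 0.9)
  q0 <- min(max(f2_0 / (1 - f1_0), 0.02), 0.95)
  start <- c(S0 = S0, f1 = f1_0, q = q0, d1 = d1_0,
             d2 = min(max(d2_0, 0.31), 2.99),
             r3 = min(max(d3_0 / d2_0, 0.06), 0.9))
  lower <- c(S0 = 1e-8, f1 = 1e-3, q = 1e-3, d1 = 3, d2 = 0.3, r3 = 0.05)
  upper <- c(S0 = Inf, f1 = 0.7, q = 0.97, d1 = 300, d2 = 3, r3 = 0.92)
  to_params <- function(p) {
    f1 <- p[["f1"]]; q <- p[["q"]]
    list(S0 = p[["S0"]], f1 = f1, f2 = q * (1 - f1),
         f3 = (1 - q) * (1 - f1),
         d1 = max(p[["d1"]], 1.05 * p[["d2"]]), d2 = p[["d2"]],
         d3 = max(p[["r3"]] * p[["d2"]], 0.05))
  }
  resid_fn <- function(p) dwi_signal("triexp", to_params(p), b) - s
  ref <- nls_refine(resid_fn, start, lower, upper, jitter_starts = 3L,
                    seed = seed)
  out <- fit_result("triexp", to_params(ref$par), b, s)
  out$converged <- ref$converged
  out
}

fit_sem <- function(b, s, seed = 7L) {
  S0 <- s[b == 0][1]
  if (!length(S0) || is.na(S0)) S0 <- max(s)
  # closed-form initialisation: log(-log(S/S0)) is linear in log(b)
  pos <- b > 0 & s < S0
  ll <- log(-log(s[pos] / S0))
  co <- stats::lm.fit(cbind(1, log(b[pos])), ll)$coefficients
  a0 <- min(max(co[[2]], 0.35), 1)
  ddc0 <- min(max(exp(co[[1]] / a0) / DC, 0.06), 4.9)
  start <- c(S0 = S0, alpha = a0, ddc = ddc0)
  lower <- c(S0 = 1e-8, alpha = 0.3, ddc = 0.05)
  upper <- c(S0 = Inf, alpha = 1, ddc = 5)
  resid_fn <- function(p)
    dwi_signal("sem", list(S0 = p[["S0"]], alpha = p[["alpha"]],
                           ddc = p[["ddc"]]), b) - s
  ref <- nls_refine(resid_fn, start, lower, upper, seed = seed)
  out <- fit_result("sem", as.list(ref$par), b, s)
  out$converged <- ref$converged
  out
}

#' Fit a diffusion model to an ROI-mean signal
#'
#' ADC and DKI are solved in closed form by (log-)linear regression; IVIM
#' and the tri-exponential model use a segmented initialisation followed
#' by bounded joint Levenberg-Marquardt refinement with multi-start; SEM
#' uses a log-log linearisation followed by bounded refinement. A fit
#' never throws on non-convergence: the best parameters so far are
#' returned with `converged = FALSE`.
#'
#' @param model Model name.
#' @param b b-values in s/mm^2 (should match [b_policy()] for the model).
#' @param signal Positive ROI-mean signal, same length as `b`.
#' @param seed Seed for the multi-start jitter (fixed default for
#'   reproducibility).
#' @return A `dwi_fit`: list with `model`, `params`, `rss`, `converged`.
#' @examples
#' b <- b_schedule_reduced()
#' s <- dwi_signal("mono", list(S0 = 100, adc = 0.91), b)
#' fit_dwi("mono", b, s)$params$adc
#' @export
fit_dwi <- function(model, b, signal, seed = 7L) {
  model <- match.arg(model, c("mono", "ivim", "triexp", "sem", "dki"))
  b <- as.numeric(b); signal <- as.numeric(signal)
  if (length(b) != length(signal)) stop("b and signal lengths differ")
  if (any(signal <= 0)) stop("signal must be positive")
  switch(model,
    mono = fit_mono(b, signal),
    dki = fit_dki(b, signal),
    ivim = fit_ivim(b, signal, seed),
    triexp = fit_triexp(b, signal, seed),
    sem = fit_sem(b, signal, seed))
}

#' ROI-mean signal of a DWI series
#'
#' The tumor ROI drawn on the b = 0 image is applied to every b-value
#' frame, and the mean in-ROI signal per b-value is returned (voxels in
#' `exclude`, e.g. necrosis, are dropped).
#'
#' @param dwi A `dwi_series`.
#' @param mask `roi_mask` aligned to the DWI geometry.
#' @param exclude Optional exclusion `roi_mask`.
#' @return Numeric vector of per-b ROI means.
#' @export
roi_mean_signal <- function(dwi, mask, exclude = NULL) {
  if (!identical(dim(dwi$data)[1:3], dim(mask$data)))
    stop("mask not aligned to DWI geometry")
  keep <- mask$data
  if (!is.null(exclude)) keep <- keep & !exclude$data
  if (!any(keep)) stop("mask is empty (after exclusions)")
  vapply(seq_along(dwi$b_values),
         function(i) mean(dwi$data[, , , i][keep]), numeric(1))
}

#' Extract the 14 diffusion features of the feature roster
#'
#' Runs all five model fits on the ROI-mean signal with each model's
#' b-value subset and returns the named diffusion features.
#'
#' @inheritParams roi_mean_signal
#' @param seed Multi-start jitter seed passed to the nonlinear fits.
#' @return Named numeric vector with elements `adc`, `ivim_f`,
#'   `ivim_dstar`, `ivim_d`, `dki_k`, `dki_dk`, `sem_alpha`, `sem_ddc`,
#'   `f1`, `f2`, `f3`, `d1`, `d2`, `d3`.
#' @export
extract_diffusion_features <- function(dwi, mask, exclude = NULL, seed = 7L) {
  s_all <- roi_mean_signal(dwi, mask, exclude)
  feats <- diffusion_features_from_signal(dwi$b_values, s_all, seed)
  feats
}

# shared by extraction and by the synthesiser when computing the realized
# (model-projected) ground truth of a noiseless patient
diffusion_features_from_signal <- function(b, s, seed = 7L) {
  sub <- b %in% b_schedule_reduced()
  if (sum(sub) < 4) sub <- rep(TRUE, length(b))
  m <- fit_dwi("mono", b[sub], s[sub], seed)$params
  iv <- fit_dwi("ivim", b, s, seed)$params
  tr <- fit_dwi("triexp", b, s, seed)$params
  se <- fit_dwi("sem", b[sub], s[sub], seed)$params
  dk <- fit_dwi("dki", b[sub], s[sub], seed)$params
  c(adc = m$adc, ivim_f = iv$f, ivim_dstar = iv$dstar, ivim_d = iv$d,
    dki_k = dk$k, dki_dk = dk$dk, sem_alpha = se$alpha, sem_ddc = se$ddc,
    f1 = tr$f1, f2 = tr$f2, f3 = tr$f3, d1 = tr$d1, d2 = tr$d2, d3 = tr$d3)
}
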