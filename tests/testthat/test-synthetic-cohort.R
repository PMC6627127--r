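test_that("group specs validate their invariants", {
  sp <- default_group_spec("control")
  expect_s3_class(sp, "group_spec")
  expect_lt(abs(sum(sp$mean[c("f1", "f2", "f3")]) - 1), 0.02)
  bad_sd <- sp$sd; bad_sd["adc"] <- -1
  expect_error(group_spec("control", sp$mean, bad_sd,
                          sp$t_stage_counts, sp$n_stage_counts),
               "non-negative")
  bad_mean <- sp$mean; bad_mean["f2"] <- 0.5
  expect_error(group_spec("control", bad_mean, sp$sd,
                          sp$t_stage_counts, sp$n_stage_counts),
               "sum to 1")
})

test_that("sampling is deterministic and respects group sizes", {
  a <- sample_cohort(seed = 5)
  b <- sample_cohort(seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 36L)
  expect_equal(as.vector(table(a$outcome)), c(22L, 14L))
  expect_identical(colnames(a), c("id", "outcome", feature_names()))
  expect_false(identical(a, sample_cohort(seed = 6)))
  expect_error(sample_cohort(n_per_group = c(0, 5)), "at least one")
})

test_that("zero-SD spec collapses every patient onto the group mean", {
  sp <- default_group_spec("control")
  sp0 <- group_spec("control", sp$mean, sp$sd * 0, sp$t_stage_counts,
                    sp$n_stage_counts)
  tbl <- sample_cohort(sp0, default_group_spec("failure"),
                       n_per_group = c(5, 1), seed = 1)
  ctrl <- tbl[tbl$outcome == "control", ]
  for (f in setdiff(cont_features(), c("f1", "f2", "f3")))
    expect_equal(stats::var(ctrl[[f]]), 0, info = f)
  # fractions are renormalised from 0.99 to exactly 1
  expect_equal(unique(ctrl$f1 + ctrl$f2 + ctrl$f3), 1)
})

test_that("sample means calibrate to the group targets", {
  # relative TBF within 3 standard errors at large n
  tbl <- sample_cohort(n_per_group = c(1e5, 1), seed = 7)
  ctrl <- tbl[tbl$outcome == "control", ]
  se <- 0.83 / sqrt(1e5)
  expect_lt(abs(mean(ctrl$tbf_rel) - 7.47), 3 * se)
  # all features within 4 SE at n = 1e4 per group. The sampler clips
  # draws to physical ranges and renormalises the tri-exponential
  # fraction triple, which shifts a few means away from the raw
  # targets; the comparison target is therefore the closed-form mean
  # of the clipped Gaussian (an independent oracle), and the
  # renormalised fractions for f1-f3.
  clipped_mean <- function(mu, sd, lo = -Inf, hi = Inf) {
    if (sd == 0) return(min(max(mu, lo), hi))
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    lo0 <- if (is.finite(lo)) lo * stats::pnorm(a) else 0
    hi0 <- if (is.finite(hi)) hi * (1 - stats::pnorm(b)) else 0
    lo0 + hi0 + mu * (stats::pnorm(b) - stats::pnorm(a)) -
      sd * (stats::dnorm(b) - stats::dnorm(a))
  }
  clips <- list(volume_mL = c(2, Inf), surface_cm2 = c(5, Inf),
                sphericity = c(0.05, 0.995), rel_mean_signal = c(0.2, Inf),
                cv = c(0, 1), glcm_contrast = c(0.01, Inf),
                glcm_correlation = c(-0.99, 0.99),
                glcm_energy = c(1e-4, 1), glcm_homogeneity = c(0.02, 1),
                tbf_abs = c(1, Inf), tbf_rel = c(0.1, Inf),
                sem_alpha = c(0.3, 1), dki_k = c(0, 3),
                ivim_f = c(0.01, 0.97))
  tbl <- sample_cohort(n_per_group = c(1e4, 1e4), seed = 11)
  for (g in c("control", "failure")) {
    spec <- default_group_spec(g)
    rows <- tbl[tbl$outcome == g, ]
    fsum <- sum(spec$mean[c("f1", "f2", "f3")])
    for (f in cont_features()) {
      se <- max(spec$sd[f], 1e-12) / 100
      target <- if (f %in% c("f1", "f2", "f3")) spec$mean[f] / fsum
      else if (f %in% names(clips))
        clipped_mean(spec$mean[f], spec$sd[f], clips[[f]][1],
                     clips[[f]][2])
      else spec$mean[f]
      slack <- if (f %in% c("f1", "f2", "f3")) 0.0015 else 1e-9
      expect_lt(abs(mean(rows[[f]]) - target), 4 * se + slack,
                label = paste(g, f))
    }
    # stage distributions match the contingency proportions
    tprop <- spec$t_stage_counts / sum(spec$t_stage_counts)
    expect_lt(max(abs(prop.table(table(factor(rows$t_stage, 1:4))) -
                        tprop)), 0.02)
  }
})

test_that("physical truncation holds on extreme draws", {
  sp <- default_group_spec("failure")
  wide <- group_spec("failure", sp$mean, sp$sd * 6, sp$t_stage_counts,
                     sp$n_stage_counts)
  tbl <- sample_cohort(default_group_spec("control"), wide,
                       n_per_group = c(1, 2000), seed = 3)
  rows <- tbl[tbl$outcome == "failure", ]
  expect_true(all(rows$f1 + rows$f2 + rows$f3 > 1 - 1e-9))
  expect_true(all(rows$d2 > 0 & rows$d3 > 0 & rows$adc > 0))
  expect_true(all(rows$sem_alpha <= 1 & rows$sem_alpha >= 0.3))
  expect_true(all(rows$sphericity <= 0.995 & rows$sphericity > 0))
  expect_true(all(rows$dki_k >= 0))
})

test_that("tumor mask synthesis meets volume and sphericity targets", {
  m <- synthesize_tumor_mask(34.3, 0.61, c(1, 1, 1), c(76, 76, 76),
                             seed = 3)
  mo <- measure_morphology(m)
  expect_lt(abs(mo$volume_mL - 34.3) / 34.3, 0.05)
  expect_lt(abs(mo$sphericity - 0.61), 0.05)
  # a sphericity-1 target yields a digital ball
  mb <- synthesize_tumor_mask(30, 1.0, c(1, 1, 1), c(52, 52, 52),
                              seed = 3)
  expect_gte(measure_morphology(mb)$sphericity, 0.95)
  # determinism
  expect_identical(
    synthesize_tumor_mask(20, 0.7, c(1.5, 1.5, 1.5), c(40, 40, 28),
                          seed = 9)$data,
    synthesize_tumor_mask(20, 0.7, c(1.5, 1.5, 1.5), c(40, 40, 28),
                          seed = 9)$data)
  # infeasibility errors
  expect_error(synthesize_tumor_mask(34.3, 0.2, c(1, 1, 1),
                                     c(76, 76, 76), seed = 3),
               "infeasible")
  expect_error(synthesize_tumor_mask(0.05, 0.8, c(3.59, 3.59, 5),
                                     c(20, 20, 10), seed = 1),
               "50 voxels")
})

test_that("noiseless DWI synthesis equals the forward model", {
  cfg <- small_cfg()
  rec <- list(f1 = 0.14, f2 = 0.23, f3 = 0.63, d1 = 32.9, d2 = 1.03,
              d3 = 0.64)
  mask <- roi_mask(array(FALSE, cfg$dwi_dim), cfg$dwi_spacing)
  mask$data[6:12, 6:12, 4:7] <- TRUE
  dwi <- synthesize_dwi(rec, mask, cfg, seed = 1, noise = FALSE)
  expect_equal(dwi$data[6, 6, 4, 1], cfg$s0_dwi)  # b = 0 gives S0
  s <- roi_mean_signal(dwi, mask)
  expect_equal(s, dwi_signal("triexp", c(list(S0 = cfg$s0_dwi), rec),
                             cfg$b_values), tolerance = 1e-12)
})

test_that("noisy DWI converges to the noiseless forward mean", {
  cfg <- small_cfg()
  rec <- list(f1 = 0.14, f2 = 0.23, f3 = 0.63, d1 = 32.9, d2 = 1.03,
              d3 = 0.64)
  mask <- roi_mask(array(TRUE, cfg$dwi_dim), cfg$dwi_spacing)  # 3240 vox
  dwi <- synthesize_dwi(rec, mask, cfg, seed = 2, noise = TRUE)
  s_true <- dwi_signal("triexp", c(list(S0 = cfg$s0_dwi), rec),
                       cfg$b_values)
  s_obs <- roi_mean_signal(dwi, mask)
  # Rician noise biases the mean upward by ~sigma^2/(2 S); allow 1%
  # where the signal is strong
  strong <- s_true > 20
  expect_true(all(abs(s_obs[strong] - s_true[strong]) / s_true[strong]
                  < 0.01))
  # reproducibility
  dwi2 <- synthesize_dwi(rec, mask, cfg, seed = 2, noise = TRUE)
  expect_identical(dwi$data, dwi2$data)
})

test_that("whole-patient synthesis round-trips through extraction", {
  cfg <- small_cfg()
  rec <- sample_cohort(seed = 8)[3, ]
  p <- synthesize_patient(rec, cfg, seed = 31, noise = FALSE)
  fv <- extract_features(p)
  tr <- unlist(p$truth_realized)[names(fv)]
  tol <- ifelse(names(fv) %in% c("sphericity", "surface_cm2",
                                 "glcm_contrast", "glcm_correlation",
                                 "glcm_energy", "glcm_homogeneity"),
                0.05, 0.01)
  rel <- abs(fv - tr) / pmax(abs(tr), 1e-9)
  expect_true(all(rel <= tol),
              info = paste(names(fv)[rel > tol], collapse = ", "))
  # the realized record keeps sampled values where generation is exact
  expect_equal(p$truth_realized$tbf_abs, rec$tbf_abs)
  expect_equal(p$truth_realized$cv, rec$cv)
})

test_that("cohort writing and reading round-trips losslessly", {
  cfg <- small_cfg()
  recs <- sample_cohort(n_per_group = c(1, 1), seed = 2)
  pats <- synthesize_cohort(recs, cfg, seed = 14, noise = TRUE)
  dir <- withr::local_tempdir()
  man <- write_cohort(pats, dir)
  expect_equal(man$n_patients, 2L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  back <- read_cohort(dir)
  expect_equal(length(back), 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$id, pats[[i]]$id)
    expect_equal(back[[i]]$t2$data, pats[[i]]$t2$data, tolerance = 1e-6)
    expect_equal(back[[i]]$dwi$data, pats[[i]]$dwi$data,
                 tolerance = 1e-6)
    expect_identical(back[[i]]$t2_tumor_mask$data,
                     pats[[i]]$t2_tumor_mask$data)
    expect_equal(unlist(back[[i]]$truth_realized[cont_features()]),
                 unlist(pats[[i]]$truth_realized[cont_features()]),
                 tolerance = 1e-9)
  }
  # a missing file is caught by manifest validation
  file.remove(file.path(dir, pats[[1]]$id, "t2.nii.gz"))
  expect_error(read_cohort(dir), "missing file")
})
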