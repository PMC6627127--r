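# shared fixtures built in code

# digital ball mask: radius in mm on an isotropic/anisotropic grid
make_ball_mask <- function(radius, spacing = c(1, 1, 1), pad = 6) {
  half <- radius / spacing
  dims <- as.integer(2 * ceiling(half) + 2 * pad)
  ctr <- (dims + 1) / 2
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  d2 <- ((g$x - ctr[1]) * spacing[1])^2 + ((g$y - ctr[2]) * spacing[2])^2 +
    ((g$z - ctr[3]) * spacing[3])^2
  roi_mask(array(d2 <= radius^2, dims), spacing)
}

make_cube_mask <- function(side_vox, spacing = c(1, 1, 1), pad = 4) {
  dims <- rep(side_vox + 2L * pad, 3L)
  m <- array(FALSE, dims)
  idx <- (pad + 1L):(pad + side_vox)
  m[idx, idx, idx] <- TRUE
  roi_mask(m, spacing)
}

# Table-calibrated control-group mean diffusion parameters
control_means <- function() {
  sp <- default_group_spec("control")
  as.list(sp$mean)
}

# small geometry for fast image-level tests
small_cfg <- function(...) {
  acquisition_config(t2_dim = c(40, 40, 26), dwi_dim = c(18, 18, 10),
                     asl_dim = c(20, 20, 10), ...)
}

# Monte-Carlo Bayes-rate oracle on the generating distributions:
# classifies draws from the sampler by exact group log-likelihood
# (independent Gaussian marginals plus stage contingencies and the
# 22/14 class prior)
bayes_rate_mc <- function(n = 20000, seed = 123) {
  sc <- default_group_spec("control")
  sf <- default_group_spec("failure")
  pri <- c(control = 22 / 36, failure = 14 / 36)
  tbl <- sample_cohort(sc, sf,
                       n_per_group = round(n * pri), seed = seed)
  feats <- setdiff(feature_names(), c("t_stage", "n_stage"))
  loglik <- function(spec) {
    l <- rep(0, nrow(tbl))
    for (f in feats)
      l <- l + stats::dnorm(tbl[[f]], spec$mean[f],
                            max(spec$sd[f], 1e-12), log = TRUE)
    tp <- spec$t_stage_counts / sum(spec$t_stage_counts)
    np <- spec$n_stage_counts / sum(spec$n_stage_counts)
    l + log(tp[tbl$t_stage]) + log(np[tbl$n_stage + 1])
  }
  lc <- loglik(sc) + log(pri["control"])
  lf <- loglik(sf) + log(pri["failure"])
  pred <- ifelse(lf > lc, "failure", "control")
  mean(pred == as.character(tbl$outcome))
}

# two-class table with a few informative and pure-noise features
make_sep_table <- function(n = 36, seed = 1, d = c(1.5, 1.2, 1.0),
                           noise_features = 3) {
  withr::with_seed(seed, {
    y <- factor(rep(c("control", "failure"), length.out = n),
                levels = c("control", "failure"))
    x <- matrix(stats::rnorm(n * (length(d) + noise_features)), n)
    for (j in seq_along(d))
      x[y == "failure", j] <- x[y == "failure", j] + d[j]
    colnames(x) <- c(paste0("inf", seq_along(d)),
                     if (noise_features > 0)
                       paste0("noise", seq_len(noise_features)))
    cbind(data.frame(outcome = y), as.data.frame(x))
  })
}
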