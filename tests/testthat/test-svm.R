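test_that("make_folds partitions patients exactly", {
  folds <- make_folds(36, 9, seed = 2)
  expect_length(folds, 9L)
  expect_true(all(lengths(folds) == 4L))
  expect_setequal(unlist(folds), 1:36)
  expect_identical(folds, make_folds(36, 9, seed = 2))
  expect_false(identical(folds, make_folds(36, 9, seed = 3)))
  expect_error(make_folds(35, 9, seed = 1), "equal folds")
  # stratified folds balance labels as far as possible
  labs <- factor(rep(c("a", "b"), c(27, 9)))
  fs <- make_folds(36, 9, seed = 1, stratified = TRUE, labels = labs)
  per_fold_b <- vapply(fs, function(f) sum(labs[f] == "b"), integer(1))
  expect_true(all(per_fold_b == 1L))
})

test_that("grid search matches a brute-force enumeration", {
  tbl <- make_sep_table(seed = 5)
  x <- as.matrix(tbl[-1]); y <- tbl$outcome
  cfg <- svm_config(gamma_exp = seq(-8, 2, 2), cost_exp = seq(-2, 6, 2))
  inner <- list(qmripredict:::inner_partition(36, 4, 7, labels = y))
  gs <- grid_search(x, y, cfg, inner_folds = inner)
  expect_equal(dim(gs$surface), c(6L, 5L))
  # independent brute force over the same grid
  brute <- expand.grid(gamma = cfg$gamma, cost = cfg$cost)
  brute$acc <- mapply(function(g, c) {
    correct <- 0
    for (f in inner[[1]]) {
      m <- e1071::svm(x[-f, ], y[-f], type = "C-classification",
                      kernel = "radial", gamma = g, cost = c,
                      scale = FALSE)
      correct <- correct + sum(predict(m, x[f, , drop = FALSE]) == y[f])
    }
    correct / 36
  }, brute$gamma, brute$cost)
  expect_equal(max(brute$acc), gs$accuracy)
  # tie-break: smallest cost, then smallest gamma, among maxima
  best <- brute[brute$acc == max(brute$acc), ]
  best <- best[order(best$cost, best$gamma), ][1, ]
  expect_equal(gs$gamma, best$gamma)
  expect_equal(gs$cost, best$cost)
  # a single-point grid returns that point
  one <- svm_config(gamma_exp = -2, cost_exp = 3)
  gs1 <- grid_search(x, y, one, inner_folds = inner)
  expect_equal(gs1$gamma, 2^-2)
  expect_equal(gs1$cost, 2^3)
})

test_that("default grids span the full published exponent ranges", {
  cfg <- svm_config()
  expect_equal(length(cfg$gamma), 31L)
  expect_equal(length(cfg$cost), 21L)
  expect_equal(range(cfg$gamma), c(2^-20, 2^10))
  expect_equal(range(cfg$cost), c(2^-10, 2^10))
})

test_that("elimination ranks a constant feature last", {
  tbl <- make_sep_table(seed = 3, d = 1.5, noise_features = 0)
  tbl$flat <- 5
  x <- as.matrix(tbl[-1]); y <- tbl$outcome
  x[, "flat"] <- 0  # standardized constant
  el <- backward_eliminate(x, y, gamma = 0.25, cost = 1,
                           svm_config(select_reps = 2L), seed = 2)
  expect_equal(el$trace$feature[1], "flat")  # eliminated first
  expect_equal(unname(el$ranking["flat"]), 2L)
  expect_equal(nrow(el$trace), 2L)  # trace covers every feature
  expect_setequal(el$trace$feature, colnames(x))
})

test_that("confusion metrics match hand calculations and flag degeneracy", {
  # brute-force all n = 32 confusion matrices against the published
  # fold-1 training row (sens 1, spec 0.92, ppv 0.95, npv 1, acc 0.97):
  # exactly two integer solutions round to it, (19,1,12,0) and
  # (20,1,11,0), and both give accuracy 31/32
  target <- c(1, 0.92, 0.95, 1, 0.97)
  sols <- list()
  for (tp in 0:32) for (fp in 0:(32 - tp)) for (tn in 0:(32 - tp - fp)) {
    fn <- 32 - tp - fp - tn
    m <- suppressWarnings(confusion_metrics(tp, fp, tn, fn))
    if (!any(is.na(m)) && all(abs(m - target) < 0.005))
      sols[[length(sols) + 1]] <- c(tp, fp, tn, fn)
  }
  expect_true(any(vapply(sols, identical, logical(1),
                         y = c(19, 1, 12, 0))))
  for (sol in sols)
    expect_equal(sum(sol[c(1, 3)]) / 32, 31 / 32)
  m <- confusion_metrics(19, 1, 12, 0)
  expect_equal(unname(m["accuracy"]), 31 / 32, tolerance = 1e-12)
  # all-correct and degenerate cases
  expect_equal(as.numeric(confusion_metrics(4, 0, 28, 0)),
               c(1, 1, 1, 1, 1))
  m0 <- confusion_metrics(0, 0, 3, 1)
  expect_equal(unname(m0["sensitivity"]), 0)
  expect_true("ppv" %in% attr(m0, "degenerate"))
  expect_error(confusion_metrics(0, 0, 0, 0), "positive total")
})

test_that("the nested experiment keeps its bookkeeping invariants", {
  tbl <- make_sep_table(n = 36, seed = 9)
  cfg <- svm_config(gamma_exp = seq(-6, 0, 2), cost_exp = seq(-2, 4, 2),
                    select_reps = 2L)
  res <- run_experiment(tbl, cfg, seed = 5)
  # every patient validated exactly once
  expect_setequal(unlist(lapply(res$folds, `[[`, "validation_idx")), 1:36)
  # fold counts sum to the fold sizes
  for (f in res$folds) {
    expect_equal(sum(f$train_counts), 32)
    expect_equal(sum(f$validation_counts), 4)
  }
  # means equal the arithmetic mean of per-fold metrics
  accs <- vapply(res$folds, function(f) f$validation_metrics["accuracy"],
                 numeric(1))
  expect_equal(unname(res$mean_validation_metrics["accuracy"]),
               mean(accs))
  # selection frequencies count selected subsets across the 9 folds
  expect_equal(sum(res$selection_frequency),
               sum(vapply(res$folds, function(f) length(f$selected),
                          integer(1))))
  expect_true(all(res$selection_frequency <= 9))
})

test_that("held-out labels cannot influence the trained models", {
  tbl <- make_sep_table(n = 36, seed = 13)
  cfg <- svm_config(gamma_exp = seq(-6, 0, 2), cost_exp = seq(-2, 4, 2),
                    select_reps = 2L)
  res1 <- run_experiment(tbl, cfg, seed = 21)
  # poison the held-out labels of fold 3 only: everything fold 3
  # learned from its training rows must be bit-identical
  folds <- make_folds(36, 9, seed = 21)
  poisoned <- tbl
  poisoned$outcome[folds[[3]]] <- factor(
    ifelse(tbl$outcome[folds[[3]]] == "control", "failure", "control"),
    levels = levels(tbl$outcome))
  res2 <- run_experiment(poisoned, cfg, seed = 21)
  expect_identical(res1$folds[[3]]$gamma, res2$folds[[3]]$gamma)
  expect_identical(res1$folds[[3]]$cost, res2$folds[[3]]$cost)
  expect_identical(res1$folds[[3]]$selected, res2$folds[[3]]$selected)
  expect_identical(res1$folds[[3]]$train_predictions,
                   res2$folds[[3]]$train_predictions)
  # but fold 3's validation metrics do change (its labels flipped)
  expect_false(isTRUE(all.equal(res1$folds[[3]]$validation_metrics,
                                res2$folds[[3]]$validation_metrics)))
})
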