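#' SVM training configuration
#'
#' Hyperparameter grids and nesting options for the RBF-SVM engine. The
#' default grids cover gamma = 2^-20 ... 2^10 and C = 2^-10 ... 2^10 at
#' integer exponent steps; the best pair is chosen by exhaustive grid
#' search on inner cross-validation accuracy with ties broken toward
#' smaller C, then smaller gamma.
#'
#' @param gamma_exp Integer exponents of the RBF kernel width grid.
#' @param cost_exp Integer exponents of the regularization grid.
#' @param inner_folds Folds of the inner CV used for tuning, feature
#'   elimination scoring and subset selection.
#' @param inner_reps Number of repeated inner-CV partitions whose
#'   scores are averaged during the elimination path and grid search.
#' @param select_reps Number of repeated inner-CV partitions used to
#'   re-score the candidate prefix subsets when choosing the final
#'   subset; the choice among ~p nested subsets is the step most prone
#'   to selection noise, so it gets a finer estimate than the path.
#' @param eliminate Run backward sequential feature elimination (TRUE)
#'   or keep all features (FALSE).
#' @param scoring `"cv"` scores candidate subsets by inner-CV accuracy;
#'   `"resubstitution"` by training-set accuracy.
#' @param class_weights Optional named class weights passed to the SVM.
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(gamma_exp = -20:10, cost_exp = -10:10,
                       inner_folds = 4L, inner_reps = 1L,
                       select_reps = 10L, eliminate = TRUE,
                       scoring = c("cv", "resubstitution"),
                       class_weights = NULL) {
  if (!length(gamma_exp) || !length(cost_exp))
    stop("hyperparameter grids must be non-empty")
  structure(list(gamma = 2^sort(as.numeric(gamma_exp)),
                 cost = 2^sort(as.numeric(cost_exp)),
                 inner_folds = as.integer(inner_folds),
                 inner_reps = max(1L, as.integer(inner_reps)),
                 select_reps = max(1L, as.integer(select_reps)),
                 eliminate = isTRUE(eliminate),
                 scoring = match.arg(scoring),
                 class_weights = class_weights),
            class = "svm_config")
}

#' Partition patients into k equal cross-validation folds
#'
#' @param n Number of patients; must be divisible by `k`.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @param stratified Balance outcome labels across folds (needs
#'   `labels`); default `FALSE` matches a purely random division.
#' @param labels Outcome labels (required when `stratified`).
#' @return List of `k` disjoint index vectors of size `n / k`.
#' @export
make_folds <- function(n, k = 9L, seed = 1L, stratified = FALSE,
                       labels = NULL) {
  if (n %% k != 0)
    stop(sprintf("k = %d does not divide n = %d into equal folds", k, n))
  withr::with_seed(seed, {
    if (stratified) {
      if (is.null(labels) || length(labels) != n)
        stop("stratified folds need one label per patient")
      # deal class-grouped, randomly permuted indices round-robin
      ord <- unlist(lapply(split(seq_len(n), labels), sample))
      folds <- split(ord, rep_len(seq_len(k), n))
    } else {
      folds <- split(sample(n), rep(seq_len(k), each = n / k))
    }
    lapply(unname(folds), as.integer)
  })
}

svm_fit <- function(x, y, gamma, cost, class_weights = NULL) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             gamma = gamma, cost = cost, scale = FALSE,
             class.weights = class_weights)
}

# inner-CV accuracy of one (gamma, cost) on one feature subset;
# degenerate single-class training folds fall back to the majority class
inner_cv_accuracy <- function(x, y, gamma, cost, folds, class_weights) {
  inner_cv_score(x, y, gamma, cost, folds, class_weights)[["accuracy"]]
}

# `folds` everywhere below is a list of partitions (repetitions), each a
# list of disjoint validation index sets; scores are averaged over
# repetitions
as_partitions <- function(folds) {
  if (is.list(folds) && length(folds) && is.list(folds[[1]])) folds
  else list(folds)
}

# accuracy plus the mean signed decision margin (|decision value|,
# negative when misclassified): the margin is a continuous secondary
# criterion used only to break accuracy ties, which are frequent when
# accuracy is quantized in steps of 1/n
inner_cv_score <- function(x, y, gamma, cost, folds, class_weights) {
  parts <- as_partitions(folds)
  correct <- 0; margin <- 0; total <- 0L
  for (part in parts) {
    for (f in part) {
      xtr <- x[-f, , drop = FALSE]; ytr <- y[-f]
      xva <- x[f, , drop = FALSE]
      if (nlevels(droplevels(ytr)) < 2L) {
        pred <- factor(rep(names(which.max(table(ytr))), length(f)),
                       levels = levels(y))
        dv <- rep(0, length(f))
      } else {
        m <- svm_fit(xtr, ytr, gamma, cost, class_weights)
        pred <- stats::predict(m, xva, decision.values = TRUE)
        dv <- abs(as.numeric(attr(pred, "decision.values")))
      }
      ok <- pred == y[f]
      correct <- correct + sum(ok)
      margin <- margin + sum(ifelse(ok, dv, -dv))
      total <- total + length(f)
    }
  }
  c(accuracy = correct / total, margin = margin / total)
}

resub_score <- function(x, y, gamma, cost, class_weights) {
  m <- svm_fit(x, y, gamma, cost, class_weights)
  pred <- stats::predict(m, x, decision.values = TRUE)
  dv <- abs(as.numeric(attr(pred, "decision.values")))
  ok <- pred == y
  c(accuracy = mean(ok), margin = mean(ifelse(ok, dv, -dv)))
}

subset_score <- function(x, y, cols, gamma, cost, cfg, folds) {
  xs <- x[, cols, drop = FALSE]
  sc <- if (cfg$scoring == "cv")
    inner_cv_score(xs, y, gamma, cost, folds, cfg$class_weights)
  else
    resub_score(xs, y, gamma, cost, cfg$class_weights)
  # lexicographic (accuracy, margin) collapsed into one key; the margin
  # term is bounded well below the 1/n accuracy quantum
  c(sc, key = sc[["accuracy"]] + 1e-4 * tanh(sc[["margin"]] / 2))
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates inner-CV accuracy on every (gamma, C) pair of the grids and
#' returns the best pair with deterministic tie-breaking (smaller C,
#' then smaller gamma) together with the full score surface.
#'
#' @param x Feature matrix (training rows, standardized).
#' @param y Outcome factor with two levels.
#' @param cfg An [svm_config()].
#' @param inner_folds Optional list of inner fold index sets; generated
#'   from `seed` when omitted.
#' @param seed Seed for generating inner folds.
#' @return List with `gamma`, `cost`, `surface` (gamma x cost matrix of
#'   accuracies) and `accuracy`.
#' @export
grid_search <- function(x, y, cfg = svm_config(), inner_folds = NULL,
                        seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("grid search needs at least two classes")
  if (is.null(inner_folds))
    inner_folds <- inner_partitions(nrow(x), cfg, seed, labels = y)
  surface <- matrix(NA_real_, length(cfg$gamma), length(cfg$cost),
                    dimnames = list(gamma = as.character(cfg$gamma),
                                    cost = as.character(cfg$cost)))
  for (j in seq_along(cfg$cost)) {
    for (i in seq_along(cfg$gamma)) {
      surface[i, j] <- inner_cv_accuracy(x, y, cfg$gamma[i], cfg$cost[j],
                                         inner_folds, cfg$class_weights)
    }
  }
  best <- which(surface == max(surface), arr.ind = TRUE)
  best <- best[order(best[, 2L], best[, 1L]), , drop = FALSE][1, ]
  list(gamma = cfg$gamma[best[1L]], cost = cfg$cost[best[2L]],
       surface = surface, accuracy = max(surface))
}

# inner folds: as-equal-as-possible partition (n need not divide
# evenly), stratified by label when given — with ~32 training patients,
# unstratified inner folds can end up with almost no minority-class
# cases, which makes tuning and elimination scores needlessly noisy
inner_partition <- function(n, k, seed, labels = NULL) {
  withr::with_seed(seed, {
    if (is.null(labels)) {
      lapply(unname(split(sample(n), rep_len(seq_len(k), n))), as.integer)
    } else {
      ord <- unlist(lapply(split(seq_len(n), labels), sample),
                    use.names = FALSE)
      lapply(unname(split(ord, rep_len(seq_len(k), n))), as.integer)
    }
  })
}

inner_partitions <- function(n, cfg, seed, labels = NULL) {
  lapply(seq_len(cfg$inner_reps), function(r)
    inner_partition(n, cfg$inner_folds, seed + r - 1L, labels))
}

#' Backward sequential feature elimination with full ranking
#'
#' Starting from all features, each iteration refits the model with
#' every single remaining feature left out and permanently removes the
#' feature whose omission yields the best score — the feature with the
#' least impact on diagnostic performance. The iteration number at
#' which a feature is eliminated defines its rank (the survivor of all
#' iterations has rank 1). The selected subset is the top-k prefix of
#' the ranking with the highest recorded score, smallest subset on
#' ties.
#'
#' @inheritParams grid_search
#' @param gamma,cost Fixed RBF hyperparameters used for every refit.
#' @return Object of class `elimination_trace`: list with `trace`
#'   (data.frame: iteration, feature, score of the set remaining after
#'   the removal), `ranking` (named integer vector, 1 = best),
#'   `selected` (character vector of selected features) and
#'   `full_score`.
#' @export
backward_eliminate <- function(x, y, gamma, cost, cfg = svm_config(),
                               inner_folds = NULL, seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  feats <- colnames(x)
  if (is.null(feats)) feats <- colnames(x) <- paste0("V", seq_len(ncol(x)))
  p <- length(feats)
  if (p < 2L) stop("need at least two features to eliminate")
  if (is.null(inner_folds))
    inner_folds <- inner_partitions(nrow(x), cfg, seed, labels = y)
  full <- subset_score(x, y, feats, gamma, cost, cfg, inner_folds)
  current <- feats
  trace <- data.frame(iteration = integer(), feature = character(),
                      score = numeric(), key = numeric())
  while (length(current) > 1L) {
    sc <- vapply(current, function(f)
      subset_score(x, y, setdiff(current, f), gamma, cost, cfg,
                   inner_folds), numeric(3))
    i_drop <- which.max(sc["key", ])  # first max: fixed-order ties
    trace <- rbind(trace, data.frame(iteration = p - length(current) + 1L,
                                     feature = current[i_drop],
                                     score = sc["accuracy", i_drop],
                                     key = sc["key", i_drop]))
    current <- current[-i_drop]
  }
  last <- subset_score(x, y, current, gamma, cost, cfg, inner_folds)
  trace <- rbind(trace, data.frame(
    iteration = p, feature = current,
    score = last[["accuracy"]], key = last[["key"]]))
  ranking <- stats::setNames(rev(seq_len(p)), trace$feature)
  ranking <- ranking[feats]  # order as input columns
  # candidate subsets: the full set and every post-removal remainder
  # (sizes p, p-1, ..., 1; the remainder after removal i is exactly the
  # top-(p-i) prefix of the final ranking). The prefix choice is the
  # step most sensitive to scoring noise, so each prefix is re-scored
  # on `select_reps` repeated inner partitions before the smallest
  # best-scoring subset is taken.
  sel_parts <- if (cfg$scoring == "cv")
    lapply(seq_len(cfg$select_reps), function(r)
      inner_partition(nrow(x), cfg$inner_folds, seed + 1000L + r,
                      labels = y))
  else inner_folds
  sizes <- seq_len(p)
  accs <- vapply(sizes, function(sz) {
    cols <- names(ranking)[ranking <= sz]
    subset_score(x, y, cols, gamma, cost, cfg, sel_parts)[["accuracy"]]
  }, numeric(1))
  size_sel <- min(sizes[accs == max(accs)])  # smallest subset on ties
  selected <- names(ranking)[ranking <= size_sel]
  structure(list(trace = trace[, c("iteration", "feature", "score")],
                 ranking = ranking, selected = selected,
                 full_score = full[["accuracy"]]),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("<elimination_trace: %d features, selected %d (%s)>\n",
              length(x$ranking), length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy from confusion counts (positive class = local failure).
#' Ratios with a zero denominator are returned as `NA` and flagged in
#' the `degenerate` attribute.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return Named numeric vector of the five metrics.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be non-negative with a positive total")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(sensitivity = rat(tp, tp + fn),
           specificity = rat(tn, tn + fp),
           ppv = rat(tp, tp + fp),
           npv = rat(tn, tn + fn),
           accuracy = (tp + tn) / sum(counts))
  attr(out, "degenerate") <- names(out)[is.na(out)]
  out
}

count_confusion <- function(pred, truth, positive = "failure") {
  c(tp = sum(pred == positive & truth == positive),
    fp = sum(pred == positive & truth != positive),
    tn = sum(pred != positive & truth != positive),
    fn = sum(pred != positive & truth == positive))
}

#' Run the nested cross-validated SVM experiment
#'
#' The full evaluation protocol: patients are randomly divided into `k`
#' equal folds; for each fold the remaining patients form the training
#' set on which — and only on which — the feature scaler is fitted, the
#' (gamma, C) pair is tuned by grid search, and backward sequential
#' elimination ranks the features and picks the best-scoring subset.
#' The final model is refitted on the training set with the selected
#' features and scored on both the training set and the held-out fold.
#' Held-out rows never influence scaling, tuning or selection.
#'
#' @param features Feature table from [extract_cohort_features()] (or
#'   [sample_cohort()]): `outcome` column plus the feature columns.
#' @param cfg An [svm_config()].
#' @param seed RNG seed controlling fold assignment and inner folds.
#' @param k Number of outer folds.
#' @param stratified Stratify outer folds by outcome.
#' @return Object of class `cv_experiment`: per-fold results (chosen
#'   hyperparameters, elimination trace, confusion counts and metrics
#'   for training and validation), mean metrics on both sides, and the
#'   feature selection frequency across folds.
#' @export
run_experiment <- function(features, cfg = svm_config(), seed = 1L,
                           k = 9L, stratified = FALSE) {
  feats <- intersect(feature_names(), colnames(features))
  if (!length(feats))
    feats <- setdiff(colnames(features), c("id", "outcome"))
  y <- factor(features$outcome, levels = c("control", "failure"))
  if (any(is.na(y))) stop("every patient needs an outcome label")
  n <- nrow(features)
  folds <- make_folds(n, k, seed, stratified = stratified, labels = y)
  fold_seeds <- withr::with_seed(seed, sample.int(1e7, k))
  fold_results <- vector("list", k)
  for (f in seq_len(k)) {
    val <- folds[[f]]
    train <- setdiff(seq_len(n), val)
    res <- tryCatch(
      run_fold(features, feats, y, train, val, cfg, fold_seeds[f]),
      error = function(e)
        stop(sprintf("fold %d failed: %s", f, conditionMessage(e)),
             call. = FALSE))
    res$fold <- f
    res$validation_idx <- val
    fold_results[[f]] <- res
  }
  metric_names <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  mean_of <- function(side) {
    m <- vapply(fold_results, function(r) r[[side]], numeric(5))
    rowMeans(m, na.rm = TRUE)
  }
  sel <- table(unlist(lapply(fold_results, function(r) r$selected)))
  sel <- sort(stats::setNames(as.integer(sel), names(sel)),
              decreasing = TRUE)
  structure(list(folds = fold_results,
                 mean_train_metrics = mean_of("train_metrics"),
                 mean_validation_metrics = mean_of("validation_metrics"),
                 selection_frequency = sel,
                 feature_names = feats, k = k, seed = seed),
            class = "cv_experiment")
}

run_fold <- function(features, feats, y, train, val, cfg, seed) {
  std <- standardize_features(features[, feats, drop = FALSE],
                              fit_rows = train)
  x <- as.matrix(std$table[, feats, drop = FALSE])
  xtr <- x[train, , drop = FALSE]; ytr <- droplevels(y[train])
  if (nlevels(ytr) < 2L) stop("training fold has a single class")
  inner <- inner_partitions(length(train), cfg, seed, labels = ytr)
  gs <- grid_search(xtr, ytr, cfg, inner_folds = inner)
  if (cfg$eliminate && length(feats) > 1L) {
    el <- backward_eliminate(xtr, ytr, gs$gamma, gs$cost, cfg,
                             inner_folds = inner)
    selected <- el$selected
    # re-tune the hyperparameters for the dimensionality of the final
    # selected subset before the final refit
    gs <- grid_search(xtr[, selected, drop = FALSE], ytr, cfg,
                      inner_folds = inner)
  } else {
    el <- NULL
    selected <- feats
  }
  model <- svm_fit(xtr[, selected, drop = FALSE], ytr, gs$gamma, gs$cost,
                   cfg$class_weights)
  pred_tr <- stats::predict(model, xtr[, selected, drop = FALSE])
  pred_va <- stats::predict(model, x[val, selected, drop = FALSE])
  ctr <- count_confusion(pred_tr, y[train])
  cva <- count_confusion(pred_va, y[val])
  list(gamma = gs$gamma, cost = gs$cost, grid_accuracy = gs$accuracy,
       elimination = el, selected = selected,
       train_counts = ctr, validation_counts = cva,
       train_metrics = confusion_metrics(ctr["tp"], ctr["fp"], ctr["tn"],
                                         ctr["fn"]),
       validation_metrics = confusion_metrics(cva["tp"], cva["fp"],
                                              cva["tn"], cva["fn"]),
       train_predictions = as.character(pred_tr))
}

#' @export
print.cv_experiment <- function(x, ...) {
  cat(sprintf("<cv_experiment: %d folds, seed %d>\n", x$k, x$seed))
  cat("mean training metrics:\n")
  print(round(x$mean_train_metrics, 3))
  cat("mean validation metrics:\n")
  print(round(x$mean_validation_metrics, 3))
  cat("most selected features:\n")
  print(utils::head(x$selection_frequency, 8))
  invisible(x)
}
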