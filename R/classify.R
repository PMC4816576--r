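#' Classification accuracy rate
#'
#' `100 * n_correct / n_total`, the percentage of correctly classified
#' trials.
#'
#' @param n_correct number of correct classification incidents.
#' @param n_total total number of classification incidents (> 0).
#' @return accuracy in percent.
#' @export
accuracy_rate <- function(n_correct, n_total) {
  if (any(n_total <= 0)) stopf("n_total must be > 0")
  if (any(n_correct < 0 | n_correct > n_total)) stopf("need 0 <= n_correct <= n_total")
  100 * n_correct / n_total
}

#' RBF-SVM hyperparameters
#'
#' @param C misclassification cost (> 0).
#' @param gamma RBF kernel width parameter (> 0).
#' @return an object of class `svm_params`.
#' @export
svm_params <- function(C, gamma) {
  if (C <= 0 || gamma <= 0) stopf("C and gamma must be > 0")
  structure(list(C = C, gamma = gamma), class = "svm_params")
}

as_label_factor <- function(labels) factor(labels, levels = c("error", "correct"))

#' Train a soft-margin RBF-SVM
#'
#' Thin wrapper around [e1071::svm()] with the radial kernel, no internal
#' rescaling (features are expected to be scaled to [0, 1] already), and
#' the error class as the positive class. Deterministic given data and
#' parameters.
#'
#' @param fm a scaled `feature_matrix` containing both classes.
#' @param params an `svm_params`.
#' @return a fitted `svm` model.
#' @export
train_svm <- function(fm, params) {
  y <- as_label_factor(fm$labels)
  if (length(unique(fm$labels)) < 2) stopf("both classes must be present")
  e1071::svm(fm$values, y, type = "C-classification", kernel = "radial",
             cost = params$C, gamma = params$gamma, scale = FALSE)
}

# Stratified k-fold assignment: within each class, trials are shuffled
# (seeded) and dealt round-robin into folds.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k > n) stopf("k (%d) exceeds the number of rows (%d)", k, n)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Precompute the per-fold scaled design matrices once, so that grid
# search and label permutations only pay for SVM fits. Scaling is fit on
# the training part of each fold (leakage-free default); with
# `scale_jointly = TRUE` a single scaler is fit on the full set, which
# reproduces whole-set scaling.
make_cv_context <- function(fm, k = 10, seed = 1, scale_jointly = FALSE) {
  fold <- stratified_folds(fm$labels, k, seed)
  if (scale_jointly) {
    fm_all <- apply_scaler(fm, fit_scaler(fm))
  }
  # with very small classes the round-robin can leave trailing folds
  # empty; those contribute no held-out trials and are dropped
  fold_ids <- intersect(seq_len(k), unique(fold))
  folds <- lapply(fold_ids, function(f) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (scale_jointly) {
      xtr <- fm_all$values[tr, , drop = FALSE]
      xte <- fm_all$values[te, , drop = FALSE]
    } else {
      fm_tr <- feature_matrix(fm$values[tr, , drop = FALSE], fm$feature_names,
                              fm$labels[tr])
      sc <- fit_scaler(fm_tr)
      xtr <- apply_scaler(fm_tr, sc)$values
      xte <- apply_scaler(feature_matrix(fm$values[te, , drop = FALSE],
                                         fm$feature_names, fm$labels[te]),
                          sc)$values
    }
    list(train = tr, test = te, xtr = xtr, xte = xte)
  })
  list(folds = folds, labels = fm$labels, n = length(fm$labels), k = k)
}

# k-fold CV accuracy of an svm_params under a given label vector,
# against a precomputed context. Returns pooled counts over held-out
# trials.
cv_eval <- function(ctx, params, labels = ctx$labels) {
  n_correct <- 0
  for (fd in ctx$folds) {
    ytr <- as_label_factor(labels[fd$train])
    if (length(unique(ytr)) < 2) {
      # degenerate under label permutation on very small sets: a
      # single-class training fold yields a constant classifier
      pred <- rep(as.character(ytr[1]), length(fd$test))
    } else {
      fit <- e1071::svm(fd$xtr, ytr, type = "C-classification", kernel = "radial",
                        cost = params$C, gamma = params$gamma, scale = FALSE)
      pred <- as.character(predict(fit, fd$xte))
    }
    n_correct <- n_correct + sum(pred == labels[fd$test])
  }
  list(accuracy = accuracy_rate(n_correct, ctx$n),
       n_correct = n_correct, n_total = ctx$n)
}

#' Stratified k-fold cross-validated accuracy
#'
#' Splits the trials into `k` stratified folds (seeded); in each fold a
#' [0, 1] scaler and an RBF-SVM are fit on the training part and the
#' held-out part is classified with them. Returns the pooled accuracy
#' over all held-out trials.
#'
#' @param fm an unscaled `feature_matrix` (scaling happens inside each
#'   fold; see `scale_jointly`).
#' @param params an `svm_params`.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param scale_jointly fit one scaler on the whole set instead of
#'   per-fold (compatibility switch; introduces a mild leak).
#' @return list with `accuracy` (percent), `n_correct`, `n_total`.
#' @export
cv_accuracy <- function(fm, params, k = 10, seed = 1, scale_jointly = FALSE) {
  ctx <- make_cv_context(fm, k, seed, scale_jointly)
  cv_eval(ctx, params)
}

#' Nested (coarse-to-fine) grid search for RBF-SVM hyperparameters
#'
#' Evaluates k-fold CV accuracy over a coarse logarithmic grid in (C,
#' gamma), then over a finer grid spanning `fine_span` powers of 2 around
#' the coarse optimum in `fine_step`-power steps, and selects the pair
#' maximizing CV accuracy over all evaluated points. Ties are broken by
#' smaller C, then smaller gamma. The same fold assignment is used for
#' every grid point.
#'
#' @param fm an unscaled `feature_matrix`.
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @param coarse_c,coarse_gamma coarse grid values (defaults
#'   `2^seq(-5, 15, 2)` and `2^seq(-15, 3, 2)`).
#' @param fine_span,fine_step fine-grid half-width and step, in powers
#'   of 2 (defaults 2 and 0.5).
#' @param scale_jointly see [cv_accuracy()].
#' @return an object of class `grid_search_result`: data.frames `coarse`
#'   and `fine` (columns C, gamma, accuracy), `selected` (`svm_params`),
#'   `selected_cv_accuracy`, `n_correct`, `n_total`, and the `cv_context`
#'   used (for permutation re-evaluation).
#' @export
nested_grid_search <- function(fm, k = 10, seed = 1,
                               coarse_c = 2^seq(-5, 15, 2),
                               coarse_gamma = 2^seq(-15, 3, 2),
                               fine_span = 2, fine_step = 0.5,
                               scale_jointly = FALSE) {
  ctx <- make_cv_context(fm, k, seed, scale_jointly)
  eval_grid <- function(cs, gs) {
    grid <- expand.grid(C = cs, gamma = gs, KEEP.OUT.ATTRS = FALSE)
    grid$accuracy <- NA_real_
    grid$n_correct <- NA_integer_
    for (i in seq_len(nrow(grid))) {
      r <- cv_eval(ctx, svm_params(grid$C[i], grid$gamma[i]))
      grid$accuracy[i] <- r$accuracy
      grid$n_correct[i] <- r$n_correct
    }
    grid
  }
  pick <- function(grid) grid[order(-grid$accuracy, grid$C, grid$gamma), ][1, ]
  coarse <- eval_grid(coarse_c, coarse_gamma)
  best_c <- pick(coarse)
  fine <- eval_grid(2^seq(log2(best_c$C) - fine_span, log2(best_c$C) + fine_span,
                          by = fine_step),
                    2^seq(log2(best_c$gamma) - fine_span, log2(best_c$gamma) + fine_span,
                          by = fine_step))
  both <- rbind(coarse, fine)
  best <- pick(both)
  structure(list(coarse = coarse, fine = fine,
                 selected = svm_params(best$C, best$gamma),
                 selected_cv_accuracy = best$accuracy,
                 n_correct = best$n_correct, n_total = ctx$n,
                 cv_context = ctx),
            class = "grid_search_result")
}

#' Permutation p-value for a classification accuracy
#'
#' Recomputes the accuracy under `n_perm` seeded random permutations of
#' the class labels, holding everything else (hyperparameters, folds,
#' trained model for transfer) fixed, and returns
#' `#{permuted accuracy >= observed} / n_perm` — the plain-proportion
#' estimator, which can attain 0. The positively biased add-one
#' estimator `(1 + #) / (n_perm + 1)` is available via `add_one`.
#'
#' @param evaluation function taking a label vector and returning an
#'   accuracy in percent.
#' @param labels the observed label vector to permute.
#' @param observed the observed accuracy in percent.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param add_one use the add-one estimator.
#' @return p-value in [0, 1].
#' @export
permutation_pvalue <- function(evaluation, labels, observed, n_perm = 1000,
                               seed = 1, add_one = FALSE) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  perm_acc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) evaluation(sample(labels)), numeric(1))
  })
  hits <- sum(perm_acc >= observed)
  if (add_one) (1 + hits) / (n_perm + 1) else hits / n_perm
}

new_repeat_result <- function(repeat_index, n_correct, n_total, p, params) {
  data.frame(repeat_index = repeat_index,
             accuracy = accuracy_rate(n_correct, n_total),
             p = p, n_correct = n_correct, n_total = n_total,
             C = params$C, gamma = params$gamma)
}

#' One within-task analysis repeat
#'
#' Extracts the feature set, balances classes with the repeat seed, runs
#' the nested grid search under stratified k-fold CV, and takes the
#' selected pair's pooled CV accuracy as the observed accuracy. The
#' permutation p-value re-runs the identical CV procedure — fold
#' stratification and per-fold scaler fits included — on each permuted
#' label vector, with the hyperparameters held at the observed selection.
#' Recomputing the folds matters: keeping the observed (stratified) folds
#' while permuting labels biases permuted accuracies below chance on
#' small sets and makes the test anti-conservative.
#'
#' @param ep an `erp_epochs` for one subject and task.
#' @param spec a `feature_set_spec`.
#' @param seed repeat seed (drives balancing, folds, permutations).
#' @param k CV folds.
#' @param n_perm label permutations.
#' @param repeat_index bookkeeping index stored in the result.
#' @param scale_jointly see [cv_accuracy()].
#' @param ... grid-search options passed to [nested_grid_search()].
#' @return one-row data.frame (repeat result).
#' @export
within_task_repeat <- function(ep, spec, seed, k = 10, n_perm = 1000,
                               repeat_index = 1, scale_jointly = FALSE, ...) {
  fm <- balance_classes(extract_features(ep, spec), seed = derive_seed(seed, 1L))
  cv_seed <- derive_seed(seed, 2L)
  gs <- nested_grid_search(fm, k = k, seed = cv_seed,
                           scale_jointly = scale_jointly, ...)
  p <- permutation_pvalue(
    evaluation = function(lab) {
      fm_perm <- feature_matrix(fm$values, fm$feature_names, lab)
      ctx <- make_cv_context(fm_perm, k = k, seed = cv_seed,
                             scale_jointly = scale_jointly)
      cv_eval(ctx, gs$selected)$accuracy
    },
    labels = fm$labels, observed = gs$selected_cv_accuracy,
    n_perm = n_perm, seed = derive_seed(seed, 3L))
  new_repeat_result(repeat_index, gs$n_correct, gs$n_total, p, gs$selected)
}

#' One cross-task transfer repeat
#'
#' Balances and extracts features on the training task, selects (C,
#' gamma) there by nested grid search, refits the scaler and the SVM on
#' the full balanced training set, then classifies the balanced test-task
#' trials (scaled with the training scaler, clipped to [0, 1]). The
#' permutation p-value permutes the test-set labels of the fixed trained
#' model.
#'
#' @param train_ep,test_ep `erp_epochs` of the two tasks for one subject.
#' @param spec a `feature_set_spec`.
#' @param seed repeat seed.
#' @param k CV folds for the grid search on the training task.
#' @param n_perm label permutations on the test set.
#' @param repeat_index bookkeeping index.
#' @param ... grid-search options.
#' @return one-row data.frame (repeat result, counts refer to the test set).
#' @export
transfer_classify <- function(train_ep, test_ep, spec, seed, k = 10,
                              n_perm = 1000, repeat_index = 1, ...) {
  fm_tr <- balance_classes(extract_features(train_ep, spec),
                           seed = derive_seed(seed, 1L))
  gs <- nested_grid_search(fm_tr, k = k, seed = derive_seed(seed, 2L), ...)
  sc <- fit_scaler(fm_tr)
  model <- train_svm(apply_scaler(fm_tr, sc), gs$selected)
  fm_te <- balance_classes(extract_features(test_ep, spec),
                           seed = derive_seed(seed, 4L))
  pred <- as.character(predict(model, apply_scaler(fm_te, sc)$values))
  n_correct <- sum(pred == fm_te$labels)
  obs <- accuracy_rate(n_correct, length(pred))
  p <- permutation_pvalue(
    evaluation = function(lab) accuracy_rate(sum(pred == lab), length(pred)),
    labels = fm_te$labels, observed = obs,
    n_perm = n_perm, seed = derive_seed(seed, 3L))
  new_repeat_result(repeat_index, n_correct, length(pred), p, gs$selected)
}

#' Repeat an analysis scheme and aggregate
#'
#' Runs `n_repeats` independent repeats of the within-task or transfer
#' analysis, each with a freshly drawn balanced correct-trial sample, and
#' aggregates accuracy, p-value and correctly-classified trial counts as
#' mean/min/max across repeats.
#'
#' @param task_epochs named list of `erp_epochs` (one per task) for one
#'   subject.
#' @param spec a `feature_set_spec`.
#' @param mode one of `"within-flanker"`, `"within-rotation"`,
#'   `"flanker->rotation"`, `"rotation->flanker"` (task names follow the
#'   names of `task_epochs`).
#' @param n_repeats number of repeats (default 10).
#' @param master_seed master seed; repeat `r` uses a derived seed.
#' @param k,n_perm,... passed to the per-repeat functions.
#' @return an object of class `classification_report`: fields `subject`,
#'   `feature_set`, `mode`, `repeats` (data.frame) and `aggregates`
#'   (one-row data.frame with mean/min/max columns).
#' @export
repeat_and_aggregate <- function(task_epochs, spec, mode, n_repeats = 10,
                                 master_seed = 1, k = 10, n_perm = 1000, ...) {
  parts <- strsplit(mode, "->", fixed = TRUE)[[1]]
  within <- length(parts) == 1
  if (within) {
    tname <- sub("^within-", "", mode)
    if (!tname %in% names(task_epochs)) stopf("unknown task '%s' in mode", tname)
  } else {
    if (!all(parts %in% names(task_epochs)))
      stopf("mode '%s' names tasks not present", mode)
  }
  reps <- do.call(rbind, lapply(seq_len(n_repeats), function(r) {
    rs <- derive_seed(master_seed, r)
    if (within) {
      within_task_repeat(task_epochs[[tname]], spec, seed = rs, k = k,
                         n_perm = n_perm, repeat_index = r, ...)
    } else {
      transfer_classify(task_epochs[[parts[1]]], task_epochs[[parts[2]]], spec,
                        seed = rs, k = k, n_perm = n_perm, repeat_index = r, ...)
    }
  }))
  agg <- data.frame(
    accuracy_mean = mean(reps$accuracy), accuracy_min = min(reps$accuracy),
    accuracy_max = max(reps$accuracy),
    p_mean = mean(reps$p), p_min = min(reps$p), p_max = max(reps$p),
    trials_correct_mean = mean(reps$n_correct),
    trials_correct_min = min(reps$n_correct),
    trials_correct_max = max(reps$n_correct),
    trials_total = reps$n_total[1])
  subject <- unique(unlist(lapply(task_epochs, function(e) e$trial_meta$subject_id)))
  structure(list(subject = if (length(subject) == 1) subject else NA,
                 feature_set = spec$name, mode = mode,
                 repeats = reps, aggregates = agg),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> subject %s, %s features, %s\n",
              x$subject, x$feature_set, x$mode))
  cat(sprintf("  accuracy %.2f%% [%.2f, %.2f], p %.3f [%.3f, %.3f], %d repeats\n",
              x$aggregates$accuracy_mean, x$aggregates$accuracy_min,
              x$aggregates$accuracy_max, x$aggregates$p_mean,
              x$aggregates$p_min, x$aggregates$p_max, nrow(x$repeats)))
  invisible(x)
}
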