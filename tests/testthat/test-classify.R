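test_that("accuracy rate is the percentage of correct incidents", {
  expect_equal(accuracy_rate(170, 250), 68)
  expect_equal(accuracy_rate(0, 10), 0)
  expect_equal(accuracy_rate(10, 10), 100)
  expect_error(accuracy_rate(1, 0), "n_total")
  expect_error(accuracy_rate(5, 3), "n_correct")
})

test_that("SVM training separates well-separated clouds and rejects one-class input", {
  ep <- separable_epochs()
  fm <- apply_scaler(extract_features(ep, feature_set_spec("combined")),
                     fit_scaler(extract_features(ep, feature_set_spec("combined"))))
  model <- train_svm(fm, svm_params(1, 0.1))
  pred <- predict(model, fm$values)
  expect_equal(mean(as.character(pred) == fm$labels), 1)
  one <- feature_matrix(matrix(1:4, 2), c("a", "b"), c("error", "error"))
  expect_error(train_svm(one, svm_params(1, 1)), "both classes")
  expect_error(svm_params(-1, 1), "must be > 0")
})

test_that("stratified folds partition each class evenly and reproducibly", {
  labels <- rep(c("error", "correct"), c(30, 30))
  f <- stratified_folds(labels, 10, seed = 2)
  expect_equal(sort(unique(f)), 1:10)
  for (k in 1:10) expect_equal(sum(labels[f == k] == "error"), 3)
  expect_identical(stratified_folds(labels, 10, seed = 2), f)
  expect_error(stratified_folds(labels, 100, seed = 1), "exceeds")
})

test_that("cross-validated accuracy: separable data, determinism, null behavior", {
  ep <- separable_epochs()
  fm <- extract_features(ep, feature_set_spec("combined"))
  r <- cv_accuracy(fm, svm_params(1, 0.1), k = 10, seed = 1)
  expect_equal(r$accuracy, 100)
  expect_equal(r$n_correct, r$n_total)
  expect_identical(cv_accuracy(fm, svm_params(1, 0.1), k = 10, seed = 1), r)
  # labels assigned at random to featureless rows hover near chance
  set.seed(8)
  accs <- vapply(1:15, function(i) {
    v <- matrix(rnorm(60 * 4), 60, 4)
    fm0 <- feature_matrix(v, paste0("f", 1:4), sample(rep(c("error", "correct"), 30)))
    cv_accuracy(fm0, svm_params(1, 0.25), k = 10, seed = i)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 38)
  expect_lt(mean(accs), 62)
})

test_that("nested grid search maximizes CV accuracy over its recorded grids", {
  ep <- separable_epochs(n_per_class = 12)
  fm <- extract_features(ep, feature_set_spec("ne"))
  gs <- do.call(nested_grid_search, c(list(fm, k = 6, seed = 3), tiny_grid()))
  expect_equal(gs$selected_cv_accuracy, 100)
  # brute-force oracle over the recorded evaluations: same accuracy and
  # the documented tie-break (smallest C, then smallest gamma)
  both <- rbind(gs$coarse, gs$fine)
  best_acc <- max(both$accuracy)
  expect_equal(gs$selected_cv_accuracy, best_acc)
  cand <- both[both$accuracy == best_acc, ]
  cand <- cand[order(cand$C, cand$gamma), ]
  expect_equal(gs$selected$C, cand$C[1])
  expect_equal(gs$selected$gamma, cand$gamma[1])
  # the fine grid cannot do worse than the coarse optimum
  expect_gte(max(gs$fine$accuracy), max(gs$coarse$accuracy))
  # every grid accuracy is reproducible from cv_accuracy with the same folds
  i <- which.max(gs$coarse$accuracy)
  r <- cv_accuracy(fm, svm_params(gs$coarse$C[i], gs$coarse$gamma[i]), k = 6, seed = 3)
  expect_equal(r$accuracy, gs$coarse$accuracy[i])
})

test_that("permutation p-value counts permuted accuracies at or above the observed", {
  labels <- rep(c("error", "correct"), each = 10)
  # evaluation that always beats the observed accuracy -> p = 1
  expect_equal(permutation_pvalue(function(l) 80, labels, observed = 50,
                                  n_perm = 50, seed = 1), 1)
  # evaluation always below -> p = 0 (plain proportion can reach 0)
  expect_equal(permutation_pvalue(function(l) 40, labels, observed = 90,
                                  n_perm = 50, seed = 1), 0)
  # add-one variant is strictly positive
  expect_equal(permutation_pvalue(function(l) 40, labels, observed = 90,
                                  n_perm = 50, seed = 1, add_one = TRUE), 1 / 51)
  expect_error(permutation_pvalue(function(l) 50, labels, 50, n_perm = 0), "n_perm")
})

test_that("self-transfer reproduces the final model's training accuracy", {
  # balanced input: balancing keeps every row, so train and test sets
  # coincide and transfer accuracy equals the training accuracy
  ep <- separable_epochs(n_per_class = 15, gap = 3, sd = 2, seed = 10)
  r <- do.call(transfer_classify,
               c(list(ep, ep, feature_set_spec("combined"), seed = 5, k = 5,
                      n_perm = 20), tiny_grid()))
  # mirror the internal steps: balanced input keeps all 30 rows, so the
  # "transfer" test set is the training set (up to row order)
  fm <- balance_classes(extract_features(ep, feature_set_spec("combined")),
                        seed = derive_seed(5, 1L))
  sc <- fit_scaler(fm)
  gs <- do.call(nested_grid_search,
                c(list(fm, k = 5, seed = derive_seed(5, 2L)), tiny_grid()))
  model <- train_svm(apply_scaler(fm, sc), gs$selected)
  train_acc <- 100 * mean(as.character(predict(model, apply_scaler(fm, sc)$values)) == fm$labels)
  expect_equal(r$accuracy, train_acc)
  expect_equal(r$n_total, 30)
})

test_that("repeat_and_aggregate: consistency of repeats and aggregates", {
  cfg <- small_config()
  eps <- list(
    flanker = simulate_subject(cfg, 1, cfg$tasks$flanker, seed = 21,
                               channels = feature_channels()),
    rotation = simulate_subject(cfg, 1, cfg$tasks$rotation, seed = 22,
                                channels = feature_channels()))
  rep3 <- do.call(repeat_and_aggregate,
                  c(list(eps, feature_set_spec("ne"), "within-flanker",
                         n_repeats = 3, master_seed = 4, k = 5, n_perm = 10),
                    tiny_grid()))
  # exact identity per repeat and aggregates inside [min, max]
  expect_equal(rep3$repeats$accuracy,
               100 * rep3$repeats$n_correct / rep3$repeats$n_total)
  a <- rep3$aggregates
  expect_gte(a$accuracy_mean, a$accuracy_min)
  expect_lte(a$accuracy_mean, a$accuracy_max)
  expect_equal(a$accuracy_mean, mean(rep3$repeats$accuracy))
  expect_equal(a$trials_correct_mean, mean(rep3$repeats$n_correct))
  # mean accuracy x total / 100 equals mean trials correct
  expect_equal(a$accuracy_mean * a$trials_total / 100, a$trials_correct_mean,
               tolerance = 1e-9)
  # single repeat: mean = min = max
  rep1 <- do.call(repeat_and_aggregate,
                  c(list(eps, feature_set_spec("ne"), "within-flanker",
                         n_repeats = 1, master_seed = 4, k = 5, n_perm = 5),
                    tiny_grid()))
  expect_equal(rep1$aggregates$accuracy_mean, rep1$aggregates$accuracy_min)
  expect_equal(rep1$aggregates$accuracy_mean, rep1$aggregates$accuracy_max)
  # determinism of the full report
  rep3b <- do.call(repeat_and_aggregate,
                   c(list(eps, feature_set_spec("ne"), "within-flanker",
                          n_repeats = 3, master_seed = 4, k = 5, n_perm = 10),
                     tiny_grid()))
  expect_identical(rep3$repeats, rep3b$repeats)
  # transfer mode records test-set counts
  tr <- do.call(repeat_and_aggregate,
                c(list(eps, feature_set_spec("ne"), "flanker->rotation",
                       n_repeats = 2, master_seed = 4, k = 5, n_perm = 10),
                  tiny_grid()))
  expect_equal(tr$aggregates$trials_total,
               2 * sum(eps$rotation$trial_meta$response == "error"))
  expect_error(repeat_and_aggregate(eps, feature_set_spec("ne"), "within-stroop",
                                    n_repeats = 1, master_seed = 1),
               "unknown task")
})

test_that("combining Ne and Pe features beats either set when both are informative", {
  cfg <- make_default_config(n_trials_range = c(80, 120),
                             ne_diff_flanker = 8, ne_diff_rotation = 8,
                             pe_diff_flanker = 8, pe_diff_rotation = 8)
  mean_acc <- sapply(c("ne", "pe", "combined"), function(fs) {
    mean(vapply(1:8, function(s) {
      ep <- simulate_subject(cfg, s, cfg$tasks$flanker,
                             seed = derive_seed(300, s),
                             channels = feature_channels())
      fm <- balance_classes(extract_features(ep, feature_set_spec(fs)),
                            seed = derive_seed(301, s))
      gs <- do.call(nested_grid_search,
                    c(list(fm, k = 5, seed = derive_seed(302, s)), tiny_grid()))
      gs$selected_cv_accuracy
    }, numeric(1)))
  })
  expect_gte(mean_acc["combined"], mean_acc["ne"])
  expect_gte(mean_acc["combined"], mean_acc["pe"])
})

test_that("classification accuracy increases with the configured Ne separation", {
  # monotone trend over three effect sizes, ne features, small subjects
  effect_sizes <- c(2, 8, 16)
  mean_acc <- vapply(seq_along(effect_sizes), function(ei) {
    d <- effect_sizes[ei]
    cfg <- make_default_config(n_trials_range = c(60, 80),
                               ne_diff_flanker = d, ne_diff_rotation = d,
                               pe_diff_flanker = 0, pe_diff_rotation = 0)
    accs <- vapply(1:6, function(s) {
      ep <- simulate_subject(cfg, s, cfg$tasks$flanker,
                             seed = derive_seed(500, ei, s),
                             channels = feature_channels())
      fm <- balance_classes(extract_features(ep, feature_set_spec("ne")),
                            seed = derive_seed(501, ei, s))
      gs <- do.call(nested_grid_search,
                    c(list(fm, k = 5, seed = derive_seed(502, ei, s)), tiny_grid()))
      gs$selected_cv_accuracy
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_gt(cor(seq_along(effect_sizes), mean_acc, method = "spearman"), 0)
  expect_gt(mean_acc[3], mean_acc[1])
})
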