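test_that("default config encodes the study conditions", {
  cfg <- make_default_config()
  expect_equal(cfg$tasks$flanker$error_rate, 0.1387)
  expect_equal(cfg$tasks$rotation$error_rate, 0.1767)
  expect_equal(cfg$tasks$flanker$rt_mean_error, 242)
  expect_equal(cfg$tasks$flanker$rt_mean_correct, 311)
  expect_equal(cfg$tasks$rotation$rt_mean_error, 436)
  expect_equal(cfg$tasks$rotation$rt_mean_correct, 446)
  expect_equal(cfg$sampling_rate, 500)
  # expected windowed-mean accuracy effects: task means of 10.15 (Ne,
  # negative-going) and 3.97 (Pe), flanker above rotation
  ne <- sapply(c("flanker", "rotation"), function(t) expected_window_difference(cfg, t, "ne"))
  pe <- sapply(c("flanker", "rotation"), function(t) expected_window_difference(cfg, t, "pe"))
  expect_equal(mean(ne), -10.15, tolerance = 1e-10)
  expect_equal(mean(pe), 3.97, tolerance = 1e-10)
  expect_lt(ne["flanker"], ne["rotation"])
  expect_gt(pe["flanker"], pe["rotation"])
})

test_that("gaussian window factor: discrete grid matches the analytic form as the grid refines", {
  f_cont <- gaussian_window_factor(70, 25, c(20, 100))
  f_fine <- gaussian_window_factor(70, 25, c(20, 100), times = seq(19.995, 100.005, by = 0.01))
  expect_equal(f_fine, f_cont, tolerance = 1e-4)
  expect_error(gaussian_window_factor(70, 25, c(20, 100), times = c(-50, 150)),
               "no samples")
})

test_that("null config removes all expected differences and is idempotent", {
  cfg <- make_default_config()
  null <- make_null_config(cfg)
  for (t in names(null$tasks)) {
    expect_equal(expected_window_difference(null, t, "ne"), 0)
    expect_equal(expected_window_difference(null, t, "pe"), 0)
  }
  expect_identical(make_null_config(null), null)
  # zero-effect configuration built directly has zero expected difference
  cfg0 <- make_default_config(ne_diff_flanker = 0, ne_diff_rotation = 0,
                              pe_diff_flanker = 0, pe_diff_rotation = 0)
  expect_equal(expected_window_difference(cfg0, "flanker", "ne"), 0)
})

test_that("noiseless trials match the closed-form component sum exactly", {
  cfg <- noiseless_config()
  ep <- simulate_subject(cfg, 1, cfg$tasks$flanker, seed = 7)
  ne <- windowed_mean(ep, ne_window())
  pe <- windowed_mean(ep, pe_window())
  for (resp in c("error", "correct")) {
    i <- which(ep$trial_meta$response == resp)[1]
    expect_equal(ne[i],
                 closed_form_windowed_mean(cfg, "flanker", resp, "FCz", ne_window()),
                 tolerance = 1e-10)
    expect_equal(pe[i],
                 closed_form_windowed_mean(cfg, "flanker", resp, "Cz", pe_window()),
                 tolerance = 1e-10)
  }
  # error-minus-correct difference equals the two-component closed form
  # (the Pe spills a few hundredths of a microvolt into the Ne window)
  d <- mean(ne[ep$trial_meta$response == "error"]) -
    mean(ne[ep$trial_meta$response == "correct"])
  d_exp <- closed_form_windowed_mean(cfg, "flanker", "error", "FCz", ne_window()) -
    closed_form_windowed_mean(cfg, "flanker", "correct", "FCz", ne_window())
  expect_equal(d, d_exp, tolerance = 1e-10)
  # and the single-component calibration target to better than 0.01 uV
  expect_equal(d, expected_window_difference(cfg, "flanker", "ne"), tolerance = 1e-3)
})

test_that("spatial falloff peaks at the component's peak channel", {
  cfg <- noiseless_config(pe_diff_flanker = 0, pe_diff_rotation = 0)
  # Pe flat: single informative component (Ne); check |windowed mean| is
  # maximal at FCz across the montage for an error trial
  ep <- simulate_subject(cfg, 1, cfg$tasks$flanker, seed = 3)
  i <- which(ep$trial_meta$response == "error")[1]
  vals <- vapply(ep$montage$channel_names, function(ch) {
    abs(windowed_mean(ep, component_window("Ne", ch, c(20, 100)))[i])
  }, numeric(1))
  expect_equal(names(which.max(vals)), "FCz")
  expect_true(all(vals <= vals["FCz"] + 1e-12))
})

test_that("simulation is deterministic and cohorts reproduce", {
  cfg <- small_config()
  a <- simulate_subject(cfg, 1, cfg$tasks$flanker, seed = 11, channels = feature_channels())
  b <- simulate_subject(cfg, 1, cfg$tasks$flanker, seed = 11, channels = feature_channels())
  expect_identical(a$data, b$data)
  expect_identical(a$trial_meta, b$trial_meta)
  co1 <- simulate_cohort(cfg, channels = c("FCz", "Cz"))
  co2 <- simulate_cohort(cfg, channels = c("FCz", "Cz"))
  expect_length(co1, 2)
  expect_named(co1[[1]], c("flanker", "rotation"))
  expect_identical(co1, co2)
  co3 <- simulate_cohort(make_default_config(n_subjects = 1, n_trials_range = c(40, 60)),
                         channels = "FCz")
  expect_length(co3, 1)
})

test_that("epoch windows that miss a measurement window are rejected", {
  expect_error(simulation_config(1, standard_montage(),
                                 make_default_config()$tasks,
                                 noise_spec(1, 1),
                                 epoch_window = c(-100, 150)),
               "measurement windows")
})

test_that("error rates and RT means match the configured task parameters", {
  cfg <- make_default_config(n_subjects = 40)
  meta <- do.call(rbind, lapply(1:40, function(i) {
    do.call(rbind, lapply(1:2, function(k) {
      simulate_subject(cfg, i, cfg$tasks[[k]],
                       seed = derive_seed(cfg$seed, i, k), channels = "FCz")$trial_meta
    }))
  }))
  for (tn in c("flanker", "rotation")) {
    tk <- cfg$tasks[[tn]]
    sel <- meta$task == tn
    expect_lt(abs(mean(meta$response[sel] == "error") - tk$error_rate), 0.015)
    err <- sel & meta$response == "error"
    expect_equal(mean(meta$rt[err]), tk$rt_mean_error, tolerance = 0.02)
    expect_equal(mean(meta$rt[sel & !err]), tk$rt_mean_correct, tolerance = 0.02)
    expect_true(all(meta$rt[sel] > 100 & meta$rt[sel] < 1000))
  }
})

test_that("pink noise has unit variance per series and zero mean", {
  x <- with_seed(5, pink_noise_matrix(500, 20))
  expect_equal(dim(x), c(500, 20))
  expect_equal(colMeans(x), rep(0, 20), tolerance = 1e-10)
  expect_equal(colMeans(x^2), rep(1, 20), tolerance = 1e-8)
  # odd length is handled too
  y <- with_seed(5, pink_noise_matrix(501, 3))
  expect_equal(colMeans(y^2), rep(1, 3), tolerance = 1e-8)
})
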