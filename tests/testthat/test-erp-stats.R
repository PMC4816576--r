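test_that("windowed mean: constants, ramps, linearity", {
  ep <- toy_epochs(n = 2, fill = 7)
  expect_equal(windowed_mean(ep, ne_window()), c(7, 7))
  # linear ramp 0 -> V across the window averages to V/2 (one-sample tol)
  times <- seq(-200, 798, by = 2)
  d <- array(0, c(1, 4, length(times)))
  sel <- times >= 20 & times <= 100
  ramp <- rep(0, length(times))
  ramp[sel] <- seq(0, 8, length.out = sum(sel))
  d[1, 1, ] <- ramp
  ep <- toy_epochs(data = d)
  expect_equal(windowed_mean(ep, ne_window())[1], 4, tolerance = 8 / sum(sel))
  # linearity: wm(a*X + b) = a*wm(X) + b
  cfg <- small_config()
  epr <- simulate_subject(cfg, 1, cfg$tasks$flanker, seed = 5, channels = c("FCz", "Cz"))
  w0 <- windowed_mean(epr, ne_window())
  ep2 <- epr
  ep2$data <- 3 * epr$data + 2
  expect_equal(windowed_mean(ep2, ne_window()), 3 * w0 + 2, tolerance = 1e-12)
  expect_error(windowed_mean(epr, component_window("x", "FCz", c(900, 990))), "outside")
})

test_that("condition ERPs average trials per task x response cell", {
  d <- array(0, c(2, 4, 500))
  d[1, , ] <- 1
  d[2, , ] <- 1
  ep <- toy_epochs(data = d, response = c("error", "error"))
  erp <- condition_erps(ep)
  expect_length(erp, 1)
  expect_true(all(erp[[1]]$data == 1))
  expect_equal(erp[[1]]$n_trials, 2)
  # +1/-1 trials cancel
  d[2, , ] <- -1
  erp <- condition_erps(toy_epochs(data = d, response = c("error", "error")))
  expect_true(all(erp[[1]]$data == 0))
  # windowed_mean on an ERP returns a scalar
  expect_equal(windowed_mean(erp[[1]], ne_window()), 0)
})

test_that("2x2 rm-ANOVA agrees with aov and with squared paired t", {
  set.seed(31)
  n <- 12
  tab <- expand.grid(subject = 1:n, a = c("flanker", "rotation"),
                     b = c("error", "correct"), KEEP.OUT.ATTRS = FALSE)
  tab$value <- rnorm(nrow(tab)) + 2 * (tab$b == "error") +
    0.8 * (tab$a == "flanker") * (tab$b == "error") + rep(rnorm(n), 4)
  res <- rm_anova_2x2(tab)
  # independent oracle: stats::aov with a within-subject error stratum
  fit <- summary(stats::aov(value ~ a * b + Error(factor(subject) / (a * b)), data = tab))
  get_f <- function(stratum, term) {
    s <- fit[[paste0("Error: factor(subject):", stratum)]][[1]]
    s[trimws(rownames(s)) == term, "F value"]
  }
  expect_equal(res$F[res$effect == "a"], get_f("a", "a"), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "b"], get_f("b", "b"), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "a:b"], get_f("a:b", "a:b"), tolerance = 1e-8)
  # main-effect F equals the squared paired t on the marginal means
  wide_b <- sapply(c("error", "correct"), function(lv) {
    sapply(1:n, function(s) mean(tab$value[tab$subject == s & tab$b == lv]))
  })
  tt <- t.test(wide_b[, 1], wide_b[, 2], paired = TRUE)
  expect_equal(res$F[res$effect == "b"], unname(tt$statistic^2), tolerance = 1e-8)
  expect_equal(res$df2, rep(n - 1, 3))
  expect_true(all(res$eta_p2 >= 0 & res$eta_p2 <= 1))
})

test_that("rm-ANOVA handles degenerate inputs per contract", {
  tab <- expand.grid(subject = 1:5, a = c("x", "y"), b = c("u", "v"))
  tab$value <- 3
  res <- rm_anova_2x2(tab)
  expect_equal(res$F, rep(0, 3))
  expect_error(rm_anova_2x2(tab[-1, ]), "all four cells")
  expect_error(rm_anova_2x2(transform(tab[tab$subject < 3, ], value = 1)), "at least 3")
})

test_that("paired bootstrap t-test: degenerate, strong and null cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(bootstrap_ttest_paired(x, x)$p_boot, 1)
  expect_equal(bootstrap_ttest_paired(x, x)$t_obs, 0)
  expect_error(bootstrap_ttest_paired(x, x - 2), "zero-variance")
  # strong separation (d > 3, n = 20) is highly significant
  set.seed(9)
  a <- rnorm(20, 4, 1)
  b <- rnorm(20, 0, 1)
  expect_lte(bootstrap_ttest_paired(a, b, n_boot = 1000, seed = 2)$p_boot, 0.01)
})

test_that("bootstrap t-test has calibrated type-I error under the null", {
  set.seed(123)
  reject <- vapply(1:400, function(i) {
    x <- rnorm(15)
    y <- rnorm(15)
    bootstrap_ttest_paired(x, y, n_boot = 199, seed = i)$p_boot < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.02)
  expect_lte(mean(reject), 0.09)
})

test_that("repeated-measures Cohen's d: arithmetic, degenerate case, recovery", {
  # constant differences: undefined
  expect_error(cohens_d_rm(1:4, 1:4 + 2), "undefined")
  # mean difference 1, SD of differences 2 -> d = 0.5
  expect_equal(cohens_d_rm(c(-1, 1, 3), c(0, 0, 0)), 0.5)
  # Monte-Carlo recovery of a configured true d = 0.8 at n = 500
  set.seed(77)
  d_hat <- cohens_d_rm(rnorm(500, 0.8, 1), rnorm(500, 0, 1e-12))
  expect_equal(d_hat, 0.8, tolerance = 0.1)
})

test_that("Benjamini-Yekutieli adjustment matches hand-computed values", {
  expect_equal(adjust_fdr_by(0.2), 0.2)
  # m = 2: c(2) = 1 + 1/2 = 1.5; step-up from the largest p:
  # p(2) = 0.04 * (2/2) * 1.5 = 0.06; p(1) = min(0.06, 0.01 * 2 * 1.5) = 0.03
  expect_equal(adjust_fdr_by(c(0.01, 0.04)), c(0.03, 0.06), tolerance = 1e-12)
  expect_equal(adjust_fdr_by(c(1, 1, 1)), c(1, 1, 1))
  expect_error(adjust_fdr_by(c(0.5, 1.2)), "0, 1")
  # BY >= BH >= raw, elementwise, against the reference step-up
  set.seed(4)
  p <- runif(25)
  expect_true(all(adjust_fdr_by(p) >= p.adjust(p, "BH")))
  expect_true(all(p.adjust(p, "BH") >= p))
})

test_that("RT exclusion keeps strictly 100-1000 ms", {
  ep <- toy_epochs(n = 3, rt = c(50, 500, 1200))
  out <- rt_filter(ep)
  expect_equal(out$trial_meta$rt, 500)
  df <- data.frame(rt = c(100, 100.1, 999.9, 1000))
  expect_equal(rt_filter(df)$rt, c(100.1, 999.9))
  ok <- toy_epochs(n = 4, rt = c(200, 300, 400, 500))
  expect_equal(n_trials(rt_filter(ok)), 4)
  expect_equal(nrow(rt_filter(df[0, , drop = FALSE])), 0)
})

test_that("ERP image: scaling, sorting and trial smoothing", {
  # constant value 2 scales to 1 everywhere
  img <- erp_image(toy_epochs(n = 45, fill = 2), "FCz", ma_window = 40)
  expect_true(all(img$image == 1))
  expect_equal(nrow(img$image), 45 - 40 + 1)
  # ma_window = 1 returns the RT-sorted single trials (scaled)
  d <- array(0, c(5, 4, 10))
  for (i in 1:5) d[i, 1, ] <- i
  ep <- toy_epochs(data = d, times = seq(0, 18, 2), rt = c(300, 100, 500, 200, 400))
  img <- erp_image(ep, "FCz", ma_window = 1)
  expect_equal(img$order, c(2, 4, 1, 5, 3))
  expect_equal(img$image[, 1], c(2, 4, 1, 5, 3) / 5)
  expect_equal(img$rt, sort(ep$trial_meta$rt))
  # alternating +1/-1 rows with ma_window = 2 average to zero
  d2 <- array(rep(c(1, -1), each = 1, times = 20), c(4, 4, 10))
  for (i in 1:4) d2[i, , ] <- (-1)^(i + 1)
  ep2 <- toy_epochs(data = d2, times = seq(0, 18, 2), rt = 1:4 * 100)
  img2 <- erp_image(ep2, "FCz", ma_window = 2)
  expect_true(all(abs(img2$image) < 1e-12))
  expect_error(erp_image(ep2, "FCz", ma_window = 10), "at least ma_window")
})
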