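#' Component measurement window
#'
#' The two shipped windows quantify the error negativity (Ne) as the mean
#' voltage 20-100 ms post-response at FCz and the error positivity (Pe)
#' as the mean voltage 180-250 ms post-response at Cz.
#'
#' @param name `"Ne"` or `"Pe"` (free-form names are allowed).
#' @param channel channel label at which the component is measured.
#' @param window `c(start, end)` in ms post-response, both endpoints
#'   inclusive on the discrete time grid.
#' @return an object of class `component_window`.
#' @export
component_window <- function(name, channel, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  structure(list(name = name, channel = channel, window = window),
            class = "component_window")
}

#' @rdname component_window
#' @export
ne_window <- function() component_window("Ne", "FCz", c(20, 100))

#' @rdname component_window
#' @export
pe_window <- function() component_window("Pe", "Cz", c(180, 250))

#' Windowed mean amplitude
#'
#' Mean of the samples whose time `t` satisfies `start <= t <= end` at the
#' named channel. For an `erp_epochs` input a per-trial vector is
#' returned; for a condition ERP (an `erp_erp`, see [condition_erps()]) a
#' scalar.
#'
#' @param x an `erp_epochs` or `erp_erp`.
#' @param cw a `component_window`.
#' @return numeric vector (one value per trial) or scalar, in microvolts.
#' @export
windowed_mean <- function(x, cw) {
  UseMethod("windowed_mean")
}

#' @export
windowed_mean.erp_epochs <- function(x, cw) {
  sel <- which(x$times >= cw$window[1] & x$times <= cw$window[2])
  if (length(sel) == 0) stopf("window [%g, %g] ms outside the epoch time axis",
                              cw$window[1], cw$window[2])
  m <- channel_matrix(x, cw$channel)
  rowMeans(m[, sel, drop = FALSE])
}

#' @export
windowed_mean.erp_erp <- function(x, cw) {
  sel <- which(x$times >= cw$window[1] & x$times <= cw$window[2])
  if (length(sel) == 0) stopf("window [%g, %g] ms outside the epoch time axis",
                              cw$window[1], cw$window[2])
  j <- match(cw$channel, x$channel_names)
  if (is.na(j)) stopf("channel '%s' not present", cw$channel)
  mean(x$data[j, sel])
}

#' Condition event-related potentials
#'
#' Averages trials within every (task, response) cell present in the
#' metadata. Each result is a channel x time matrix with its trial count.
#'
#' @param x an `erp_epochs`.
#' @return named list of `erp_erp` objects (`<task>.<response>`), each
#'   with fields `data` (channel x time), `channel_names`, `times`,
#'   `n_trials`.
#' @export
condition_erps <- function(x) {
  meta <- x$trial_meta
  if (is.null(meta$task)) meta$task <- "task"
  cells <- split(seq_len(nrow(meta)), interaction(meta$task, meta$response, drop = TRUE))
  lapply(cells, function(idx) {
    m <- x$data[idx, , , drop = FALSE]
    erp <- apply(m, c(2, 3), mean)
    structure(list(data = erp, channel_names = x$montage$channel_names,
                   times = x$times, n_trials = length(idx)),
              class = "erp_erp")
  })
}

#' Two-by-two repeated-measures ANOVA
#'
#' Within-subject 2x2 ANOVA computed through the subject-level contrasts:
#' for each effect (factor A, factor B, interaction) the per-subject
#' contrast is formed and the effect F equals the squared paired t on that
#' contrast, with df = (1, n - 1) and partial eta squared
#' `t^2 / (t^2 + n - 1)`.
#'
#' @param table data.frame with columns `subject`, `a`, `b`, `value`,
#'   where `a` and `b` are two-level factors and every subject has all
#'   four cells exactly once.
#' @return data.frame with one row per effect (`a`, `b`, `a:b`):
#'   `effect`, `F`, `df1`, `df2`, `p`, `eta_p2`.
#' @export
rm_anova_2x2 <- function(table) {
  stopifnot(all(c("subject", "a", "b", "value") %in% names(table)))
  a_lv <- sort(unique(as.character(table$a)))
  b_lv <- sort(unique(as.character(table$b)))
  if (length(a_lv) != 2 || length(b_lv) != 2) stopf("both factors must have 2 levels")
  wide <- stats::reshape(
    transform(table, cell = paste(a, b, sep = ".")),
    idvar = "subject", timevar = "cell",
    direction = "wide", drop = c("a", "b"))
  cells <- paste("value", c(paste(a_lv[1], b_lv, sep = "."),
                            paste(a_lv[2], b_lv, sep = ".")), sep = ".")
  if (!all(cells %in% names(wide)) || anyNA(wide[cells]))
    stopf("every subject needs all four cells")
  n <- nrow(wide)
  if (n < 3) stopf("need at least 3 subjects")
  m <- as.matrix(wide[cells]) # columns: a1b1 a1b2 a2b1 a2b2
  contrasts <- list(
    a       = c(1, 1, -1, -1) / 2,
    b       = c(1, -1, 1, -1) / 2,
    `a:b`   = c(1, -1, -1, 1))
  out <- lapply(names(contrasts), function(eff) {
    d <- drop(m %*% contrasts[[eff]])
    if (stats::sd(d) == 0) {
      # degenerate: no between-subject variability on this contrast
      f <- if (mean(d) == 0) 0 else Inf
    } else {
      f <- (mean(d) / (stats::sd(d) / sqrt(n)))^2
    }
    data.frame(effect = eff, F = f, df1 = 1, df2 = n - 1,
               p = stats::pf(f, 1, n - 1, lower.tail = FALSE),
               eta_p2 = if (is.infinite(f)) 1 else f / (f + n - 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Paired bootstrap t-test
#'
#' Observed statistic is the paired t; the null distribution is obtained
#' by resampling the mean-centered paired differences with replacement.
#' The two-sided p-value uses the add-one estimator
#' `(1 + #{|t*| >= |t_obs|}) / (n_boot + 1)`.
#'
#' @param x,y paired numeric vectors of equal length >= 3.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param seed RNG seed.
#' @return list with `t_obs`, `p_boot`, `n_boot`.
#' @export
bootstrap_ttest_paired <- function(x, y, n_boot = 2000, seed = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == d[1]) && d[1] == 0) return(list(t_obs = 0, p_boot = 1, n_boot = n_boot))
    stopf("zero-variance differences")
  }
  n <- length(d)
  t_obs <- mean(d) / (stats::sd(d) / sqrt(n))
  dc <- d - mean(d)
  t_star <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      di <- dc[sample.int(n, n, replace = TRUE)]
      s <- stats::sd(di)
      if (s == 0) return(0)
      mean(di) / (s / sqrt(n))
    }, numeric(1))
  })
  list(t_obs = t_obs,
       p_boot = (1 + sum(abs(t_star) >= abs(t_obs))) / (n_boot + 1),
       n_boot = n_boot)
}

#' Cohen's d for repeated measures
#'
#' The difference-score formulation: `mean(x - y) / sd(x - y)`. Among the
#' several repeated-measures variants in use this one matches the paired
#' t statistic up to `sqrt(n)`.
#'
#' @param x,y paired numeric vectors.
#' @return scalar effect size.
#' @export
cohens_d_rm <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) stopf("zero-variance differences: d is undefined")
  mean(d) / s
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary
#' dependence (with the harmonic-sum correction factor), as implemented
#' by `stats::p.adjust(method = "BY")`.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length.
#' @export
adjust_fdr_by <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stopf("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BY")
}

#' Reaction-time exclusion rule
#'
#' Keeps trials with 100 ms < RT < 1000 ms (strict inequalities).
#'
#' @param x an `erp_epochs`, or a data.frame with an `rt` column.
#' @return same type as the input, with out-of-range trials removed.
#' @export
rt_filter <- function(x) {
  if (inherits(x, "erp_epochs")) {
    keep <- x$trial_meta$rt > 100 & x$trial_meta$rt < 1000
    return(subset_trials(x, keep))
  }
  x[x$rt > 100 & x$rt < 1000, , drop = FALSE]
}

#' RT-sorted ERP image
#'
#' Single-channel trial x time image: trials sorted by ascending reaction
#' time, values scaled to [-1, 1] by the maximum absolute value, then
#' smoothed down the trial axis with a boxcar moving average of length
#' `ma_window` ("valid" convolution: `n - ma_window + 1` output rows).
#'
#' @param x an `erp_epochs` with RTs.
#' @param channel channel label.
#' @param ma_window moving-average length in trials (default 40).
#' @return list with `image` ((n - ma + 1) x time matrix), `order`
#'   (trial sort order), `rt` (sorted RTs), `times`.
#' @export
erp_image <- function(x, channel, ma_window = 40) {
  n <- n_trials(x)
  if (n < ma_window) stopf("need at least ma_window (%d) trials, got %d", ma_window, n)
  ord <- order(x$trial_meta$rt)
  m <- channel_matrix(x, channel)[ord, , drop = FALSE]
  mx <- max(abs(m))
  if (mx > 0) m <- m / mx
  if (ma_window > 1) {
    cs <- apply(m, 2, cumsum)
    cs <- rbind(0, cs)
    m <- (cs[(ma_window + 1):(n + 1), , drop = FALSE] -
            cs[1:(n - ma_window + 1), , drop = FALSE]) / ma_window
  }
  list(image = m, order = ord, rt = x$trial_meta$rt[ord], times = x$times)
}

#' Subject-level condition table for a simulated cohort
#'
#' Streams over the cohort (one subject at a time, simulating only the
#' channels needed) and tabulates, per subject x task x response: the Ne
#' and Pe windowed mean amplitudes, mean RT after the 100-1000 ms
#' exclusion, trial counts and empirical error rate. This is the input
#' to the 2x2 repeated-measures ANOVAs and the behavioral tests, and the
#' basis of the effect-recovery checks.
#'
#' @param config a `simulation_config`.
#' @param channels channels to simulate (default: the two measurement
#'   channels; see [simulate_subject()] for why a subset is distributionally
#'   exact).
#' @return data.frame with one row per subject x task x response.
#' @export
cohort_condition_table <- function(config, channels = c("FCz", "Cz")) {
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    for (k in seq_along(config$tasks)) {
      tk <- config$tasks[[k]]
      ep <- simulate_subject(config, i, tk,
                             seed = derive_seed(config$seed, i, k),
                             channels = channels)
      ep <- rt_filter(ep)
      ne <- windowed_mean(ep, ne_window())
      pe <- windowed_mean(ep, pe_window())
      for (resp in c("error", "correct")) {
        sel <- ep$trial_meta$response == resp
        rows[[length(rows) + 1]] <- data.frame(
          subject = i, task = tk$name, response = resp,
          ne = mean(ne[sel]), pe = mean(pe[sel]),
          rt = mean(ep$trial_meta$rt[sel]), n = sum(sel),
          error_rate = mean(ep$trial_meta$response == "error"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
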