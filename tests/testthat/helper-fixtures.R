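# Shared fixtures: all data are built in code at test time.

# internal helpers exercised directly by the tests
with_seed <- errclass:::with_seed
pink_noise_matrix <- errclass:::pink_noise_matrix
stratified_folds <- errclass:::stratified_folds
make_cv_context <- errclass:::make_cv_context
cv_eval <- errclass:::cv_eval

# Channels needed by both feature sets, plus mastoids for re-referencing.
feature_channels <- function() c("Fz", "FCz", "FC1", "FC2", "Cz", "CPz", "C1", "C2")

# A small, fast cohort configuration; `...` overrides make_default_config
# arguments (noise, effect sizes, trial counts, ...).
small_config <- function(n_subjects = 2, n_trials_range = c(40, 60), ...) {
  make_default_config(n_subjects = n_subjects, n_trials_range = n_trials_range, ...)
}

# Noise-free configuration with no between-subject variability: every
# voltage is an exact closed-form function of the component specs.
noiseless_config <- function(...) {
  small_config(noise = noise_spec(0, 0, 0), between_subject_amplitude_sd = 0, ...)
}

# Epochs with constant or user-supplied voltages on a tiny montage.
toy_montage <- function(channels = c("FCz", "Cz", "M1", "M2")) {
  std <- standard_montage()
  idx <- match(channels, std$channel_names)
  montage(channels, std$positions[idx, , drop = FALSE], std$channel_types[idx])
}

toy_epochs <- function(n = 4, channels = c("FCz", "Cz", "M1", "M2"),
                       times = seq(-200, 798, by = 2), fill = 0,
                       data = NULL, response = NULL, rt = NULL) {
  m <- toy_montage(channels)
  if (is.null(data)) data <- array(fill, c(n, length(channels), length(times)))
  n <- dim(data)[1]
  if (is.null(response)) response <- rep(c("error", "correct"), length.out = n)
  meta <- data.frame(subject_id = 1L, task = "flanker", response = response,
                     rt = if (is.null(rt)) stats::runif(n, 200, 400) else rt)
  epochs(data, m, 1000 / diff(times[1:2]), times, meta, lock = "response")
}

# Exact per-channel expectation of a noiseless simulated trial's windowed
# mean: sum over components of amplitude x spatial weight x discrete
# window factor.
closed_form_windowed_mean <- function(config, task, response, channel, cw) {
  tk <- config$tasks[[task]]
  grid <- seq(config$epoch_window[1], config$epoch_window[2],
              by = 1000 / config$sampling_rate)
  val <- 0
  for (cn in c("ne", "pe")) {
    comp <- tk[[cn]]
    amp <- if (response == "error") comp$amplitude_error else comp$amplitude_correct
    d <- channel_distances(config$montage, comp$peak_channel)[[channel]]
    w <- exp(-d^2 / (2 * comp$spatial_sigma^2))
    f <- gaussian_window_factor(comp$peak_latency, comp$width, cw$window, times = grid)
    val <- val + amp * w * f
  }
  val
}

# Separable two-cluster feature epochs for classifier tests: errors and
# correct trials sit in well-separated Gaussian clouds at every feature
# electrode.
separable_epochs <- function(n_per_class = 20, gap = 30, sd = 1, seed = 42,
                             times = seq(-200, 798, by = 2)) {
  chans <- feature_channels()
  n <- 2 * n_per_class
  resp <- rep(c("error", "correct"), each = n_per_class)
  data <- array(0, c(n, length(chans), length(times)))
  with_seed(seed, {
    for (i in seq_len(n)) {
      mu <- if (resp[i] == "error") gap else 0
      for (j in seq_along(chans)) {
        data[i, j, ] <- rnorm(1, mu, sd)
      }
    }
  })
  toy_epochs(data = data, channels = chans, times = times, response = resp)
}

# Tiny hyperparameter grids that keep grid searches fast in tests.
tiny_grid <- function() {
  list(coarse_c = 2^c(-1, 3, 7), coarse_gamma = 2^c(-7, -3, 1),
       fine_span = 1, fine_step = 1)
}
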