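#' Feature set specification
#'
#' The Ne feature set is the windowed mean voltage (20-100 ms) at the five
#' electrodes around the Ne peak (Fz, FCz, FC1, FC2, Cz); the Pe set the
#' windowed mean (180-250 ms) at the five electrodes around the Pe peak
#' (Cz, FCz, CPz, C1, C2); the combined set concatenates both (10
#' features, Ne columns first).
#'
#' @param name `"ne"`, `"pe"` or `"combined"`.
#' @return an object of class `feature_set_spec` with fields `name` and
#'   `parts` (list of (electrodes, window) blocks).
#' @export
feature_set_spec <- function(name = c("ne", "pe", "combined")) {
  name <- match.arg(name)
  ne_part <- list(prefix = "ne", electrodes = c("Fz", "FCz", "FC1", "FC2", "Cz"),
                  window = c(20, 100))
  pe_part <- list(prefix = "pe", electrodes = c("Cz", "FCz", "CPz", "C1", "C2"),
                  window = c(180, 250))
  parts <- switch(name,
                  ne = list(ne_part),
                  pe = list(pe_part),
                  combined = list(ne_part, pe_part))
  structure(list(name = name, parts = parts), class = "feature_set_spec")
}

#' Feature matrix container
#'
#' @param values trials x features numeric matrix.
#' @param feature_names character vector of column names.
#' @param labels per-trial factor/character labels (`"error"`/`"correct"`).
#' @param scaled logical flag: values have been scaled to [0, 1].
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_names, labels, scaled = FALSE) {
  values <- as.matrix(values)
  if (anyNA(values)) stopf("feature values must not contain NA")
  if (length(labels) != nrow(values)) stopf("labels length must match rows")
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 labels = as.character(labels), scaled = scaled),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%s); %d error / %d correct\n",
              nrow(x$values), ncol(x$values),
              if (x$scaled) "scaled" else "microvolts",
              sum(x$labels == "error"), sum(x$labels == "correct")))
  invisible(x)
}

#' Extract windowed-mean features from epochs
#'
#' One row per trial; entry (trial, electrode) is the mean voltage at that
#' electrode within the block's time window.
#'
#' @param x an `erp_epochs`.
#' @param spec a `feature_set_spec`.
#' @return an unscaled `feature_matrix` with labels taken from the trial
#'   metadata.
#' @export
extract_features <- function(x, spec) {
  cols <- list()
  nms <- character(0)
  for (part in spec$parts) {
    missing <- setdiff(part$electrodes, x$montage$channel_names)
    if (length(missing) > 0)
      stopf("electrode(s) missing from montage: %s", paste(missing, collapse = ", "))
    for (el in part$electrodes) {
      cw <- component_window(part$prefix, el, part$window)
      cols[[length(cols) + 1]] <- windowed_mean(x, cw)
      nms <- c(nms, paste(part$prefix, el, sep = "_"))
    }
  }
  feature_matrix(do.call(cbind, cols), nms, x$trial_meta$response, scaled = FALSE)
}

#' Fit a [0, 1] linear scaler
#'
#' Records the per-feature minimum and maximum of the fitting rows.
#'
#' @param train a `feature_matrix` with >= 2 rows.
#' @return an object of class `scaler_params` (fields `min`, `max`).
#' @export
fit_scaler <- function(train) {
  if (nrow(train$values) < 2) stopf("need at least 2 rows to fit a scaler")
  structure(list(min = apply(train$values, 2, min),
                 max = apply(train$values, 2, max)),
            class = "scaler_params")
}

#' Apply a fitted scaler
#'
#' Maps each feature through `(v - min) / (max - min)`. Constant features
#' (max == min) map to 0.5; values outside the fitted range (from a
#' non-fitting partition) are clipped to [0, 1].
#'
#' @param x a `feature_matrix`.
#' @param s a `scaler_params` with matching feature count.
#' @return a scaled `feature_matrix`.
#' @export
apply_scaler <- function(x, s) {
  if (length(s$min) != ncol(x$values)) stopf("scaler/feature dimension mismatch")
  rng <- s$max - s$min
  v <- sweep(x$values, 2, s$min)
  v <- sweep(v, 2, ifelse(rng > 0, rng, 1), "/")
  v[, rng == 0] <- 0.5
  v[v < 0] <- 0
  v[v > 1] <- 1
  feature_matrix(v, x$feature_names, x$labels, scaled = TRUE)
}

#' Balance classes by subsampling correct trials
#'
#' Keeps every error trial and a seeded uniform random sample (without
#' replacement) of equally many correct trials, then shuffles the row
#' order deterministically. Re-drawing with a different seed yields the
#' per-repeat correct-trial samples of the 10-repeat analysis scheme.
#'
#' @param fm a `feature_matrix` containing both classes with
#'   `n_correct >= n_error`.
#' @param seed RNG seed for the subsample and shuffle.
#' @return a balanced `feature_matrix` with exactly equal class counts.
#' @export
balance_classes <- function(fm, seed) {
  err <- which(fm$labels == "error")
  cor <- which(fm$labels == "correct")
  if (length(err) == 0 || length(cor) == 0) stopf("both classes must be present")
  if (length(cor) < length(err))
    stopf("fewer correct than error trials; swap class roles upstream")
  keep <- with_seed(seed, {
    sel <- c(err, sort(sample(cor, length(err))))
    sample(sel)
  })
  feature_matrix(fm$values[keep, , drop = FALSE], fm$feature_names,
                 fm$labels[keep], fm$scaled)
}
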