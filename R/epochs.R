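#' Single-trial epochs container
#'
#' Holds a trial x channel x sample voltage array (microvolts) together
#' with its montage, sampling rate, time axis and per-trial metadata.
#'
#' @param data numeric array, dimensions (trial, channel, sample).
#' @param montage an `erp_montage` whose channels match `dim(data)[2]`.
#' @param sampling_rate sampling rate in Hz.
#' @param times numeric vector of sample times in ms relative to the lock
#'   event; length must equal `dim(data)[3]`.
#' @param trial_meta data.frame with one row per trial; must contain a
#'   `response` column with values `"error"` or `"correct"` and may carry
#'   `subject_id`, `task` and `rt` (ms).
#' @param lock `"response"` or `"stimulus"`.
#' @return an object of class `erp_epochs`.
#' @export
epochs <- function(data, montage, sampling_rate, times, trial_meta,
                   lock = c("response", "stimulus")) {
  lock <- match.arg(lock)
  if (length(dim(data)) != 3) stopf("data must be a 3-d array (trial x channel x sample)")
  if (dim(data)[2] != length(montage$channel_names))
    stopf("channel dimension (%d) does not match montage (%d)",
          dim(data)[2], length(montage$channel_names))
  if (dim(data)[3] != length(times)) stopf("sample dimension does not match times")
  if (nrow(trial_meta) != dim(data)[1]) stopf("trial_meta rows do not match trials")
  if (!"response" %in% names(trial_meta)) stopf("trial_meta must have a 'response' column")
  if (!all(trial_meta$response %in% c("error", "correct")))
    stopf("response labels must be 'error' or 'correct'")
  if (anyNA(data)) stopf("epoch voltages must not contain NaN/NA")
  structure(list(data = data, montage = montage,
                 sampling_rate = sampling_rate, times = times,
                 trial_meta = trial_meta, lock = lock),
            class = "erp_epochs")
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat(sprintf("<erp_epochs> %d trials x %d channels x %d samples (%g Hz, %s-locked)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate, x$lock))
  cat(sprintf("  time %g..%g ms; %d error / %d correct trials\n",
              min(x$times), max(x$times),
              sum(x$trial_meta$response == "error"),
              sum(x$trial_meta$response == "correct")))
  invisible(x)
}

#' Number of trials in an epochs object
#' @param x an `erp_epochs`.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' Subset epochs by trial index
#'
#' @param x an `erp_epochs`.
#' @param i integer or logical trial index.
#' @return an `erp_epochs` with the selected trials.
#' @export
subset_trials <- function(x, i) {
  epochs(x$data[i, , , drop = FALSE], x$montage, x$sampling_rate, x$times,
         x$trial_meta[i, , drop = FALSE], x$lock)
}

#' Extract one channel as a trial x sample matrix
#' @param x an `erp_epochs`.
#' @param channel channel label.
#' @export
channel_matrix <- function(x, channel) {
  j <- match(channel, x$montage$channel_names)
  if (is.na(j)) stopf("channel '%s' not present", channel)
  m <- x$data[, j, , drop = FALSE]
  dim(m) <- dim(x$data)[c(1, 3)]
  m
}
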