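#' Persist epochs to the internal container
#'
#' Writes two files: `<path>.bin`, the voltage array as little-endian
#' float64 in (trial, channel, sample) order (trial index varying
#' fastest, R column-major), and `<path>.json`, a metadata sidecar with
#' the montage, sampling rate, time axis, lock event and per-trial
#' metadata table. The round trip through [read_epochs()] is lossless.
#'
#' @param x an `erp_epochs`.
#' @param path file path prefix (without extension).
#' @return invisibly, the two file paths.
#' @export
write_epochs <- function(x, path) {
  bin <- paste0(path, ".bin")
  js <- paste0(path, ".json")
  con <- file(bin, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(x$data), con, size = 8, endian = "little")
  meta <- list(
    format = "errclass-epochs", version = 1L,
    dims = dim(x$data), endian = "little", dtype = "float64",
    sampling_rate = x$sampling_rate, times = x$times, lock = x$lock,
    montage = list(channel_names = x$montage$channel_names,
                   positions = unname(x$montage$positions),
                   channel_types = x$montage$channel_types),
    trial_meta = x$trial_meta)
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(bin, js))
}

read_epochs_container <- function(path) {
  js <- paste0(path, ".json")
  bin <- paste0(path, ".bin")
  if (!file.exists(js)) stopf("metadata sidecar not found: %s", js)
  if (!file.exists(bin)) stopf("voltage file not found: %s", bin)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (!identical(meta$format, "errclass-epochs"))
    stopf("'%s' is not an epochs container", js)
  dims <- as.integer(meta$dims)
  n_values <- prod(dims)
  expect_bytes <- n_values * 8
  got_bytes <- file.info(bin)$size
  if (got_bytes < expect_bytes)
    stopf("truncated voltage file '%s': expected %d bytes, found %d (short at byte offset %d)",
          bin, expect_bytes, got_bytes, got_bytes)
  con <- file(bin, "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, "double", n = n_values, size = 8, endian = "little")
  meta_df <- as.data.frame(meta$trial_meta, stringsAsFactors = FALSE)
  if (!"response" %in% names(meta_df))
    stopf("container '%s' lacks per-trial response labels", path)
  m <- montage(meta$montage$channel_names,
               matrix(unlist(meta$montage$positions), ncol = 2, byrow = !is.matrix(meta$montage$positions)),
               meta$montage$channel_types)
  epochs(array(v, dims), m, meta$sampling_rate, meta$times, meta_df,
         lock = meta$lock)
}

#' Read epochs from disk
#'
#' @param path file path: the container prefix (for
#'   `format = "container"`) or a BrainVision `.vhdr` header (for
#'   `format = "brainvision"`).
#' @param format one of `"container"`, `"brainvision"`, `"eeglab-set"`.
#'   The EEGLAB `.set` route (a MATLAB v5 file) is not implemented.
#' @param window,lock,label_map only for `"brainvision"`: epoch window in
#'   ms, lock type, and a named character vector mapping marker
#'   descriptions to `"error"`/`"correct"` labels.
#' @return an `erp_epochs`.
#' @export
read_epochs <- function(path, format = c("container", "brainvision", "eeglab-set"),
                        window = c(-200, 798), lock = "response",
                        label_map = NULL) {
  format <- match.arg(format)
  switch(format,
         container = read_epochs_container(path),
         brainvision = {
           bv <- read_brainvision(path)
           ev <- bv$markers[bv$markers$description %in% names(label_map), , drop = FALSE]
           if (nrow(ev) == 0) stopf("no markers matching label_map found")
           events <- data.frame(sample = ev$position,
                                response = unname(label_map[ev$description]),
                                stringsAsFactors = FALSE)
           segment_epochs(bv$continuous, events, window, lock = lock)
         },
         `eeglab-set` = stopf("EEGLAB .set input is not supported; export to BrainVision or the internal container"))
}

# Minimal INI-style section parser for BrainVision headers.
parse_bv_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Supports the common binary variants: IEEE_FLOAT_32 and INT_16, in
#' MULTIPLEXED or VECTORIZED orientation, with per-channel resolution
#' scaling to microvolts. Returns the continuous recording plus the
#' marker table from the `.vmrk` file. Channel positions are not stored
#' in BrainVision headers, so schematic positions are taken from
#' [standard_montage()] where channel names match and set to the origin
#' otherwise.
#'
#' @param vhdr_path path to the `.vhdr` header file.
#' @return list with `continuous` (an `erp_continuous`) and `markers`
#'   (data.frame: type, description, position, length, channel).
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stopf("header not found: %s", vhdr_path)
  hdr <- parse_bv_ini(readLines(vhdr_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  bi <- hdr[["Binary Infos"]]
  if (!identical(toupper(ci$DataFormat), "BINARY"))
    stopf("only BINARY BrainVision data are supported")
  n_ch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  dirn <- dirname(vhdr_path)
  ch_entries <- hdr[["Channel Infos"]]
  ch <- t(vapply(ch_entries, function(v) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    c(name = parts[1], resolution = if (length(parts) >= 3 && nzchar(parts[3])) parts[3] else "1")
  }, character(2)))
  fmt <- toupper(bi$BinaryFormat)
  eeg_file <- file.path(dirn, ci$DataFile)
  sz <- file.info(eeg_file)$size
  if (is.na(sz)) stopf("data file not found: %s", eeg_file)
  con <- file(eeg_file, "rb")
  on.exit(close(con), add = TRUE)
  if (fmt == "IEEE_FLOAT_32") {
    raw_v <- readBin(con, "double", n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    raw_v <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                     endian = "little")
  } else stopf("unsupported BinaryFormat '%s'", bi$BinaryFormat)
  n_samp <- length(raw_v) %/% n_ch
  raw_v <- raw_v[seq_len(n_samp * n_ch)]
  orient <- toupper(ci$DataOrientation)
  d <- if (orient == "VECTORIZED") {
    t(matrix(raw_v, n_samp, n_ch))
  } else {
    matrix(raw_v, n_ch, n_samp)
  }
  d <- d * as.numeric(ch[, "resolution"])
  std <- standard_montage()
  pos <- matrix(0, n_ch, 2)
  hit <- match(ch[, "name"], std$channel_names)
  pos[!is.na(hit), ] <- std$positions[hit[!is.na(hit)], ]
  types <- ifelse(!is.na(hit), std$channel_types[replace(hit, is.na(hit), 1)], "eeg")
  mont <- montage(unname(ch[, "name"]), pos, types)
  markers <- data.frame(type = character(0), description = character(0),
                        position = integer(0), length = integer(0),
                        channel = integer(0), stringsAsFactors = FALSE)
  if (!is.null(ci$MarkerFile)) {
    vmrk <- file.path(dirn, ci$MarkerFile)
    if (file.exists(vmrk)) {
      mk <- parse_bv_ini(readLines(vmrk, warn = FALSE))[["Marker Infos"]]
      if (length(mk) > 0) {
        markers <- do.call(rbind, lapply(mk, function(v) {
          p <- strsplit(v, ",", fixed = TRUE)[[1]]
          data.frame(type = p[1], description = p[2],
                     position = as.integer(p[3]),
                     length = as.integer(p[4]),
                     channel = as.integer(p[5]), stringsAsFactors = FALSE)
        }))
        rownames(markers) <- NULL
      }
    }
  }
  list(continuous = continuous_record(d, mont, fs), markers = markers)
}

#' Write a continuous recording in BrainVision format
#'
#' IEEE_FLOAT_32, multiplexed. Mainly used for round-trip testing of the
#' reader and for exporting synthetic data to other EEG toolboxes.
#'
#' @param continuous an `erp_continuous`.
#' @param path_prefix output path without extension; writes `.vhdr`,
#'   `.vmrk` and `.eeg`.
#' @param markers optional data.frame with `description` and `position`
#'   (1-based sample) columns.
#' @return invisibly, the header path.
#' @export
write_brainvision <- function(continuous, path_prefix, markers = NULL) {
  base <- basename(path_prefix)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", base, ".eeg"),
           paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nrow(continuous$data)),
           paste0("SamplingInterval=", format(1e6 / continuous$sampling_rate, scientific = FALSE)),
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_len(nrow(continuous$data)),
                   continuous$montage$channel_names))
  writeLines(hdr, paste0(path_prefix, ".vhdr"), useBytes = TRUE)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Marker Infos]")
  if (!is.null(markers) && nrow(markers) > 0) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(markers)),
                        markers$description, markers$position))
  }
  writeLines(mk, paste0(path_prefix, ".vmrk"))
  con <- file(paste0(path_prefix, ".eeg"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(continuous$data), con, size = 4, endian = "little")
  invisible(paste0(path_prefix, ".vhdr"))
}

#' Export the per-trial metadata table as TSV
#'
#' @param x an `erp_epochs`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_trial_table <- function(x, path) {
  utils::write.table(x$trial_meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
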