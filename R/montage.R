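#' Electrode montage
#'
#' A montage is a set of uniquely named channels with schematic 2-D
#' head-surface coordinates (head radius approximately 1, x increasing to
#' the right, y increasing towards the front). Coordinates are only used
#' for the isotropic spatial falloff of simulated components and for
#' simple layout plots, so a schematic projection is sufficient.
#'
#' @param channel_names character vector of unique channel labels.
#' @param positions numeric matrix (channels x 2) of finite coordinates.
#' @param channel_types character vector: `"eeg"`, `"mastoid"` or `"eog"`.
#'   Non-EEG channels are excluded from pooled artifact statistics.
#' @return an object of class `erp_montage`.
#' @export
montage <- function(channel_names, positions,
                    channel_types = rep("eeg", length(channel_names))) {
  if (anyDuplicated(channel_names)) stopf("montage channel names must be unique")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(channel_names) || ncol(positions) != 2)
    stopf("positions must be a (channels x 2) matrix")
  if (!all(is.finite(positions))) stopf("montage positions must be finite")
  if (length(channel_types) != length(channel_names))
    stopf("channel_types length mismatch")
  rownames(positions) <- channel_names
  structure(list(channel_names = channel_names,
                 positions = positions,
                 channel_types = channel_types),
            class = "erp_montage")
}

#' Standard 63-channel recording montage
#'
#' The extended 10-10 EEG layout used throughout the package: 57 scalp
#' electrodes, two mastoids (M1, M2) and four periocular EOG channels,
#' 63 channels in total. All electrodes required for the Ne feature set
#' (Fz, FCz, FC1, FC2, Cz) and the Pe feature set (Cz, FCz, CPz, C1, C2)
#' are included. Positions are schematic: row labels map to an
#' anterior-posterior coordinate and electrode numbers to symmetric
#' left/right offsets.
#'
#' @return an `erp_montage` with 63 channels.
#' @export
standard_montage <- function() {
  scalp <- c("FPz", "FP1", "FP2", "AFz", "AF7", "AF3", "AF4", "AF8",
             "Fz", "F7", "F3", "F4", "F8",
             "FCz", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8",
             "T7", "C5", "C3", "Cz", "C1", "C2", "C4", "C6", "T8",
             "TP7", "TP8", "CPz", "CP5", "CP3", "CP1", "CP2", "CP4", "CP6",
             "Pz", "P7", "P3", "P1", "P2", "P4", "P8",
             "POz", "PO9", "PO7", "PO3", "PO4", "PO8", "PO10",
             "Oz", "O1", "O2")
  row_y <- c(FP = 0.90, AF = 0.72, F = 0.54, FT = 0.28, FC = 0.28,
             T = 0.00, C = 0.00, TP = -0.28, CP = -0.28,
             P = -0.54, PO = -0.72, O = -0.90)
  idx_x <- c(0.18, 0.18, 0.40, 0.40, 0.62, 0.62, 0.82, 0.82, 0.95, 0.95)
  pos <- t(vapply(scalp, function(ch) {
    row <- sub("[0-9z]+$", "", ch)
    num <- sub("^[A-Z]+", "", ch)
    y <- row_y[[row]]
    if (num == "z") return(c(0, y))
    i <- as.integer(num)
    x <- idx_x[i] * if (i %% 2 == 1) -1 else 1
    c(x, y)
  }, numeric(2)))
  aux <- rbind(M1 = c(-0.95, -0.30), M2 = c(0.95, -0.30),
               SO2 = c(0.25, 0.98), IO2 = c(0.25, 1.06),
               LO1 = c(-0.55, 0.94), LO2 = c(0.55, 0.94))
  montage(c(scalp, rownames(aux)),
          rbind(pos, aux),
          c(rep("eeg", length(scalp)),
            "mastoid", "mastoid", rep("eog", 4)))
}

#' Euclidean distance of every montage channel to a reference channel
#'
#' @param m an `erp_montage`.
#' @param channel reference channel label.
#' @return named numeric vector of distances.
#' @export
channel_distances <- function(m, channel) {
  if (!channel %in% m$channel_names) stopf("channel '%s' not in montage", channel)
  p0 <- m$positions[channel, ]
  d <- sqrt(rowSums(sweep(m$positions, 2, p0)^2))
  names(d) <- m$channel_names
  d
}
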