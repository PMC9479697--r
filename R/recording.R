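#' Multichannel EEG/EOG recording
#'
#' Container for a time-major multichannel biosignal recording: a numeric
#' sample matrix (rows = time, columns = channels, amplitudes in microvolts),
#' a sampling rate, ordered channel labels and a per-channel modality tag
#' (`"EEG"` or `"EOG"`).
#'
#' @param samples numeric matrix, one column per channel, one row per sample.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector of channel names, one per column.
#' @param modality character vector of `"EEG"`/`"EOG"`, one per column.
#' @return an object of class `psa_recording`.
#' @examples
#' rec <- new_recording(matrix(rnorm(200), ncol = 2), fs = 100,
#'                      channel_labels = c("Cz", "HEOG"),
#'                      modality = c("EEG", "EOG"))
#' n_samples(rec)
#' @export
new_recording <- function(samples, fs, channel_labels, modality) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (length(channel_labels) != ncol(samples))
    stop("channel_labels length must equal channel count")
  if (length(modality) != ncol(samples))
    stop("modality length must equal channel count")
  if (!all(modality %in% c("EEG", "EOG")))
    stop("modality entries must be 'EEG' or 'EOG'")
  colnames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels),
                 modality = as.character(modality)),
            class = "psa_recording")
}

#' @export
print.psa_recording <- function(x, ...) {
  cat(sprintf("psa_recording: %d channels (%d EEG, %d EOG), %d samples @ %g Hz (%.1f s)\n",
              length(x$channel_labels), sum(x$modality == "EEG"),
              sum(x$modality == "EOG"), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  invisible(x)
}

#' @rdname new_recording
#' @param rec a `psa_recording`.
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' Subset a recording by modality
#'
#' @param rec a `psa_recording`.
#' @param modality `"EEG"` or `"EOG"`.
#' @return a `psa_recording` containing only the requested channels.
#' @export
recording_modality <- function(rec, modality) {
  keep <- rec$modality == modality
  if (!any(keep)) stop("no channels of modality ", modality)
  new_recording(rec$samples[, keep, drop = FALSE], rec$fs,
                rec$channel_labels[keep], rec$modality[keep])
}

#' Standard 30-channel 10-20 EEG montage plus two EOG channels
#'
#' Channel order is the fixed ordering contract used throughout the package
#' (feature vectors, synthetic recordings, reports).
#'
#' @return character vector of 32 channel labels (30 EEG then 2 EOG).
#' @export
psa_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "T7", "C3", "Cz", "C4", "T8",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2",
    "HEOG", "VEOG")
}

#' @rdname psa_montage
#' @export
psa_modality <- function() c(rep("EEG", 30), rep("EOG", 2))

#' Read or write a recording
#'
#' CSV dialect: a header row of channel labels, one sample per row, with a
#' JSON sidecar (`<path>.meta.json`) holding the sampling rate and per-channel
#' modality. EDF uses the standard 16-bit European Data Format; amplitudes
#' are quantized to the channel's physical range on write.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; default inferred from the extension.
#' @return `read_recording`: a `psa_recording`. `write_recording`: `path`,
#'   invisibly.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "edf") return(read_edf(path))
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop("format error: missing sidecar metadata file ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("format error: sidecar field 'fs' missing")
  dat <- read.csv(path, check.names = FALSE)
  if (ncol(dat) < 1L) stop("format error: no channel columns")
  labels <- colnames(dat)
  modality <- meta$modality
  if (is.null(modality)) stop("format error: sidecar field 'modality' missing")
  if (length(modality) != length(labels))
    stop("format error: modality length ", length(modality),
         " does not match ", length(labels), " channel columns")
  new_recording(as.matrix(dat), meta$fs, labels, modality)
}

#' @rdname read_recording
#' @param rec a `psa_recording`.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") return(write_edf(rec, path))
  df <- as.data.frame(rec$samples)
  colnames(df) <- rec$channel_labels
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, labels = rec$channel_labels,
                            modality = rec$modality),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
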