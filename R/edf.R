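# Minimal EDF (European Data Format) reader/writer for continuous
# equal-rate recordings. Header layout follows the EDF specification:
# 256-byte fixed header + 256 bytes per signal, then data records of
# 16-bit little-endian integers scaled channel-wise between the digital
# and physical ranges. Annotations and per-channel rates are not supported.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' @rdname read_recording
#' @export
write_edf <- function(rec, path) {
  ns <- length(rec$channel_labels)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- nrow(rec$samples)
  n_rec <- ceiling(n / fs)
  # pad the last record with the final sample value
  X <- rec$samples
  if (n < n_rec * fs)
    X <- rbind(X, X[rep(n, n_rec * fs - n), , drop = FALSE])
  pmin_ <- apply(X, 2, min); pmax_ <- apply(X, 2, max)
  span <- pmax_ - pmin_
  pmin_[span == 0] <- pmin_[span == 0] - 1
  pmax_[span == 0] <- pmax_[span == 0] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),                 # record duration, seconds
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  fld(rec$channel_labels, 16)
  fld(rep("", ns), 80)                                  # transducer
  fld(rep("uV", ns), 8)                                 # physical dimension
  fld(formatC(pmin_, digits = 6, format = "g"), 8)
  fld(formatC(pmax_, digits = 6, format = "g"), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rec$modality, 80)                                 # prefiltering: modality tag
  fld(rep(fs, ns), 8)                                   # samples per record
  fld(rep("", ns), 32)                                  # reserved

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- vapply(seq_len(ns), function(ch) {
      as.integer(round((X[idx, ch] - pmin_[ch]) * scale[ch]) + dmin)
    }, integer(fs))
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname read_recording
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("format error: invalid signal count in EDF header")
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  prefilter <- rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1L)
    stop("format error: per-channel sampling rates are not supported")
  if (seek(con) != hdr_bytes) seek(con, hdr_bytes)
  fs <- spr[1] / rec_dur
  X <- matrix(0, nrow = n_rec * spr[1], ncol = ns)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    blk <- matrix(raw, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns))
      X[idx, ch] <- pmin_[ch] + (blk[, ch] - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
  }
  modality <- ifelse(prefilter %in% c("EEG", "EOG"), prefilter,
                     ifelse(grepl("EOG", labels, ignore.case = TRUE), "EOG", "EEG"))
  new_recording(X, fs, labels, modality)
}
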