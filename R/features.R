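#' Sample entropy
#'
#' Negative log ratio of the number of (v+1)-length to v-length template
#' matches at Chebyshev tolerance `eta`, self-matches excluded
#' (Richman-Moorman convention). Low values indicate regular, self-similar
#' signals. Defaults follow the mental-state feature settings: template
#' length `v = 2` and tolerance `0.2 * sd(x)`.
#'
#' @param x numeric series, length greater than `v + 1`.
#' @param v template length (default 2).
#' @param eta absolute match tolerance; `NULL` (default) uses `0.2 * sd(x)`.
#' @return nonnegative scalar; `+Inf` with attribute `saturated = TRUE` when
#'   no (v+1)-length matches exist.
#' @export
sample_entropy <- function(x, v = 2L, eta = NULL) {
  x <- as.numeric(x)
  if (length(x) <= v + 1L) stop("invalid input: series length must exceed v + 1")
  if (is.null(eta)) {
    s <- sd(x)
    if (s == 0) stop("degenerate input: zero standard deviation with relative tolerance")
    eta <- 0.2 * s
  }
  cnt <- cpp_sampen_counts(x, as.integer(v), eta)
  if (cnt[1] == 0) stop("degenerate input: no template matches at length v")
  if (cnt[2] == 0) return(structure(Inf, saturated = TRUE))
  -log(cnt[2] / cnt[1])
}

#' Differential entropy of a series under a Gaussian model
#'
#' For a series with empirical variance `s2` (mean of squared mean-removed
#' samples) returns `0.5 * log(2 * pi * e * s2)`, the differential entropy
#' of the fitted Gaussian. Shift-invariant; scaling by `c` adds `log(c)`.
#'
#' @param x numeric series, length at least 2.
#' @param s2 optional precomputed variance (skips the empirical estimate).
#' @return scalar differential entropy in nats.
#' @export
differential_entropy <- function(x, s2 = NULL) {
  if (is.null(s2)) {
    if (length(x) < 2L) stop("invalid input: series length must be >= 2")
    s2 <- mean((x - mean(x))^2)
  }
  if (s2 <= 0) stop("degenerate input: zero variance")
  0.5 * log(2 * pi * exp(1) * s2)
}

#' Band power and band energy
#'
#' Time-domain summaries of a rhythm-band series: band power is the mean of
#' squared samples and band energy the sum of squared samples, so
#' `band_energy(x) == band_power(x) * length(x)` identically.
#'
#' @param x numeric series, nonempty.
#' @return nonnegative scalar.
#' @export
band_power <- function(x) {
  if (length(x) < 1L) stop("invalid input: empty series")
  mean(x^2)
}

#' @rdname band_power
#' @export
band_energy <- function(x) {
  if (length(x) < 1L) stop("invalid input: empty series")
  sum(x^2)
}

# Equal-frequency discretization into `bins` levels via ranks.
discretize_ef <- function(x, bins = 8L) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / length(x)))
}

#' Plug-in mutual information between a feature and a discrete label
#'
#' Empirical mutual information (natural log, nats) of the joint
#' distribution of a discretized feature and a discrete label. Continuous
#' features are binned into `bins` equal-frequency levels; already-discrete
#' inputs can be passed with `discretize = FALSE`.
#'
#' @param xf numeric feature series (or discrete codes).
#' @param yl discrete labels, same length as `xf`.
#' @param bins number of equal-frequency bins (default 8).
#' @param discretize bin `xf` before estimation (default `TRUE`).
#' @return nonnegative scalar MI in nats.
#' @examples
#' mutual_information(rnorm(1000), sample(0:1, 1000, TRUE))  # near zero
#' @export
mutual_information <- function(xf, yl, bins = 8L, discretize = TRUE) {
  if (length(xf) != length(yl)) stop("invalid input: length mismatch")
  if (length(xf) < 2L) stop("invalid input: need at least 2 observations")
  xd <- if (discretize) discretize_ef(xf, bins) else xf
  tab <- table(xd, yl)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  idx <- p > 0
  mi <- sum(p[idx] * log(p[idx] / outer(px, py)[idx]))
  max(mi, 0)
}

# Welch power spectral density: Hann segments, 50% overlap.
welch_psd <- function(x, fs, seg_sec = 1, overlap = 0.5) {
  n <- length(x)
  nseg <- min(round(seg_sec * fs), n)
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  norm <- fs * sum(w^2)
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    P <- abs(fft(seg))^2 / norm
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nseg)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nseg, psd = psd * dbl)
}

#' EOG low/high-frequency power ratio
#'
#' Ratio of integrated power spectral density over the low band (0-1.5 Hz)
#' to that over the high band (1.5-30 Hz), estimated by Welch's method with
#' 1 s Hann segments at 50% overlap. The ratio rises when arousal is low
#' (slow eye movements dominate).
#'
#' @param x single-channel EOG window (nominally at 128 Hz).
#' @param fs sampling rate in Hz (default 128).
#' @param low,high integration bands in Hz.
#' @param floor_eps denominator floor; below it the ratio is capped and
#'   flagged with attribute `saturated = TRUE`.
#' @return nonnegative scalar power ratio.
#' @export
eog_power_ratio <- function(x, fs = 128, low = c(0, 1.5), high = c(1.5, 30),
                            floor_eps = 1e-12) {
  if (length(x) < fs) stop("invalid input: window must be at least 1 s long")
  W <- welch_psd(x, fs)
  pl <- sum(W$psd[W$freq >= low[1] & W$freq <= low[2]])
  ph <- sum(W$psd[W$freq > high[1] & W$freq <= high[2]])
  if (ph < floor_eps) return(structure(pl / floor_eps, saturated = TRUE))
  pl / ph
}

eeg_feature_fun <- function(kind, se_v = 2L, se_eta = 0.2) {
  switch(kind,
         DE = function(x) differential_entropy(x),
         SE = function(x) sample_entropy(x, se_v, se_eta * sd(x)),
         BP = band_power,
         BE = band_energy,
         stop("unknown EEG feature kind: ", kind))
}

#' Assemble the 152-dimensional mental-state vector
#'
#' Combines the per-band EEG feature (default differential entropy) of all
#' 30 EEG channels with the two EOG power ratios into the fixed-order
#' feature vector: channels in montage order, bands in
#' delta/theta/alpha/beta/gamma order within each channel, then the two EOG
#' values last (150 EEG + 2 EOG = 152 dimensions).
#'
#' @param rhythms named list: one entry per EEG channel (montage order),
#'   each a named list of the five band series as returned by
#'   [wavelet_rhythms()].
#' @param eog list of two single-channel EOG windows (at `fs_eog`).
#' @param kind EEG feature kind: `"DE"` (default), `"SE"`, `"BP"` or `"BE"`.
#' @param fs_eog EOG sampling rate for the power ratio (default 128).
#' @return named numeric vector of length 152 with attribute
#'   `normalized = FALSE`.
#' @export
assemble_features <- function(rhythms, eog, kind = "DE", fs_eog = 128) {
  bands <- rhythm_band_names()
  if (length(eog) != 2L) stop("schema error: expected 2 EOG windows, got ", length(eog))
  fn <- eeg_feature_fun(kind)
  chans <- names(rhythms)
  if (is.null(chans)) chans <- paste0("ch", seq_along(rhythms))
  vals <- numeric(0)
  for (i in seq_along(rhythms)) {
    rb <- rhythms[[i]]
    for (b in bands) {
      if (is.null(rb[[b]]))
        stop(sprintf("schema error: channel %s is missing band %s", chans[i], b))
      v <- fn(rb[[b]])
      names(v) <- paste(chans[i], b, sep = ".")
      vals <- c(vals, v)
    }
  }
  pr <- vapply(seq_along(eog), function(j) {
    as.numeric(eog_power_ratio(eog[[j]], fs = fs_eog))
  }, 0)
  names(pr) <- paste0("EOG", seq_along(eog), ".PR")
  out <- c(vals, pr)
  attr(out, "normalized") <- FALSE
  out
}

#' Batch feature extraction from preprocessed window batches
#'
#' Computes the per-window feature matrix (`n_windows x 152` under the
#' default montage) from the `eeg`/`eog` window batches returned by
#' [preprocess_recording()], using the same ordering contract as
#' [assemble_features()]: channel-major, band-minor, EOG power ratios
#' last. This is the vectorized path the closed-loop simulator uses.
#'
#' @param prep list with `eeg` and `eog` `psa_windows` batches.
#' @param kind EEG feature kind (`"DE"` default, `"SE"`, `"BP"`, `"BE"`).
#' @param config a [psa_config()] list.
#' @return numeric feature matrix, one row per window.
#' @export
features_from_windows <- function(prep, kind = "DE", config = psa_config()) {
  eegw <- prep$eeg$windows
  d <- dim(eegw)                       # [win_len, n_windows, n_channels]
  nw <- d[2]; nch <- d[3]; wl <- d[1]
  X <- matrix(eegw, nrow = wl)         # column blocks: windows of channel 1, 2, ...
  bn <- rhythm_band_names()
  chans <- prep$eeg$channel_labels
  out <- matrix(0, nrow = nw, ncol = nch * 5)
  cn <- character(nch * 5)
  levels <- config$features$wavelet_levels
  fast <- kind %in% c("DE", "BP", "BE") && wl %% 2^levels == 0
  if (fast) {
    # Parseval route: band second moments straight from the analysis DWT
    f <- db5_filters()
    M <- cpp_dwt_band_moments(X, f$lo, f$hi, levels)
    ss <- rbind(delta = M[levels + 1, ],
                theta = M[levels, ], alpha = M[levels - 1, ],
                beta = M[levels - 2, ],
                gamma = M[levels - 3, ] + M[levels - 4, ])
    mu <- M[levels + 2, ]              # window mean (lives in the delta band)
    band_vals_fast <- function(b, cols) {
      s <- ss[b, cols]
      switch(kind,
        DE = {
          s2 <- s / wl - if (b == "delta") mu[cols]^2 else 0
          0.5 * log(2 * pi * exp(1) * pmax(s2, 1e-300))
        },
        BP = s / wl,
        BE = s)
    }
  } else {
    bands <- wavelet_rhythms_mat(X, levels)
    band_vals <- function(B) {
      switch(kind,
        DE = {
          s2 <- pmax(colMeans(B^2) - colMeans(B)^2, 1e-300)
          0.5 * log(2 * pi * exp(1) * s2)
        },
        BP = colMeans(B^2),
        BE = colSums(B^2),
        SE = apply(B, 2, function(col) {
          v <- sample_entropy(col)
          if (is.infinite(v)) 10 else as.numeric(v)  # saturation sentinel
        }),
        stop("unknown EEG feature kind: ", kind))
    }
  }
  for (ci in seq_len(nch)) {
    cols <- ((ci - 1) * nw + 1):(ci * nw)
    for (bi in seq_along(bn)) {
      idx <- (ci - 1L) * 5L + bi
      out[, idx] <- if (fast) band_vals_fast(bn[bi], cols)
                    else band_vals(bands[[bn[bi]]][, cols, drop = FALSE])
      cn[idx] <- paste(chans[ci], bn[bi], sep = ".")
    }
  }
  colnames(out) <- cn
  eogw <- prep$eog$windows
  fs_eog <- prep$eog$source_fs
  pr <- vapply(seq_len(dim(eogw)[3]), function(ch)
    apply(eogw[, , ch, drop = FALSE], 2, function(w)
      as.numeric(eog_power_ratio(as.numeric(w), fs = fs_eog))), numeric(nw))
  colnames(pr) <- paste0("EOG", seq_len(ncol(pr)), ".PR")
  cbind(out, pr)
}

#' Rank candidate EEG features by mutual information with labels
#'
#' Computes the plug-in mutual information between every feature column of
#' each candidate feature kind and a discrete label vector, and summarises
#' the mean MI per kind. Used to select the per-band EEG feature carried in
#' the state vector (differential entropy by default).
#'
#' @param feature_tables named list of numeric matrices (one per feature
#'   kind, e.g. `DE`, `SE`, `BP`, `BE`), each `n_obs x n_features` with
#'   `channel.band` column names.
#' @param labels discrete label vector of length `n_obs` (at least 2 classes).
#' @param bins equal-frequency bins for discretization (default 8).
#' @return a `data.frame` with columns `kind`, `feature`, `mi`, plus a
#'   `summary` attribute (named mean MI per kind) and `best_kind`.
#' @export
rank_features <- function(feature_tables, labels, bins = 8L) {
  if (length(unique(labels)) < 2L)
    stop("degenerate labels: need at least 2 classes")
  rows <- do.call(rbind, lapply(names(feature_tables), function(kind) {
    M <- feature_tables[[kind]]
    if (nrow(M) != length(labels)) stop("invalid input: row/label mismatch for ", kind)
    mi <- apply(M, 2, mutual_information, yl = labels, bins = bins)
    data.frame(kind = kind,
               feature = colnames(M) %||% paste0("f", seq_len(ncol(M))),
               mi = as.numeric(mi), row.names = NULL)
  }))
  summ <- tapply(rows$mi, rows$kind, mean)
  attr(rows, "summary") <- summ
  attr(rows, "best_kind") <- names(summ)[which.max(summ)]
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Running min-max feature normalizer
#'
#' Accumulates per-dimension minima and maxima over training batches and
#' maps features into `[0, 1]` (clipped once the statistics are frozen for
#' testing/control sessions).
#'
#' @param dim feature dimensionality.
#' @return a normalizer state list.
#' @export
make_normalizer <- function(dim = 152L) {
  list(min = rep(Inf, dim), max = rep(-Inf, dim), frozen = FALSE)
}

#' @rdname make_normalizer
#' @param norm a normalizer state.
#' @param X feature matrix (rows = observations) or vector.
#' @export
update_normalizer <- function(norm, X) {
  if (norm$frozen) return(norm)
  X <- rbind(X)
  norm$min <- pmin(norm$min, apply(X, 2, min))
  norm$max <- pmax(norm$max, apply(X, 2, max))
  norm
}

#' @rdname make_normalizer
#' @export
apply_normalizer <- function(norm, X) {
  vec <- is.null(dim(X))
  X <- rbind(X)
  rng <- pmax(norm$max - norm$min, 1e-12)
  Y <- sweep(sweep(X, 2, norm$min), 2, rng, "/")
  Y <- pmin(pmax(Y, 0), 1)
  if (vec) as.numeric(Y) else Y
}
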