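# Shared fixtures, all generated in code.

sine_wave <- function(freq, fs, n, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / fs + phase)
}

# Tiny two-channel recording for I/O round-trips.
tiny_recording <- function(n = 200, fs = 100) {
  set.seed(99)
  new_recording(cbind(rnorm(n), sine_wave(5, fs, n)), fs,
                c("Cz", "HEOG"), c("EEG", "EOG"))
}

# Normalizer fixed to the identity on [0, 1].
unit_normalizer <- function(dim = 152L) {
  norm <- make_normalizer(dim)
  norm$min <- rep(0, dim); norm$max <- rep(1, dim); norm$frozen <- TRUE
  norm
}

# Independent O(n^2) sample-entropy oracle: explicit double loop, written
# without reference to the package implementation.
sampen_oracle <- function(x, m = 2L, r = 0.2 * sd(x)) {
  n <- length(x)
  nt <- n - m
  b_m <- 0L; b_m1 <- 0L
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (j <= i) next
      ok_m <- TRUE
      for (k in 0:(m - 1)) {
        if (abs(x[i + k] - x[j + k]) > r) { ok_m <- FALSE; break }
      }
      if (!ok_m) next
      b_m <- b_m + 1L
      if (abs(x[i + m] - x[j + m]) <= r) b_m1 <- b_m1 + 1L
    }
  }
  if (b_m == 0L) return(NA_real_)
  if (b_m1 == 0L) return(Inf)
  -log(b_m1 / b_m)
}

# Plug-in MI oracle by direct summation over a contingency table of counts.
mi_oracle_table <- function(counts) {
  p <- counts / sum(counts)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  s
}

# Small policy + state for gradient checks.
small_policy <- function(seed = 1, sizes = c(6L, 5L, 4L)) {
  init_policy(sizes, seed = seed)
}

flatten_grad <- function(g) unlist(g[c("W1", "b1", "W2", "b2")], use.names = FALSE)

# Miniature closed-loop configuration: 10 windows per round, short buffer.
mini_config <- function(...) {
  psa_config(
    preprocess = list(n_windows = 10L),
    task = list(k = 10L, track_length = 10),
    pretrain = list(enabled = FALSE),
    protocol = list(train_rounds = 4L, practice_rounds = 1L,
                    test_rounds = 2L, control_rounds = 2L),
    ...)
}
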