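test_that("sample entropy equals the brute-force template-counting oracle", {
  set.seed(21)
  x <- rnorm(100)
  expect_equal(sample_entropy(x), sampen_oracle(x), tolerance = 1e-12)
  # property: agreement across lengths and signal shapes
  for (i in 1:15) {
    n <- sample(30:200, 1)
    y <- switch(1 + i %% 3,
                rnorm(n),
                cumsum(rnorm(n)),
                sine_wave(4, 64, n) + rnorm(n, sd = 0.3))
    o <- sampen_oracle(y)
    if (is.finite(o)) expect_equal(sample_entropy(y), o, tolerance = 1e-12)
  }
})

test_that("regular series have lower sample entropy than shuffled ones", {
  set.seed(22)
  periodic <- rep(c(1, 2, 3), length.out = 99)
  shuffled <- sample(periodic)
  eta <- 0.2 * sd(periodic)
  expect_lt(sample_entropy(periodic, eta = eta), sample_entropy(shuffled, eta = eta))
  # defaults: v = 2, eta = 0.2 sd
  z <- rnorm(80)
  expect_equal(sample_entropy(z), sample_entropy(z, v = 2, eta = 0.2 * sd(z)))
  expect_error(sample_entropy(rep(1, 50)), "degenerate")
})

test_that("differential entropy matches the Gaussian closed form", {
  set.seed(23)
  x <- rnorm(10000, sd = 2)
  expect_equal(differential_entropy(x), 0.5 * log(2 * pi * exp(1) * 4),
               tolerance = 0.05)
  # scaling law: DE(2x) = DE(x) + log 2
  y <- rnorm(300)
  expect_equal(differential_entropy(2 * y) - differential_entropy(y), log(2),
               tolerance = 1e-12)
  # constructed zero: variance exactly 1/(2 pi e)
  s <- sqrt(1 / (2 * pi * exp(1)))
  expect_equal(differential_entropy(c(-s, s)), 0, tolerance = 1e-12)
  # shift invariance
  expect_equal(differential_entropy(y + 17.3), differential_entropy(y))
  expect_error(differential_entropy(rep(2, 10)), "degenerate")
})

test_that("band power and band energy satisfy their identities", {
  x <- sine_wave(4, 64, 64 * 4)  # integer periods
  expect_equal(band_power(x), 0.5, tolerance = 1e-3)
  expect_equal(band_power(rep(0, 10)), 0)
  expect_equal(band_energy(rep(0, 10)), 0)
  set.seed(24)
  y <- rnorm(137)
  expect_equal(band_energy(y) / band_power(y), length(y))
  expect_error(band_power(numeric(0)), "invalid input")
})

test_that("mutual information matches plug-in summation and its identities", {
  # MI(X;X) = H(X) for discrete codes
  set.seed(25)
  codes <- sample(1:4, 400, replace = TRUE)
  tab <- table(codes)
  H <- -sum((tab / 400) * log(tab / 400))
  expect_equal(mutual_information(codes, codes, discretize = FALSE), H,
               tolerance = 1e-9)

  # independence: near zero for large n
  xf <- rnorm(10000); yl <- sample(0:1, 10000, replace = TRUE)
  expect_lt(mutual_information(xf, yl), 0.01)

  # printed 2x2 table: expand counts to observations, compare to the oracle
  counts <- matrix(c(40, 10, 10, 40), 2, byrow = TRUE)
  xs <- rep(c(1, 1, 2, 2), times = c(40, 10, 10, 40))
  ys <- rep(c(1, 2, 1, 2), times = c(40, 10, 10, 40))
  expect_equal(mutual_information(xs, ys, discretize = FALSE),
               mi_oracle_table(counts), tolerance = 1e-12)

  # symmetry and nonnegativity on discretized inputs
  for (i in 1:10) {
    a <- sample(1:5, 200, replace = TRUE)
    b <- sample(1:3, 200, replace = TRUE)
    m1 <- mutual_information(a, b, discretize = FALSE)
    m2 <- mutual_information(b, a, discretize = FALSE)
    expect_equal(m1, m2, tolerance = 1e-12)
    expect_gte(m1, 0)
  }
  expect_error(mutual_information(1:5, 1:6), "length mismatch")
})

test_that("EOG power ratio separates slow and fast activity", {
  fs <- 128; n <- 256
  fast <- sine_wave(10, fs, n)
  expect_lt(eog_power_ratio(fast, fs), 0.05)

  # analytic power ratio is 1e4; the 1 s Hann Welch estimator leaks part of
  # the 0.5 Hz main lobe above 1.5 Hz, bounding the observable ratio lower
  slow <- sine_wave(0.5, fs, n) + sine_wave(10, fs, n, amp = 0.01)
  expect_gt(eog_power_ratio(slow, fs), 50)

  both <- sine_wave(1, fs, n) + sine_wave(10, fs, n)
  pr <- eog_power_ratio(both, fs)
  expect_gte(pr, 0.5); expect_lte(pr, 2)

  pure_slow <- sine_wave(0.5, fs, n)
  sat <- eog_power_ratio(pure_slow, fs)
  expect_true(is.null(attr(sat, "saturated")) || isTRUE(attr(sat, "saturated")))
})

test_that("feature assembly follows the 152-dimension ordering contract", {
  set.seed(26)
  chans <- psa_montage()[1:30]
  rhythms <- setNames(lapply(1:30, function(i) wavelet_rhythms(rnorm(512))), chans)
  eog <- list(rnorm(256), rnorm(256))
  v <- assemble_features(rhythms, eog)
  expect_length(v, 152)
  expect_equal(sum(!grepl("^EOG", names(v))), 150)
  expect_equal(names(v)[1:5], paste("Fp1", rhythm_band_names(), sep = "."))
  expect_equal(names(v)[151:152], c("EOG1.PR", "EOG2.PR"))
  # determinism
  expect_identical(v, assemble_features(rhythms, eog))
  # schema error names the offender
  broken <- rhythms
  broken[["Cz"]]$alpha <- NULL
  expect_error(assemble_features(broken, eog), "Cz.*alpha")
})

test_that("batch extraction agrees with per-window assembly", {
  set.seed(27)
  rec <- emit_signals(latent_state(), operator_profile(), duration = 14)
  cfg <- psa_config(preprocess = list(n_windows = 5L))
  prep <- preprocess_recording(rec, cfg)
  Fm <- features_from_windows(prep, "DE", cfg)
  expect_equal(dim(Fm), c(5, 152))
  w3 <- setNames(lapply(1:30, function(ch) wavelet_rhythms(prep$eeg$windows[, 3, ch])),
                 prep$eeg$channel_labels)
  v3 <- assemble_features(w3, list(prep$eog$windows[, 3, 1], prep$eog$windows[, 3, 2]))
  expect_equal(as.numeric(Fm[3, ]), as.numeric(v3), tolerance = 1e-10)
  # BP/BE identities hold on the batch path too
  Fbp <- features_from_windows(prep, "BP", cfg)
  Fbe <- features_from_windows(prep, "BE", cfg)
  expect_equal(Fbe[, 1:150] / Fbp[, 1:150],
               matrix(512, 5, 150), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("feature ranking finds the informative feature kind", {
  set.seed(28)
  n <- 600
  labels <- sample(0:1, n, replace = TRUE)
  informative <- function() labels + rnorm(n, sd = 0.35)
  noise <- function() rnorm(n)
  tables <- list(
    DE = cbind(a = informative(), b = informative(), c = informative()),
    BP = cbind(a = noise(), b = noise(), c = noise()),
    BE = cbind(a = noise(), b = noise(), c = noise()))
  rk <- rank_features(tables, labels)
  summ <- attr(rk, "summary")
  expect_gt(summ["DE"], summ["BP"])
  expect_gt(summ["DE"], summ["BE"])
  expect_equal(attr(rk, "best_kind"), "DE")
  expect_true(all(rk$mi >= 0))

  # labels independent of everything: all mean MI small
  rnd <- sample(0:1, 5000, replace = TRUE)
  tab0 <- list(DE = matrix(rnorm(5000 * 2), ncol = 2))
  expect_lt(mean(rank_features(tab0, rnd)$mi), 0.02)

  expect_error(rank_features(tables, rep(1, n)), "degenerate labels")
})

test_that("running min-max normalization clips once frozen", {
  norm <- make_normalizer(3)
  norm <- update_normalizer(norm, rbind(c(0, 10, -1), c(1, 20, 1)))
  out <- apply_normalizer(norm, c(0.5, 15, 0))
  expect_equal(out, c(0.5, 0.5, 0.5))
  norm$frozen <- TRUE
  norm2 <- update_normalizer(norm, rbind(c(-5, 0, 0)))  # ignored when frozen
  expect_identical(norm2$min, norm$min)
  expect_equal(apply_normalizer(norm, c(9, 100, -7)), c(1, 1, 0))
})
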