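# Filtering, resampling, epoching and rhythm decomposition.

test_that("notch filter removes the powerline tone and spares nearby bands", {
  fs <- 500
  t <- seq_len(30 * fs) / fs           # one scoring epoch
  zero <- matrix(0, 2, length(t))
  expect_equal(notch_filter(zero, fs = fs), zero)

  tone50 <- matrix(sin(2 * pi * 50 * t), 1)
  out50 <- notch_filter(tone50, fs = fs)
  expect_lt(rms(out50) / rms(tone50), 0.05)

  tone10 <- matrix(sin(2 * pi * 10 * t), 1)
  out10 <- notch_filter(tone10, fs = fs)
  expect_lt(abs(rms(out10) / rms(tone10) - 1), 0.02)

  expect_error(notch_filter(tone10, fs = 100, f0 = 50), "Nyquist")
})

test_that("band-pass filter passes in-band and rejects out-of-band tones", {
  fs <- 100
  t <- seq_len(30 * fs) / fs
  zero <- matrix(0, 3, length(t))
  expect_equal(bandpass_filter(zero, 8, 13, fs), zero)

  tone2 <- matrix(sin(2 * pi * 2 * t), 1)
  expect_lt(rms(bandpass_filter(tone2, 8, 13, fs)) / rms(tone2), 0.05)

  tone10 <- matrix(sin(2 * pi * 10 * t), 1)
  expect_lt(abs(rms(bandpass_filter(tone10, 8, 13, fs)) / rms(tone10) - 1),
            0.05)

  expect_error(bandpass_filter(tone10, 13, 8, fs), "band edges")
  expect_error(bandpass_filter(tone10, 1, 60, fs), "band edges")
})

test_that("filters are zero-phase: a symmetric pulse stays symmetric", {
  fs <- 100
  n <- 1001
  x <- matrix(exp(-((seq_len(n) - 501) / 20)^2), 1)   # symmetric Gaussian
  for (y in list(bandpass_filter(x, 1, 30, fs),
                 notch_filter(x, fs = fs, f0 = 25))) {
    expect_equal(which.max(y), 501)
    expect_equal(y[1, 501 + 1:100], y[1, 501 - 1:100], tolerance = 1e-6)
  }
})

test_that("downsampling keeps counts, DC, and in-band amplitude", {
  fs_in <- 500; fs_out <- 100
  x <- matrix(rnorm(2 * 30 * fs_in), 2)
  y <- downsample(x, fs_in, fs_out)
  expect_equal(ncol(y), 3000)

  dc <- matrix(2.5, 1, 30 * fs_in)
  ydc <- downsample(dc, fs_in, fs_out)
  expect_equal(max(abs(ydc - 2.5)) / 2.5, 0, tolerance = 1e-6)

  t <- seq_len(30 * fs_in) / fs_in
  tone40 <- matrix(sin(2 * pi * 40 * t), 1)
  y40 <- downsample(tone40, fs_in, fs_out)
  amp <- fft_amplitude(drop(y40), 40, fs_out)
  expect_lt(abs(amp - 1), 0.1)

  expect_error(downsample(x, 100, 500), "exceed")
})

test_that("filtering and downsampling commute with channel permutation", {
  set.seed(42)
  fs <- 500
  x <- matrix(rnorm(4 * fs * 10), 4)
  perm <- c(3, 1, 4, 2)
  expect_equal(bandpass_filter(x, 1, 30, fs)[perm, ],
               bandpass_filter(x[perm, ], 1, 30, fs))
  expect_equal(downsample(x, 500, 100)[perm, ],
               downsample(x[perm, ], 500, 100))
})

test_that("epoch splitting windows, drops remainders and flags exclusions", {
  fs <- 100
  rec <- eeg_recording(matrix(rnorm(8 * 300 * fs), 8), fs,
                       annotations = rep(c("W", "QS"), 5))
  eps <- epoch_split(rec)
  expect_length(eps, 10)
  expect_equal(dim(eps[[1]]$data), c(8, 3000))
  expect_equal(vapply(eps, function(e) e$epoch_index, 0L), 0:9)
  expect_equal(vapply(eps, function(e) e$label, ""), rep(c("W", "QS"), 5))

  rec305 <- eeg_recording(matrix(rnorm(8 * 305 * fs), 8), fs)
  eps305 <- epoch_split(rec305)
  expect_length(eps305, 10)
  # sample conservation: epochs + dropped remainder = total
  expect_equal(sum(vapply(eps305, function(e) ncol(e$data), 0)) + 5 * fs,
               ncol(rec305$data))

  rec3 <- eeg_recording(matrix(rnorm(8 * 90 * fs), 8), fs,
                        annotations = c("W", "QS", "AS"))
  eps3 <- epoch_split(rec3, exclude = 1L)
  kept <- Filter(function(e) !e$excluded, eps3)
  expect_equal(vapply(kept, function(e) e$epoch_index, 0L), c(0L, 2L))

  short <- eeg_recording(matrix(0, 8, 10 * fs), fs)
  expect_warning(out <- epoch_split(short), "shorter")
  expect_length(out, 0)
})

test_that("unannotated epochs come back UNSCORED and excluded", {
  fs <- 100
  rec <- eeg_recording(matrix(rnorm(8 * 60 * fs), 8), fs,
                       annotations = "AS")
  eps <- epoch_split(rec)
  expect_equal(eps[[2]]$label, "UNSCORED")
  expect_true(eps[[2]]$excluded)
  expect_false(eps[[1]]$excluded)
})

test_that("rhythm extraction separates the canonical bands in fixed order", {
  fs <- 100
  zero <- matrix(0, 8, 30 * fs)
  bs0 <- extract_rhythms(zero, fs)
  expect_equal(names(bs0), c("broadband", "delta", "theta", "alpha", "beta"))
  for (b in bs0) expect_equal(b, zero)

  t <- seq_len(30 * fs) / fs
  x6 <- matrix(rep(sin(2 * pi * 6 * t), each = 8), 8, byrow = FALSE)
  bs <- extract_rhythms(x6, fs)
  expect_gte(rms(bs$theta), 10 * rms(bs$alpha))
  for (b in bs) expect_equal(dim(b), dim(x6))

  expect_error(extract_rhythms(x6, fs = 50, bands = c("delta", "beta")),
               "beta")
})

test_that("preprocessing pipeline lands at the working rate with labels intact", {
  fs <- 500
  ann <- c("W", "AS")
  rec <- eeg_recording(matrix(rnorm(8 * 60 * fs), 8), fs, annotations = ann)
  pre <- preprocess_recording(rec)
  expect_equal(pre$fs, 100)
  expect_equal(ncol(pre$data), 6000)
  expect_equal(pre$annotations, ann)
})
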