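# Zero-phase filtering, resampling and epoching of multi-channel EEG.
# All filters operate row-wise (one row = one channel) and are applied to the
# full recording before epoching, so no per-epoch transients are introduced.

.check_signal_matrix <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x))
    stop("signal must be a numeric channels x samples matrix")
  x
}

# Forward-backward filtering with odd-reflection edge padding (continuous in
# value and slope at the ends), so filter start-up transients do not leak
# into the signal. pad is in samples, capped at the signal length - 1.
.zero_phase <- function(b, a, ch, pad) {
  n <- length(ch)
  p <- max(0L, min(as.integer(pad), n - 1L))
  ext <- if (p > 0)
    c(2 * ch[1] - ch[(p + 1):2], ch, 2 * ch[n] - ch[(n - 1):(n - p)])
  else ch
  y <- signal::filtfilt(b, a, ext)
  y[(p + 1):(p + n)]
}

#' Zero-phase powerline notch filter
#'
#' Removes a narrow band around the powerline frequency with a second-order
#' IIR notch (biquad, quality factor \code{q}) applied forward and backward,
#' so the net filter has zero phase.
#'
#' @param x Numeric matrix, channels x samples (a vector is treated as one
#'   channel).
#' @param fs Sampling rate in Hz.
#' @param f0 Notch center frequency in Hz (default 50, European powerline).
#' @param q Quality factor; the -3 dB notch width is \code{f0/q} Hz.
#' @return Filtered matrix of the same shape.
#' @export
notch_filter <- function(x, fs, f0 = 50, q = 30) {
  x <- .check_signal_matrix(x)
  if (f0 >= fs / 2)
    stop("notch frequency f0 = ", f0, " Hz is at or above Nyquist (fs/2 = ",
         fs / 2, " Hz)")
  # RBJ audio-cookbook notch biquad
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1]
  a <- a / a[1]
  pad <- round(3 * fs * q / (pi * f0))    # ~3 ring-down time constants
  t(apply(x, 1L, function(ch) .zero_phase(b, a, ch, pad)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-\code{order} Butterworth band-pass forward and backward
#' (zero phase; the effective magnitude order is doubled).
#'
#' @inheritParams notch_filter
#' @param lo,hi Band edges in Hz, \code{0 < lo < hi < fs/2}.
#' @param order One-pass Butterworth design order (default 5).
#' @return Filtered matrix of the same shape.
#' @export
bandpass_filter <- function(x, lo, hi, fs, order = 5) {
  x <- .check_signal_matrix(x)
  if (!(lo > 0 && hi > lo && hi < fs / 2))
    stop("invalid band edges: need 0 < lo < hi < fs/2, got [", lo, ", ", hi,
         "] Hz at fs = ", fs, " Hz")
  bt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  pad <- round(3 * fs / lo)               # slowest edge sets the transient
  t(apply(x, 1L, function(ch) .zero_phase(bt$b, bt$a, ch, pad)))
}

#' Anti-aliased down-sampling
#'
#' Resamples each channel in the frequency domain: the spectrum is truncated
#' at the new Nyquist frequency and inverted at the new length. Content below
#' the new Nyquist (including DC) is preserved essentially exactly; content
#' above it is removed rather than aliased.
#'
#' @inheritParams notch_filter
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return Matrix with \code{round(ncol(x) * fs_out / fs_in)} samples per
#'   channel.
#' @export
downsample <- function(x, fs_in, fs_out) {
  x <- .check_signal_matrix(x)
  if (fs_out > fs_in) stop("fs_out must not exceed fs_in")
  if (fs_out == fs_in) return(x)
  n_in <- ncol(x)
  n_out <- round(n_in * fs_out / fs_in)
  t(apply(x, 1L, function(ch) .fft_resample(ch, n_out)))
}

# Spectrum-truncation resampling of one real signal to length n_out < n.
.fft_resample <- function(ch, n_out) {
  n <- length(ch)
  X <- stats::fft(ch)
  Y <- complex(n_out)
  half <- floor(n_out / 2)
  Y[1L] <- X[1L]
  if (half >= 1) {
    Y[2L:(half + 1L)] <- X[2L:(half + 1L)]
    if (n_out %% 2L == 0L) {
      # shared Nyquist bin: keep it real to preserve a real signal
      Y[half + 1L] <- Re(X[half + 1L])
    }
    if (half > 1 || n_out %% 2L == 1L) {
      k <- seq_len(n_out - half - 1L)
      Y[n_out - k + 1L] <- Conj(Y[k + 1L])
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Split a recording into fixed-length scoring epochs
#'
#' Cuts the recording into consecutive non-overlapping windows of
#' \code{epoch_s} seconds (the sleep-scoring unit; default 30 s), dropping
#' any trailing partial window. Epoch \code{i} (0-based) carries annotation
#' \code{i} when available, else \code{"UNSCORED"}. Epochs that are
#' unscored, listed in \code{exclude}, or (optionally) fail the amplitude
#' criterion are flagged \code{excluded}.
#'
#' @param rec An \code{eeg_recording}.
#' @param epoch_s Epoch length in seconds.
#' @param exclude Integer vector of 0-based epoch indices to exclude
#'   (e.g. from a visual-artifact list).
#' @param artifact_reject If \code{TRUE}, additionally exclude epochs with
#'   any |sample| > \code{amp_limit} or any flat (zero-variance) channel.
#' @param amp_limit Amplitude rejection threshold in microvolts.
#' @return List of epochs; each has elements \code{data} (channels x
#'   samples), \code{label}, \code{subject_id}, \code{epoch_index} (0-based)
#'   and \code{excluded}.
#' @export
epoch_split <- function(rec, epoch_s = 30, exclude = integer(),
                        artifact_reject = FALSE, amp_limit = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- round(epoch_s * rec$fs)           # samples per epoch
  n_ep <- ncol(rec$data) %/% spe
  if (n_ep < 1L) {
    warning("recording shorter than one epoch; returning empty list")
    return(list())
  }
  lapply(seq_len(n_ep), function(i) {
    idx <- ((i - 1L) * spe + 1L):(i * spe)
    lab <- if (i <= length(rec$annotations)) rec$annotations[i] else "UNSCORED"
    dat <- rec$data[, idx, drop = FALSE]
    excl <- lab == "UNSCORED" || (i - 1L) %in% exclude
    if (!excl && artifact_reject) {
      flat <- apply(dat, 1L, function(ch) max(ch) == min(ch))
      excl <- any(abs(dat) > amp_limit) || any(flat)
    }
    structure(list(data = dat, label = lab, subject_id = rec$subject_id,
                   epoch_index = i - 1L, excluded = excl),
              class = "eeg_epoch")
  })
}

#' Decompose an epoch into rhythm bands
#'
#' Returns the broadband signal (the preprocessed epoch itself, nominally
#' 0.3-35 Hz) together with the four canonical rhythm bands, each obtained
#' with a zero-phase fifth-order Butterworth band-pass: delta 1-4 Hz,
#' theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz. Band order is fixed:
#' broadband, delta, theta, alpha, beta.
#'
#' @param x Channels x samples matrix (one epoch), or an \code{eeg_epoch}.
#' @param fs Sampling rate in Hz.
#' @param bands Character vector of band names to compute (subset of
#'   \code{names(MVBN_BANDS)}); defaults to all five.
#' @return Named list of matrices, one per band, in canonical order; class
#'   \code{"band_set"}.
#' @export
extract_rhythms <- function(x, fs, bands = names(MVBN_BANDS)) {
  if (inherits(x, "eeg_epoch")) x <- x$data
  x <- .check_signal_matrix(x)
  bands <- intersect(names(MVBN_BANDS), bands)   # canonical order
  if (length(bands) == 0L) stop("no valid band names given")
  out <- lapply(bands, function(b) {
    rng <- MVBN_BANDS[[b]]
    if (fs < 2 * rng[2])
      stop("sampling rate ", fs, " Hz too low for band '", b, "' (needs >= ",
           2 * rng[2], " Hz)")
    if (b == "broadband") x else bandpass_filter(x, rng[1], rng[2], fs)
  })
  names(out) <- bands
  structure(out, class = "band_set", fs = fs)
}

#' Standard preprocessing of a raw recording
#'
#' Applies, in order: powerline notch (skipped with a message when the notch
#' center is at or above the working Nyquist frequency, as for recordings
#' already at 100 Hz), 0.3-35 Hz zero-phase Butterworth band-pass, and
#' down-sampling to \code{fs_out}. Annotations are carried through
#' unchanged.
#'
#' @param rec An \code{eeg_recording}.
#' @param band Band-pass edges in Hz.
#' @param notch Notch center in Hz (\code{NULL} to disable).
#' @param fs_out Target sampling rate in Hz.
#' @param order Butterworth design order.
#' @return The preprocessed \code{eeg_recording} at \code{fs_out}.
#' @export
preprocess_recording <- function(rec, band = c(0.3, 35), notch = 50,
                                 fs_out = 100, order = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  if (!is.null(notch)) {
    if (notch < 0.95 * rec$fs / 2) {
      x <- notch_filter(x, fs = rec$fs, f0 = notch)
    } else {
      message("notch at ", notch, " Hz skipped: at/above Nyquist for fs = ",
              rec$fs, " Hz")
    }
  }
  x <- bandpass_filter(x, band[1], band[2], fs = rec$fs, order = order)
  if (fs_out < rec$fs) x <- downsample(x, rec$fs, fs_out)
  rec$data <- x
  rec$fs <- fs_out
  rec
}

#' Construct an EEG recording object
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Channel names, one per row of \code{data}.
#' @param subject_id Subject identifier.
#' @param annotations Character vector of per-epoch stage labels
#'   (\code{W}, \code{AS}, \code{QS} or \code{UNSCORED}).
#' @return An object of class \code{"eeg_recording"}.
#' @export
eeg_recording <- function(data, fs, channel_labels = MVBN_CHANNELS,
                          subject_id = "s1", annotations = character()) {
  data <- .check_signal_matrix(data)
  stopifnot(nrow(data) == length(channel_labels), fs > 0)
  bad <- setdiff(annotations, c(MVBN_STAGES, "UNSCORED"))
  if (length(bad))
    stop("unknown stage label(s): ", paste(unique(bad), collapse = ", "))
  structure(list(subject_id = as.character(subject_id),
                 channel_labels = channel_labels,
                 fs = fs, data = data,
                 annotations = as.character(annotations)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording '", x$subject_id, "': ", nrow(x$data), " channels x ",
      ncol(x$data), " samples @ ", x$fs, " Hz (",
      round(ncol(x$data) / x$fs / 60, 1), " min), ",
      length(x$annotations), " annotated epochs\n", sep = "")
  invisible(x)
}
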