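# Seeded synthetic neonatal-like EEG whose stage label is encoded in the
# cross-channel coupling structure. Each class couples specific channel
# pairs through a shared narrowband oscillator mixed into both channels of
# the pair; every channel additionally receives independent 1/f-like (pink)
# noise. These are controlled test signals, not a model of real neonatal
# EEG morphology (no trace alternant, no delta brushes).

#' Specify a synthetic EEG dataset
#'
#' Defaults define the package's standard study conditions: 6 subjects, 60
#' epochs per class per subject, coupling strength 0.9, pink-noise amplitude
#' 0.3 (relative to the unit-RMS oscillator), 100 Hz sampling, 30-s epochs.
#' The three class templates are test fixtures, not physiological claims:
#' \itemize{
#'   \item \code{QS}: delta (2 Hz) oscillators shared within (F3,F4) and
#'     (C3,C4);
#'   \item \code{AS}: theta (6 Hz) oscillators shared within (T3,T4) and
#'     (P3,P4);
#'   \item \code{W}: no coupled pairs; extra independent beta-band noise on
#'     every channel.
#' }
#' Each subject carries deterministic jitter (oscillator frequency +-10%,
#' amplitude +-20%) so that leave-one-subject-out evaluation is non-trivial.
#'
#' @param n_subjects Number of subjects.
#' @param epochs_per_class Epochs per class per subject.
#' @param coupling Oscillator mixing weight a in [0, 1].
#' @param noise Pink-noise amplitude relative to the unit-RMS oscillator.
#' @param fs Sampling rate in Hz.
#' @param epoch_s Epoch length in seconds.
#' @param seed Base RNG seed; all generation is deterministic given it.
#' @param amp_uv Overall physical scale in microvolts.
#' @param classes Optional custom class templates: named list (names =
#'   stage labels) of lists with elements \code{pairs} (list of channel-name
#'   pairs), \code{center_hz} (oscillator frequency), and optional
#'   \code{beta_noise} (extra beta-band noise amplitude).
#' @return Object of class \code{"mvbn_synth_spec"}.
#' @export
synth_spec <- function(n_subjects = 6, epochs_per_class = 60, coupling = 0.9,
                       noise = 0.3, fs = 100, epoch_s = 30, seed = 1,
                       amp_uv = 30, classes = NULL) {
  stopifnot(n_subjects >= 1, epochs_per_class >= 1,
            coupling >= 0, coupling <= 1, noise >= 0, fs > 0)
  if (is.null(classes)) {
    classes <- list(
      W  = list(pairs = list(), center_hz = NA_real_, beta_noise = coupling),
      AS = list(pairs = list(c("T3", "T4"), c("P3", "P4")), center_hz = 6),
      QS = list(pairs = list(c("F3", "F4"), c("C3", "C4")), center_hz = 2)
    )
  }
  if (!all(names(classes) %in% MVBN_STAGES))
    stop("class labels must be drawn from ", paste(MVBN_STAGES, collapse = ", "))
  for (cl in classes) {
    chs <- unlist(cl$pairs)
    if (length(chs) && !all(chs %in% MVBN_CHANNELS))
      stop("coupling pair references unknown channel(s): ",
           paste(setdiff(chs, MVBN_CHANNELS), collapse = ", "))
  }
  structure(list(n_subjects = n_subjects, epochs_per_class = epochs_per_class,
                 coupling = coupling, noise = noise, fs = fs,
                 epoch_s = epoch_s, seed = seed, amp_uv = amp_uv,
                 classes = classes),
            class = "mvbn_synth_spec")
}

# Unit-RMS pink noise (power ~ 1/f^0.8) by spectral shaping of white noise.
.pink_noise <- function(n, exponent = 0.8) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  fk <- pmin(k, n - k)                        # folded bin index, symmetric
  shape <- c(0, fk[-1]^(-exponent / 2))       # zero out DC
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(x)
  x / s
}

# Band-limited (13-30 Hz) unit-RMS noise for the wake template.
.beta_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  y <- drop(bandpass_filter(matrix(x, 1), 13, 30, fs))
  s <- sd(y)
  if (s == 0) return(y)
  y / s
}

#' Generate one synthetic subject recording
#'
#' Builds \code{epochs_per_class} epochs for every class template, in
#' class-interleaved order, and attaches the per-epoch stage annotations.
#' For an epoch of class c, every coupled pair shares one narrowband
#' oscillator (sinusoid at the subject-jittered class frequency, fresh
#' random phase per epoch per pair) mixed with weight \code{coupling} into
#' both channels; all channels receive independent pink noise of amplitude
#' \code{noise}. Deterministic given \code{(spec$seed, subject_index)}.
#'
#' @param spec A \code{\link{synth_spec}}.
#' @param subject_index 1-based subject number.
#' @return An \code{eeg_recording} at \code{spec$fs} with annotations.
#' @export
generate_recording <- function(spec, subject_index) {
  stopifnot(inherits(spec, "mvbn_synth_spec"), subject_index >= 1)
  set.seed((spec$seed * 7919L + subject_index * 104729L) %% .Machine$integer.max)
  fs <- spec$fs
  spe <- round(spec$epoch_s * fs)
  C <- length(MVBN_CHANNELS)
  jit_f <- stats::runif(1, 0.9, 1.1)          # per-subject frequency jitter
  jit_a <- stats::runif(1, 0.8, 1.2)          # per-subject amplitude jitter

  class_names <- names(spec$classes)
  n_ep <- spec$epochs_per_class * length(class_names)
  labels <- rep(class_names, spec$epochs_per_class)   # interleaved classes
  data <- matrix(0, C, n_ep * spe)
  tt <- seq_len(spe) / fs
  for (e in seq_len(n_ep)) {
    cl <- spec$classes[[labels[e]]]
    ep <- matrix(0, C, spe)
    for (ch in seq_len(C)) ep[ch, ] <- spec$noise * .pink_noise(spe)
    for (pr in cl$pairs) {
      f0 <- cl$center_hz * jit_f
      phi0 <- stats::runif(1, 0, 2 * pi)
      osc <- sqrt(2) * sin(2 * pi * f0 * tt + phi0)   # unit RMS
      idx <- match(pr, MVBN_CHANNELS)
      ep[idx[1], ] <- ep[idx[1], ] + spec$coupling * osc
      ep[idx[2], ] <- ep[idx[2], ] + spec$coupling * osc
    }
    bn <- cl$beta_noise %||% 0
    if (bn > 0)
      for (ch in seq_len(C)) ep[ch, ] <- ep[ch, ] + bn * .beta_noise(spe, fs)
    data[, ((e - 1) * spe + 1):(e * spe)] <- ep
  }
  eeg_recording(spec$amp_uv * jit_a * data, fs,
                subject_id = sprintf("synth%02d", subject_index),
                annotations = labels)
}

#' Generate a full synthetic dataset
#'
#' One recording per subject (each with its own deterministic jitter, same
#' class structure) plus the ground-truth coupling table.
#'
#' @param spec A \code{\link{synth_spec}}.
#' @return List with \code{recordings} (list of \code{eeg_recording}) and
#'   \code{coupling_table} (data frame: class, channel pair, oscillator
#'   frequency).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "mvbn_synth_spec"))
  recs <- lapply(seq_len(spec$n_subjects),
                 function(i) generate_recording(spec, i))
  rows <- list()
  for (nm in names(spec$classes)) {
    cl <- spec$classes[[nm]]
    for (pr in cl$pairs)
      rows[[length(rows) + 1L]] <-
        data.frame(class = nm, ch1 = pr[1], ch2 = pr[2],
                   center_hz = cl$center_hz, stringsAsFactors = FALSE)
  }
  coupling_table <- if (length(rows)) do.call(rbind, rows)
    else data.frame(class = character(), ch1 = character(),
                    ch2 = character(), center_hz = numeric())
  list(recordings = recs, coupling_table = coupling_table)
}
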