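# Pairwise functional-connectivity estimators and the multi-view tensor.
#
# Five views of the coupling between two channels:
#   pcc  linear temporal correlation (Pearson)
#   mi   information-theoretic dependence (histogram plug-in, bits)
#   plv  phase-locking value, |mean unit phasor of the phase difference|
#   pli  phase-lag index, |mean sign of the phase difference|
#   psi  phase-instability index, mean |wrapped first difference| of the
#        phase-difference series (NOT the classical phase-slope index; the
#        estimator is implemented exactly as defined for this model)

#' Wrap angles into (-pi, pi]
#' @param p Numeric vector/matrix of angles in radians.
#' @return Wrapped angles, same shape.
#' @export
wrap_phase <- function(p) -((-p + pi) %% (2 * pi) - pi)

#' Pearson correlation between two channels
#'
#' Standard sample correlation \code{cov(x, y) / sqrt(var(x) var(y))}. A
#' constant input has no defined correlation; it is returned as 0 with a
#' warning.
#'
#' @param x,y Equal-length numeric sample vectors (length >= 2).
#' @return Correlation in [-1, 1].
#' @export
pearson_cc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input to pearson_cc; returning 0")
    return(0)
  }
  stats::cor(x, y)
}

# Equal-width bin index over the vector's own [min, max]; a constant vector
# collapses into bin 1.
.bin_index <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  pmin(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L, bins)
}

#' Histogram mutual information between two channels
#'
#' Plug-in estimate of the mutual information in bits (log base 2) from an
#' equal-width joint histogram: each vector is binned over its own
#' [min, max] range into \code{bins} bins, and empty joint cells contribute
#' zero.
#'
#' @param x,y Equal-length numeric sample vectors.
#' @param bins Number of histogram bins per axis (default 16).
#' @return Mutual information in bits (>= 0).
#' @export
mutual_information <- function(x, y, bins = 16) {
  n <- length(x)
  if (n != length(y) || n < 2) stop("x and y must have equal length >= 2")
  bx <- .bin_index(x, bins)
  by <- .bin_index(y, bins)
  joint <- tabulate(bx + bins * (by - 1L), nbins = bins * bins) / n
  pj <- matrix(joint, bins, bins)        # [x-bin, y-bin]
  px <- rowSums(pj)
  py <- colSums(pj)
  nz <- which(pj > 0, arr.ind = TRUE)
  p <- pj[nz]
  sum(p * log2(p / (px[nz[, 1]] * py[nz[, 2]])))
}

#' Instantaneous phase via the analytic signal
#'
#' Computes each channel's instantaneous phase as the argument of its
#' analytic signal (Hilbert-transform convention, FFT implementation),
#' wrapped to (-pi, pi]. Meaningful on band-limited signals; on broadband
#' signals the instantaneous phase is only weakly defined.
#'
#' @param x Channels x samples numeric matrix (>= 8 samples), or a vector.
#' @return Matrix of phases in radians, same shape as \code{x}.
#' @export
instantaneous_phase <- function(x) {
  x <- .check_signal_matrix(x)
  n <- ncol(x)
  if (n < 8) stop("need at least 8 samples for phase estimation")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  t(apply(x, 1L, function(ch) Arg(stats::fft(stats::fft(ch) * h,
                                             inverse = TRUE) / n)))
}

#' Phase-locking value
#'
#' Modulus of the mean unit phasor of a phase-difference series:
#' \code{|mean(exp(1i * dphi))|}. 1 for perfectly locked phases, near
#' \code{sqrt(pi / (4 N))} for independent uniform phases.
#'
#' @param dphi Phase-difference vector in radians (length >= 1).
#' @return Value in [0, 1].
#' @export
plv <- function(dphi) {
  if (length(dphi) < 1) stop("empty phase-difference series")
  Mod(mean(exp(1i * dphi)))
}

#' Phase-lag index
#'
#' Absolute mean sign of the phase difference, \code{|mean(sign(dphi))|};
#' insensitive to zero-lag (volume-conduction-like) coupling since
#' \code{sign(0) = 0}.
#'
#' @inheritParams plv
#' @return Value in [0, 1].
#' @export
pli <- function(dphi) {
  if (length(dphi) < 1) stop("empty phase-difference series")
  abs(mean(sign(dphi)))
}

#' Phase-instability index
#'
#' Mean absolute first difference of the phase-difference series, with each
#' first difference wrapped into (-pi, pi] before taking the absolute value.
#' Zero for a constant phase lag; grows with phase-relation volatility.
#'
#' @inheritParams plv
#' @return Value >= 0.
#' @export
psi <- function(dphi) {
  if (length(dphi) < 2) stop("need at least 2 phase-difference samples")
  mean(abs(wrap_phase(diff(dphi))))
}

#' Connectivity matrix of one epoch under one measure
#'
#' Evaluates the chosen measure on every unordered channel pair of a
#' channels x samples matrix. Phase-based measures (plv, pli, psi) first
#' extract per-channel instantaneous phases and use the wrapped difference
#' \code{phi_i - phi_j}. The diagonal is set to the measure's self-value
#' convention: 1 for pcc and plv, 0 for mi, pli and psi (so unbounded
#' self-information never dominates downstream normalization).
#'
#' @param x Channels x samples matrix (>= 2 channels).
#' @param measure One of \code{"pcc"}, \code{"mi"}, \code{"plv"},
#'   \code{"pli"}, \code{"psi"}.
#' @param bins Histogram bins for \code{measure = "mi"}.
#' @return Symmetric C x C matrix with the measure as a \code{"measure"}
#'   attribute.
#' @export
connectivity_matrix <- function(x, measure = MVBN_MEASURES, bins = 16) {
  measure <- match.arg(measure)
  x <- .check_signal_matrix(x)
  C <- nrow(x)
  if (C < 2) stop("need at least 2 channels")
  A <- matrix(0, C, C)
  if (measure == "pcc") {
    sds <- apply(x, 1L, sd)
    if (any(sds == 0)) {
      warning("constant channel(s); their correlations set to 0")
      ok <- sds > 0
      if (sum(ok) >= 2) A[ok, ok] <- stats::cor(t(x[ok, , drop = FALSE]))
    } else {
      A <- stats::cor(t(x))
    }
    diag(A) <- 1
  } else if (measure == "mi") {
    for (i in 1:(C - 1)) for (j in (i + 1):C)
      A[i, j] <- A[j, i] <- mutual_information(x[i, ], x[j, ], bins)
  } else {
    ph <- instantaneous_phase(x)
    f <- switch(measure, plv = plv, pli = pli, psi = psi)
    for (i in 1:(C - 1)) for (j in (i + 1):C) {
      dphi <- wrap_phase(ph[i, ] - ph[j, ])
      A[i, j] <- A[j, i] <- f(dphi)
    }
    if (measure == "plv") diag(A) <- 1
  }
  structure(A, measure = measure)
}

#' Define the set of connectivity views
#'
#' A view specification is an ordered list of (measure, band) pairs; the
#' multi-view tensor stacks one connectivity matrix per view in this order.
#' The default preset \code{"default10"} is the model's 10-view
#' configuration: all five measures on the broadband signal followed by all
#' five measures on the delta band (delta dominates neonatal EEG).
#'
#' @param measures Character vector of measure codes, or the preset name
#'   \code{"default10"}.
#' @param bands Character vector of band names, recycled against
#'   \code{measures}.
#' @return Data frame with columns \code{measure} and \code{band}, class
#'   \code{"mvbn_view_spec"}.
#' @examples
#' view_spec()                         # the 10-view default
#' view_spec(c("pcc", "plv"), "delta") # a 2-view spec
#' @export
view_spec <- function(measures = "default10", bands = NULL) {
  if (identical(measures, "default10")) {
    vs <- data.frame(
      measure = rep(MVBN_MEASURES, 2),
      band = rep(c("broadband", "delta"), each = 5),
      stringsAsFactors = FALSE)
  } else {
    if (is.null(bands)) stop("bands must be given with explicit measures")
    vs <- data.frame(measure = measures, band = bands,
                     stringsAsFactors = FALSE)
  }
  if (!all(vs$measure %in% MVBN_MEASURES))
    stop("unknown measure(s): ",
         paste(setdiff(vs$measure, MVBN_MEASURES), collapse = ", "))
  if (!all(vs$band %in% names(MVBN_BANDS)))
    stop("unknown band(s): ",
         paste(setdiff(vs$band, names(MVBN_BANDS)), collapse = ", "))
  if (anyDuplicated(paste(vs$measure, vs$band)))
    stop("duplicate (measure, band) pairs in view spec")
  structure(vs, class = c("mvbn_view_spec", "data.frame"))
}

#' Build the multi-view brain network of one epoch
#'
#' Stacks one connectivity matrix per view of \code{spec}, computed on the
#' matching rhythm band, into an N x C x C tensor. Views from unbounded
#' measures (mi, psi) are min-max normalized to [0, 1] per view by default
#' so all views enter the model on a comparable scale.
#'
#' @param bands A \code{band_set} from \code{\link{extract_rhythms}} (only
#'   the bands named in \code{spec} are required).
#' @param spec A \code{\link{view_spec}}.
#' @param normalize Min-max normalize mi/psi views (default \code{TRUE}).
#' @param bins Histogram bins for the mi views.
#' @return N x C x C array with the spec attached as attribute
#'   \code{"view_spec"}.
#' @export
build_multiview <- function(bands, spec = view_spec(), normalize = TRUE,
                            bins = 16) {
  stopifnot(inherits(spec, "mvbn_view_spec"))
  missing_b <- setdiff(unique(spec$band), names(bands))
  if (length(missing_b))
    stop("band(s) not present in band set: ",
         paste(missing_b, collapse = ", "))
  C <- nrow(bands[[spec$band[1]]])
  N <- nrow(spec)
  G <- array(0, dim = c(N, C, C))
  # phases are shared by plv/pli/psi within a band: compute once per band
  need_phase <- unique(spec$band[spec$measure %in% c("plv", "pli", "psi")])
  phases <- lapply(bands[need_phase], instantaneous_phase)
  for (k in seq_len(N)) {
    m <- spec$measure[k]
    b <- spec$band[k]
    A <- if (m %in% c("plv", "pli", "psi"))
      .phase_conn_matrix(phases[[b]], m)
    else
      connectivity_matrix(bands[[b]], m, bins = bins)
    if (normalize && m %in% c("mi", "psi")) {
      rng <- range(A)
      if (rng[2] > rng[1]) A <- (A - rng[1]) / (rng[2] - rng[1])
    }
    G[k, , ] <- A
  }
  attr(G, "view_spec") <- spec
  G
}

# Vectorized phase-measure matrix from a precomputed phase matrix.
.phase_conn_matrix <- function(ph, measure) {
  C <- nrow(ph)
  A <- matrix(0, C, C)
  for (i in 1:(C - 1)) {
    dphi <- wrap_phase(ph[rep(i, C - i), , drop = FALSE] -
                       ph[(i + 1):C, , drop = FALSE])
    v <- switch(measure,
      plv = Mod(rowMeans(exp(1i * dphi))),
      pli = abs(rowMeans(sign(dphi))),
      psi = rowMeans(abs(wrap_phase(dphi[, -1, drop = FALSE] -
                                    dphi[, -ncol(dphi), drop = FALSE]))))
    A[i, (i + 1):C] <- v
    A[(i + 1):C, i] <- v
  }
  if (measure == "plv") diag(A) <- 1
  A
}

#' Extract multi-view features from preprocessed recordings
#'
#' Runs epoch splitting, rhythm decomposition and multi-view network
#' construction over a list of recordings, dropping excluded epochs, and
#' returns the stacked epoch tensor with labels and subject ids — the input
#' expected by \code{\link{mvbn_fit}} and \code{\link{run_cv}}.
#'
#' @param recordings A single \code{eeg_recording} or a list of them
#'   (already preprocessed, i.e. at the working sampling rate).
#' @param spec A \code{\link{view_spec}}.
#' @param epoch_s Epoch length in seconds.
#' @param exclude Named list: per subject id, a vector of 0-based epoch
#'   indices to exclude.
#' @param normalize,bins Passed to \code{\link{build_multiview}}.
#' @return An object of class \code{"mvbn_dataset"}: list with \code{x}
#'   (L x N x C x C array), \code{y} (factor of stage labels),
#'   \code{subject} (character), \code{view_spec}.
#' @export
extract_features <- function(recordings, spec = view_spec(), epoch_s = 30,
                             exclude = list(), normalize = TRUE, bins = 16) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  tensors <- list(); labels <- character(); subjects <- character()
  for (rec in recordings) {
    eps <- epoch_split(rec, epoch_s = epoch_s,
                       exclude = exclude[[rec$subject_id]] %||% integer())
    eps <- Filter(function(e) !e$excluded, eps)
    for (e in eps) {
      bs <- extract_rhythms(e$data, rec$fs, bands = unique(spec$band))
      tensors[[length(tensors) + 1L]] <-
        build_multiview(bs, spec, normalize = normalize, bins = bins)
      labels <- c(labels, e$label)
      subjects <- c(subjects, e$subject_id)
    }
  }
  if (!length(tensors)) stop("no scored epochs found")
  N <- dim(tensors[[1]])[1]; C <- dim(tensors[[1]])[2]
  x <- array(0, dim = c(length(tensors), N, C, C))
  for (l in seq_along(tensors)) x[l, , , ] <- tensors[[l]]
  structure(list(x = x,
                 y = factor(labels, levels = MVBN_STAGES),
                 subject = subjects,
                 view_spec = spec),
            class = "mvbn_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mvbn_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat("Multi-view network dataset: ", d[1], " epochs x ", d[2], " views x ",
      d[3], "x", d[4], " channels; ", length(unique(x$subject)),
      " subject(s)\n", sep = "")
  print(table(subject = x$subject, stage = x$y))
  invisible(x)
}
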