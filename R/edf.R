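# Minimal EDF (European Data Format) input/output.
#
# EDF is a fixed-layout format: a 256-byte ASCII header, 256 ASCII bytes per
# signal, then data records of 16-bit little-endian integers that map
# linearly from the digital to the physical range. This reader/writer
# supports the plain-EDF subset needed here: equal-duration records,
# one sampling rate per signal, no embedded annotation signals.

.edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)          # left-justified, space-padded
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over a physical range of
#' \code{phys_range} microvolts (values outside are clipped). One data
#' record holds one second of signal, so \code{fs} must be a positive
#' integer and the recording is truncated to a whole number of seconds.
#' When the recording carries annotations, a plain-text sidecar label file
#' (one stage per line) is written next to the EDF unless
#' \code{labels_path = NA}.
#'
#' @param rec An \code{eeg_recording}.
#' @param path Output EDF path.
#' @param phys_range Physical full-scale in microvolts (symmetric).
#' @param labels_path Path for the sidecar label file; default replaces the
#'   EDF extension with \code{.labels.txt}; \code{NA} suppresses it.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = 1000, labels_path = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs) || fs <= 0) stop("write_edf needs an integer fs")
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) stop("recording shorter than one data record (1 s)")

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(paste("X X X", rec$subject_id), 80),
    .edf_pad(paste("Startdate 01-JAN-2024", rec$subject_id), 80),
    .edf_pad("01.01.24", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (ns + 1), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad("1", 8), .edf_pad(ns, 4)
  )
  field <- function(vals, width)
    paste(vapply(vals, .edf_pad, "", width = width), collapse = "")
  hdr <- paste0(
    hdr,
    field(paste("EEG", rec$channel_labels), 16),
    field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    field(rep(-phys_range, ns), 8),
    field(rep(phys_range, ns), 8),
    field(rep(-32767L, ns), 8),
    field(rep(32767L, ns), 8),
    field(rep("", ns), 80),
    field(rep(fs, ns), 8),
    field(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  scale <- 32767 / phys_range
  dig <- round(pmin(pmax(rec$data[, seq_len(n_rec * fs), drop = FALSE],
                         -phys_range), phys_range) * scale)
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    # record = each signal's samples back to back
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }

  if (length(rec$annotations) && !isTRUE(is.na(labels_path))) {
    if (is.null(labels_path)) labels_path <- .sidecar_path(path)
    write_stage_labels(rec$annotations, labels_path)
  }
  invisible(path)
}

.sidecar_path <- function(edf_path)
  paste0(tools::file_path_sans_ext(edf_path), ".labels.txt")

#' Read an EDF file into a recording
#'
#' Parses the EDF header, checks that every required channel is present (a
#' missing channel is a hard error naming the channel), verifies that the
#' required channels share one sampling rate, and returns the signals
#' reordered to \code{required_channels}. Channel labels are matched after
#' stripping a leading \code{"EEG"} prefix and reference suffixes such as
#' \code{"-REF"}. Per-epoch stage annotations are read from a sidecar label
#' file (\code{<path>.labels.txt}) when present, else all epochs are
#' \code{UNSCORED}.
#'
#' @param path EDF file path.
#' @param required_channels Canonical channel list; default
#'   \code{MVBN_CHANNELS}.
#' @param labels_path Optional explicit sidecar label path.
#' @return An \code{eeg_recording} with channels in canonical order.
#' @export
read_edf <- function(path, required_channels = MVBN_CHANNELS,
                     labels_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rd(8))
  if (!identical(version, "0")) stop("not a parseable EDF file: ", path)
  rd(80)                                  # patient id
  rec_id <- trimws(rd(80))
  rd(16)                                  # start date + time
  rd(8)                                   # header bytes
  rd(44)                                  # reserved
  n_rec <- as.integer(trimws(rd(8)))
  dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1) stop("not a parseable EDF file: ", path)

  fld <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  labels <- fld(16)
  fld(80); fld(8); phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8)); fld(80)
  spr <- as.integer(fld(8))               # samples per record, per signal
  fld(32)

  clean <- toupper(gsub("^EEG\\s*", "",
                        gsub("[-_ ](REF|LE|AVG|A1|A2|M1|M2)$", "", labels,
                             ignore.case = TRUE)))
  pos <- match(toupper(required_channels), clean)
  if (anyNA(pos))
    stop("required channel ", required_channels[which(is.na(pos))[1]],
         " absent")
  if (length(unique(spr[pos])) != 1L)
    stop("inconsistent per-channel sampling rates among required channels")
  fs <- spr[pos[1]] / dur

  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * sum(spr)) stop("truncated EDF data: ", path)
  offsets <- c(0L, cumsum(spr))
  data <- matrix(0, nrow = length(pos), ncol = n_rec * spr[pos[1]])
  for (ci in seq_along(pos)) {
    s <- pos[ci]
    gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    cols <- unlist(lapply(seq_len(n_rec) - 1L, function(r)
      r * sum(spr) + offsets[s] + seq_len(spr[s])))
    data[ci, ] <- (raw[cols] - dig_min[s]) * gain + phys_min[s]
  }

  subject <- sub("^Startdate \\S+\\s*", "", rec_id)
  if (!nzchar(subject)) subject <- tools::file_path_sans_ext(basename(path))
  if (is.null(labels_path)) labels_path <- .sidecar_path(path)
  ann <- if (file.exists(labels_path)) read_stage_labels(labels_path)
         else character()
  eeg_recording(data, fs, required_channels, subject, ann)
}

#' Read / write sidecar stage-label files
#'
#' Plain-text label files hold one stage per line (\code{W}, \code{AS},
#' \code{QS} or \code{UNSCORED}), aligned to 0-based epoch index.
#'
#' @param path Label file path.
#' @return \code{read_stage_labels}: character vector of stage labels.
#' @export
read_stage_labels <- function(path) {
  labs <- trimws(readLines(path, warn = FALSE))
  labs <- labs[nzchar(labs)]
  bad <- setdiff(labs, c(MVBN_STAGES, "UNSCORED"))
  if (length(bad))
    stop("unknown stage label(s) in ", path, ": ",
         paste(unique(bad), collapse = ", "))
  labs
}

#' @rdname read_stage_labels
#' @param labels Character vector of stage labels.
#' @export
write_stage_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}

#' Read a plain-text epoch exclusion list
#'
#' One 0-based epoch index per line; blank lines and \code{#} comments are
#' ignored.
#'
#' @param path Exclusion-list path.
#' @return Integer vector of 0-based epoch indices.
#' @export
read_exclusion_list <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) return(integer())
  idx <- suppressWarnings(as.integer(ln))
  if (anyNA(idx)) stop("non-integer entry in exclusion list ", path)
  idx
}
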