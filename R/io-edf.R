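## Continuous EDF read/write for polysomnography traces.
## EDF stores each signal as 16-bit integers per fixed-duration data record,
## with a per-signal linear digital->physical calibration in an ASCII header.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = max(1, width - 2))
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

#' Write continuous EEG to an EDF file
#'
#' Writes a European Data Format (EDF) file with one data record per second.
#' Each channel gets a symmetric physical range covering its data, mapped onto
#' the full 16-bit digital range, so the quantization step is
#' `2 * max(abs(x)) / 65535` microvolts. The signal is zero-padded to a whole
#' number of records; the original sample count is restored on read via the
#' recording-identification field.
#'
#' @param eeg An [eeg_continuous()] object (microvolt units).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_continuous"))
  rate <- eeg$rate
  if (abs(rate - round(rate)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  rate <- as.integer(round(rate))
  ns <- nrow(eeg$data)
  n_samp <- ncol(eeg$data)
  n_rec <- as.integer(ceiling(n_samp / rate))
  pad <- n_rec * rate - n_samp
  data <- if (pad > 0) cbind(eeg$data, matrix(0, ns, pad)) else eeg$data

  ## integer physical bounds keep the ASCII header exact; symmetric digital
  ## range makes gain = phys_max / 32767 with zero offset
  phys_max <- pmax(ceiling(apply(abs(data), 1, max)), 1)
  dig_max <- 32767; dig_min <- -32767
  gain <- phys_max / dig_max

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("X X X X", 80),
    .edf_pad(paste0("Startdate X X X X nsamples=", n_samp), 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256L * (1L + ns), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(1, 8),
    .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, .edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(eeg$channels, 16)
  field(rep("", ns), 80)                                   # transducer
  field(rep("uV", ns), 8)                                  # physical dimension
  writeChar(paste(vapply(-phys_max, .edf_num, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(phys_max, .edf_num, "", width = 8), collapse = ""), con, eos = NULL)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                                   # prefiltering
  field(rep(rate, ns), 8)                                  # samples per record
  field(rep("", ns), 32)

  dig <- matrix(0L, ns, n_rec * rate)
  for (i in seq_len(ns))
    dig[i, ] <- as.integer(pmax(dig_min, pmin(dig_max, round(data[i, ] / gain[i]))))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a continuous EDF file
#'
#' @param path Input file path.
#' @return An [eeg_continuous()] with data in the file's physical units.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readChar(con, w)
  rd(8)                                      # version
  rd(80)                                     # patient id
  rec_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fields(16)
  fields(80); fields(8)
  phys_min <- as.numeric(fields(8)); phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8)); dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1L)
    stop("read_edf supports a single sampling rate across signals")
  rate <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, "integer", ns * spr[1], size = 2, signed = TRUE,
                   endian = "little")
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, idx] <- matrix(blk, nrow = spr[1])[, seq_len(ns)] |> t()
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  off <- phys_max - gain * dig_max
  data <- data * gain + off
  m <- regmatches(rec_id, regexpr("nsamples=[0-9]+", rec_id))
  if (length(m) == 1L) {
    n_true <- as.integer(sub("nsamples=", "", m))
    if (n_true <= ncol(data)) data <- data[, seq_len(n_true), drop = FALSE]
  }
  eeg_continuous(data, rate, labels)
}

#' Write / read a stimulus event table as TSV
#'
#' Columns: `onset_sample` (0-based sample index), `stimulus_id`, `condition`,
#' `roughness`, `pitch`, plus any extra columns present.
#'
#' @param events Data frame of events.
#' @param path File path.
#' @return `path` invisibly (writer); a data frame (reader).
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("onset_sample", "stimulus_id", "condition", "roughness",
                  "pitch") %in% names(events)))
  write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  if (is.unsorted(ev$onset_sample, strictly = TRUE))
    stop("event onsets must be strictly increasing")
  ev
}

#' Write / read a hypnogram as TSV
#'
#' One stage label (`W`, `N1`, `N2`, `N3`, `R`) per 20-second epoch, in order.
#'
#' @param hyp A `hypnogram` object (see [hypnogram()]).
#' @param path File path.
#' @return `path` invisibly (writer); a `hypnogram` (reader).
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(epoch = seq_along(hyp$stages) - 1L,
                   onset_s = (seq_along(hyp$stages) - 1L) * hyp$epoch_length,
                   stage = hyp$stages)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  hypnogram(df$stage)
}

#' Hypnogram container
#'
#' Sleep stages scored on consecutive 20-second epochs.
#'
#' @param stages Character vector over `{W, N1, N2, N3, R}`.
#' @param epoch_length Epoch length in seconds; the scoring standard (and this
#'   package) uses 20 s.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_length = 20) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), c("W", "N1", "N2", "N3", "R"))
  if (length(bad)) stop("unknown sleep stages: ", paste(bad, collapse = ", "))
  if (epoch_length != 20) stop("hypnogram epochs are scored on 20-s windows")
  structure(list(stages = stages, epoch_length = epoch_length),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tb <- table(factor(x$stages, levels = c("W", "N1", "N2", "N3", "R")))
  cat(sprintf("<hypnogram> %d x %g-s epochs (%.1f min): %s\n",
              length(x$stages), x$epoch_length,
              length(x$stages) * x$epoch_length / 60,
              paste(names(tb), tb, sep = "=", collapse = " ")))
  invisible(x)
}
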