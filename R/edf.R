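# Compact European Data Format (EDF) writer/reader.
#
# 16-bit EDF with one-second data records. Channel kind is encoded in the
# label field using the conventional "EEG Fz" / "EOG veog" / "MEG MEG01"
# prefixes; the true sample count is kept in the reserved header field so a
# final zero-padded record can be trimmed on read. Header timestamps are
# fixed (not wall-clock) so identical recordings serialize byte-identically.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) edf_pad(sub("\\.?0+$", "", sprintf("%.6f", x)), width)

#' Write a continuous recording to an EDF file
#'
#' Samples are quantized to 16 bits over a symmetric per-channel physical
#' range covering the data, so the round-trip error is at most
#' `physical_range / 2^16`. The sampling rate must be a whole number (one
#' data record per second); a trailing partial second is zero-padded and
#' trimmed again by [read_edf()].
#'
#' @param rec a [continuous_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  check_that(inherits(rec, "continuous_recording"), "rec must be a continuous_recording")
  n <- ncol(rec$data)
  check_that(n > 0, "cannot write an empty recording")
  srate <- rec$srate
  check_that(abs(srate - round(srate)) < 1e-9, "EDF writer requires an integer sampling rate")
  srate <- round(srate)
  ns <- nrow(rec$data)
  n_rec <- ceiling(n / srate)

  phys_max <- apply(abs(rec$data), 1, max)
  phys_max[phys_max == 0] <- 1
  phys_max <- signif(phys_max * 1.0001, 6)  # headroom so max value stays in range
  dig_max <- 32767

  kind_prefix <- c(eeg = "EEG", eog = "EOG", meg = "MEG")
  labels <- paste(kind_prefix[rec$channels$kind], rec$channels$label)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad("Startdate 01-JAN-2000 X X X", 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 * (1 + ns), 8))
  wr(edf_pad(sprintf("RN400 NSAMP=%d", n), 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(ns, 4))
  wr(paste(vapply(labels, edf_pad, "", width = 16), collapse = ""))
  wr(paste(rep(edf_pad("synthetic", 80), ns), collapse = ""))
  wr(paste(vapply(rec$channels$unit, edf_pad, "", width = 8), collapse = ""))
  wr(paste(vapply(-phys_max, edf_num, "", width = 8), collapse = ""))
  wr(paste(vapply(phys_max, edf_num, "", width = 8), collapse = ""))
  wr(paste(rep(edf_pad(-dig_max, 8), ns), collapse = ""))
  wr(paste(rep(edf_pad(dig_max, 8), ns), collapse = ""))
  wr(paste(rep(edf_pad("", 80), ns), collapse = ""))
  wr(paste(rep(edf_pad(srate, 8), ns), collapse = ""))
  wr(paste(rep(edf_pad("", 32), ns), collapse = ""))

  scale <- dig_max / phys_max
  padded <- cbind(rec$data, matrix(0, ns, n_rec * srate - n))
  for (r in seq_len(n_rec)) {
    block <- padded[, (r - 1) * srate + seq_len(srate), drop = FALSE]
    dig <- round(block * scale)  # channels x samples
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return A [continuous_recording]; labels, kinds, units and rate are
#'   restored exactly, sample values within the 16-bit quantization of the
#'   declared physical range.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  check_that(version == "0", "not an EDF file (version field '%s')", version)
  rd(80); rd(80); rd(8); rd(8); rd(8)
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  check_that(ns > 0, "EDF file declares no channels")
  labels_raw <- vapply(seq_len(ns), function(i) rd(16), "")
  rd(80 * ns)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  check_that(length(unique(spr)) == 1, "channels with mixed sampling rates are not supported")
  srate <- spr[1] / rec_dur

  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2, endian = "little")
    data[, (r - 1) * spr[1] + seq_len(spr[1])] <- matrix(raw, ns, spr[1], byrow = TRUE)
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- data * scale + (phys_max - scale * dig_max)

  m <- regmatches(reserved, regexec("NSAMP=(\\d+)", reserved))[[1]]
  if (length(m) == 2) data <- data[, seq_len(as.integer(m[2])), drop = FALSE]

  parts <- strsplit(labels_raw, " +")
  kinds <- tolower(vapply(parts, `[`, "", 1))
  labels <- vapply(parts, function(p) paste(p[-1], collapse = " "), "")
  bad <- !(kinds %in% c("eeg", "eog", "meg"))
  if (any(bad)) { labels[bad] <- labels_raw[bad]; kinds[bad] <- "eeg" }
  continuous_recording(data, labels, kinds, srate)
}
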