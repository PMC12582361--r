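# Minimal European Data Format (EDF, 16-bit) reader/writer.
# Covers the subset needed for multichannel ECoG at a single sampling rate:
# continuous signals, equal fs across channels, 1-s data records.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a channels-by-samples matrix to an EDF file
#'
#' Signals are quantized to 16-bit integers over a symmetric physical range
#' taken from the data (per channel), so round-trip error is bounded by the
#' per-channel quantization step (range / 65534).
#'
#' @param samples numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz; must divide samples into whole 1-s records.
#' @param labels character channel labels (<= 16 bytes each).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(samples, fs, labels, path) {
  stopifnot(is.matrix(samples), nrow(samples) == length(labels), fs > 0)
  if (!all(is.finite(samples))) stop("non-finite sample values cannot be written")
  n_ch <- nrow(samples)
  spr <- as.integer(round(fs))            # samples per 1-s record
  n_rec <- floor(ncol(samples) / spr)
  if (n_rec < 1L) stop("recording shorter than one 1-s data record")
  samples <- samples[, seq_len(n_rec * spr), drop = FALSE]

  phys_max <- pmax(apply(abs(samples), 1L, max), 1e-6)
  dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))

  hdr <- paste0(
    .edf_pad("0", 8L),
    .edf_pad("X X X X", 80L),
    .edf_pad("Startdate X X X X", 80L),
    .edf_pad("01.01.01", 8L), .edf_pad("00.00.00", 8L),
    .edf_pad(256L * (1L + n_ch), 8L),
    .edf_pad("", 44L),
    .edf_pad(n_rec, 8L),
    .edf_pad("1", 8L),
    .edf_pad(n_ch, 4L)
  )
  sig_hdr <- paste0(
    paste(vapply(labels, .edf_pad, "", width = 16L), collapse = ""),
    paste(rep(.edf_pad("", 80L), n_ch), collapse = ""),
    paste(rep(.edf_pad("uV", 8L), n_ch), collapse = ""),
    paste(vapply(-phys_max, .edf_pad, "", width = 8L), collapse = ""),
    paste(vapply(phys_max, .edf_pad, "", width = 8L), collapse = ""),
    paste(rep(.edf_pad(-dig_max, 8L), n_ch), collapse = ""),
    paste(rep(.edf_pad(dig_max, 8L), n_ch), collapse = ""),
    paste(rep(.edf_pad("", 80L), n_ch), collapse = ""),
    paste(rep(.edf_pad(spr, 8L), n_ch), collapse = ""),
    paste(rep(.edf_pad("", 32L), n_ch), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)

  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    block <- t(round(samples[, idx, drop = FALSE] * scale))
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by this package (or any single-rate EDF)
#'
#' @param path EDF file path.
#' @return list with `samples` (channels x samples matrix, physical units),
#'   `fs` (Hz) and `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L)                                    # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  n_ch <- as.integer(rd(4L))
  rdv <- function(w) vapply(seq_len(n_ch), function(i) rd(w), "")
  labels <- rdv(16L)
  rdv(80L); rdv(8L)
  phys_min <- as.numeric(rdv(8L)); phys_max <- as.numeric(rdv(8L))
  dig_min <- as.numeric(rdv(8L));  dig_max <- as.numeric(rdv(8L))
  rdv(80L)
  spr <- as.integer(rdv(8L))
  rdv(32L)
  if (length(unique(spr)) != 1L) stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1L] / rec_dur

  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 endian = "little", signed = TRUE)
  samples <- matrix(0, n_ch, n_rec * spr[1L])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  off <- phys_max - gain * dig_max
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
      samples[ch, idx] <- raw[pos + seq_len(spr[ch])] * gain[ch] + off[ch]
      pos <- pos + spr[ch]
    }
  }
  list(samples = samples, fs = fs, labels = labels)
}
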