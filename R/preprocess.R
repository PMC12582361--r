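# Preprocessing: zero-phase band-pass and notch filtering, and a robust
# automated artifact mask replacing visual screening.

#' Artifact mask
#'
#' @param bad logical matrix (channels x samples), TRUE where masked.
#' @param reject per-channel logical reject flag.
#' @return object of class `sevo_mask`.
#' @export
artifact_mask <- function(bad, reject = rep(FALSE, nrow(bad))) {
  stopifnot(is.matrix(bad), is.logical(bad), length(reject) == nrow(bad))
  structure(list(bad = bad, reject = reject), class = "sevo_mask")
}

#' Masked sample ranges per channel
#' @param mask a [artifact_mask()].
#' @return list per channel of two-column matrices (0-based half-open ranges).
#' @export
mask_ranges <- function(mask) {
  lapply(seq_len(nrow(mask$bad)), function(ch) {
    r <- rle(mask$bad[ch, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    cbind(start = starts[r$values], end = ends[r$values])
  })
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, implemented as a
#' high-pass / low-pass cascade so the extreme band ratio (0.016-300 Hz at
#' 1000 Hz) stays numerically stable.
#'
#' @param rec a [recording()].
#' @param lo,hi band edges in Hz; `hi` must be below Nyquist.
#' @param order Butterworth order per section (default 2 high-pass,
#'   4 low-pass as `c(2, 4)`).
#' @return filtered [recording()].
#' @export
bandpass <- function(rec, lo = 0.016, hi = 300, order = c(2, 4)) {
  if (hi >= rec$fs / 2) stop("upper band edge at or above Nyquist")
  if (lo <= 0) stop("lower band edge must be positive")
  hp <- signal::butter(order[1], lo / (rec$fs / 2), type = "high")
  lp <- signal::butter(order[2], hi / (rec$fs / 2), type = "low")
  out <- rec
  for (ch in seq_len(nrow(rec$samples))) {
    x <- signal::filtfilt(hp, rec$samples[ch, ])
    out$samples[ch, ] <- signal::filtfilt(lp, x)
  }
  out
}

#' Zero-phase notch filter for line noise
#'
#' Butterworth band-stop applied forward-backward; with the default 3 Hz
#' stop band the double pass gives deep attenuation at `f0` while leaving
#' tones 5 Hz away essentially untouched.
#'
#' @param rec a [recording()].
#' @param f0 line frequency (Hz), default 60.
#' @param half_width half-width of the stop band (Hz).
#' @param order Butterworth order.
#' @return filtered [recording()].
#' @export
notch <- function(rec, f0 = 60, half_width = 1.5, order = 2) {
  if (f0 >= rec$fs / 2) stop("notch frequency at or above Nyquist")
  bs <- signal::butter(order, c(f0 - half_width, f0 + half_width) / (rec$fs / 2),
                       type = "stop")
  out <- rec
  for (ch in seq_len(nrow(rec$samples)))
    out$samples[ch, ] <- signal::filtfilt(bs, rec$samples[ch, ])
  out
}

#' Automated robust-threshold artifact mask
#'
#' Deterministic stand-in for visual screening: samples whose absolute
#' deviation from the channel median exceeds `z_amp` robust SDs (MAD-based)
#' are masked, masked runs are dilated by `min_gap` seconds, and channels
#' with more than half their samples masked (or zero MAD) are reject-flagged.
#' Masking only annotates; sample values are never altered.
#'
#' @param rec a [recording()].
#' @param z_amp robust-z threshold (default 6).
#' @param min_gap dilation half-width in seconds (default 0.5).
#' @param reject_frac masked fraction above which a channel is rejected.
#' @return a [artifact_mask()].
#' @export
auto_artifact_mask <- function(rec, z_amp = 6, min_gap = 0.5,
                               reject_frac = 0.5) {
  n <- ncol(rec$samples)
  bad <- matrix(FALSE, nrow(rec$samples), n)
  reject <- logical(nrow(rec$samples))
  pad <- as.integer(round(min_gap * rec$fs))
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    med <- stats::median(x)
    s <- stats::mad(x)
    if (s == 0) { reject[ch] <- TRUE; bad[ch, ] <- TRUE; next }
    hitv <- abs(x - med) > z_amp * s
    if (any(hitv)) {
      r <- rle(hitv)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      b <- logical(n)
      for (j in which(r$values))
        b[max(1L, starts[j] - pad):min(n, ends[j] + pad)] <- TRUE
      bad[ch, ] <- b
    }
    if (mean(bad[ch, ]) > reject_frac) reject[ch] <- TRUE
  }
  artifact_mask(bad, reject)
}

#' Attach a mask to a recording
#' @param rec a [recording()].
#' @param mask a [artifact_mask()].
#' @return the recording with `$mask` set.
#' @export
set_mask <- function(rec, mask) {
  stopifnot(inherits(mask, "sevo_mask"),
            nrow(mask$bad) == nrow(rec$samples),
            ncol(mask$bad) == ncol(rec$samples))
  rec$mask <- mask
  rec
}
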