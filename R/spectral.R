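# Morlet wavelet spectral amplitude (square root of power) and z-scoring
# against a control anaesthetic stage.

BAND_RANGES <- list(delta = c(3, 4), hfo = c(80, 300))

.band_grid <- function(band) {
  switch(band,
         delta = c(3, 3.5, 4),
         hfo = seq(80, 300, by = 10),
         stop("unknown band: ", band))
}

#' Morlet-wavelet band spectral amplitude
#'
#' Complex Morlet transform evaluated on a frequency grid spanning the band
#' (delta: 3, 3.5, 4 Hz; HFO: 80 to 300 Hz in 10 Hz steps by default), with
#' `n_cycles` cycles per wavelet. Per-sample band amplitude is the mean over
#' the grid of the per-frequency amplitude (square root of power). The
#' transform runs in the frequency domain over overlapping chunks whose
#' margins (four wavelet SDs) are discarded, so chunking introduces no
#' interior edge effects. Output is aligned sample-for-sample with the
#' input; masked samples and rejected channels propagate as NA.
#'
#' @param rec a preprocessed [recording()].
#' @param band "delta" (3-4 Hz) or "hfo" (80-300 Hz).
#' @param grid optional frequency grid (Hz) overriding the default.
#' @param n_cycles wavelet width in cycles (default 7).
#' @return object of class `sevo_amp` with `values` (channels x samples),
#'   `band`, `fs`, `labels`, `zscored_to = "none"`.
#' @export
wavelet_amplitude <- function(rec, band = c("delta", "hfo"), grid = NULL,
                              n_cycles = 7) {
  band <- match.arg(band)
  if (is.null(grid)) grid <- .band_grid(band)
  if (max(grid) >= rec$fs / 2) stop("band reaches or exceeds Nyquist")
  fs <- rec$fs
  n <- ncol(rec$samples)
  margin <- as.integer(ceiling(4 * n_cycles / (2 * pi * min(grid)) * fs))
  core <- 2L^16L - 2L * margin
  if (n <= 2L^16L) core <- n                    # single chunk, no splitting
  values <- matrix(NA_real_, nrow(rec$samples), n)
  starts <- seq(1L, n, by = core)
  for (ch in seq_len(nrow(rec$samples))) {
    if (!is.null(rec$mask) && rec$mask$reject[ch]) next
    for (s0 in starts) {
      s1 <- min(s0 + core - 1L, n)
      a <- max(1L, s0 - margin); b <- min(n, s1 + margin)
      amp <- .morlet_mean_amp(rec$samples[ch, a:b], fs, grid, n_cycles)
      values[ch, s0:s1] <- amp[(s0 - a + 1L):(s1 - a + 1L)]
    }
    if (!is.null(rec$mask)) values[ch, rec$mask$bad[ch, ]] <- NA_real_
  }
  structure(list(values = values, band = band, fs = fs,
                 labels = rec$channels$label, grid = grid,
                 zscored_to = "none", control_mean = NULL,
                 control_sd = NULL),
            class = "sevo_amp")
}

# Mean-over-grid Morlet amplitude of one signal chunk via FFT: each wavelet
# is a Gaussian in the frequency domain (SD = f / n_cycles), applied to the
# analytic (positive-frequency, doubled) spectrum so a unit-amplitude tone
# at a grid frequency returns amplitude 1 there.
.morlet_mean_amp <- function(x, fs, grid, n_cycles) {
  n <- length(x)
  nfft <- 2L^as.integer(ceiling(log2(n)))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  f_axis <- (seq_len(nfft) - 1L) * fs / nfft
  pos <- f_axis <= fs / 2                        # keep positive frequencies
  acc <- numeric(n)
  for (f in grid) {
    sigma_f <- f / n_cycles
    G <- numeric(nfft)
    G[pos] <- 2 * exp(-0.5 * ((f_axis[pos] - f) / sigma_f)^2)
    w <- stats::fft(X * G, inverse = TRUE) / nfft
    acc <- acc + Mod(w[seq_len(n)])
  }
  acc / length(grid)
}

#' z-score a spectral amplitude series against a control stage
#'
#' Per channel, subtracts the mean and divides by the SD of the unmasked
#' control-period amplitude (the full annotated control span). Channels with
#' fewer than `min_control_s` seconds of usable control data, or zero
#' control SD, are excluded (set NA) with a warning.
#'
#' @param amp a [wavelet_amplitude()] result.
#' @param segments epoch table from [segment_stages()].
#' @param control "Iso" or "SWS".
#' @param min_control_s minimum usable control data per channel (seconds).
#' @return `sevo_amp` with `zscored_to = control` and the per-channel
#'   control mean/SD retained.
#' @export
zscore_to_control <- function(amp, segments, control = c("Iso", "SWS"),
                              min_control_s = 60) {
  control <- match.arg(control)
  if (amp$zscored_to != "none") stop("amplitude series already z-scored")
  seg <- segments[segments$stage == control, , drop = FALSE]
  if (nrow(seg) == 0L) stop("no ", control, " control segments present")
  idx <- unlist(lapply(seq_len(nrow(seg)), function(i)
    (seg$start_sample[i] + 1L):seg$end_sample[i]))
  out <- amp
  out$control_mean <- rep(NA_real_, nrow(amp$values))
  out$control_sd <- rep(NA_real_, nrow(amp$values))
  dropped <- character()
  for (ch in seq_len(nrow(amp$values))) {
    ctrl <- amp$values[ch, idx]
    ctrl <- ctrl[is.finite(ctrl)]
    if (length(ctrl) < min_control_s * amp$fs || stats::sd(ctrl) == 0) {
      out$values[ch, ] <- NA_real_
      dropped <- c(dropped, amp$labels[ch])
      next
    }
    mu <- mean(ctrl); sdv <- stats::sd(ctrl)
    out$values[ch, ] <- (amp$values[ch, ] - mu) / sdv
    out$control_mean[ch] <- mu
    out$control_sd[ch] <- sdv
  }
  if (length(dropped))
    warning("channels excluded for unusable ", control, " baseline: ",
            paste(dropped, collapse = ", "))
  out$zscored_to <- control
  out
}
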