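# Burst binarization of z-scored spectral amplitude and pairwise plug-in
# transfer-entropy effective connectivity.

#' Binarize z-scored spectral amplitude into burst bins
#'
#' The epoch is cut into bins of `bin_cycles` wave-cycles, where the cycle
#' frequency is the lower band edge (delta: 3 Hz so 2-s bins; HFO: 80 Hz so
#' 75-ms bins). A bin is 1 if it overlaps a run of samples above the
#' z-threshold lasting at least `min_cycles` cycles; runs spanning a bin
#' boundary credit every bin they touch. Bins containing masked (NA)
#' samples are dropped as missing, not zero. A trailing partial bin is
#' discarded.
#'
#' @param amp_z a z-scored [wavelet_amplitude()] series.
#' @param start_sample,end_sample epoch range (0-based half-open); defaults
#'   to the whole series.
#' @param threshold z threshold (default 2).
#' @param min_cycles minimum burst duration in wave-cycles (default 3).
#' @param bin_cycles bin length in wave-cycles (default 6).
#' @return object of class `sevo_bursts`: `bits` (channels x bins matrix of
#'   0/1/NA), `bin_duration_s`, `cycle_freq_hz`, `band`, `labels`.
#' @export
binarize_bursts <- function(amp_z, start_sample = 0L,
                            end_sample = ncol(amp_z$values),
                            threshold = 2, min_cycles = 3, bin_cycles = 6) {
  if (amp_z$zscored_to == "none")
    stop("amplitude series must be z-scored before binarization")
  fs <- amp_z$fs
  cycle_freq <- BAND_RANGES[[amp_z$band]][1]
  bin_len <- bin_cycles / cycle_freq * fs
  min_run <- min_cycles / cycle_freq * fs       # samples, possibly fractional
  n <- end_sample - start_sample
  n_bins <- floor(n / bin_len)
  if (n_bins < 1L) stop("epoch shorter than one bin (", bin_len / fs, " s)")
  bin_of <- function(s) floor((s - 1L) / bin_len) + 1L   # 1-based sample -> bin
  bits <- matrix(0L, nrow(amp_z$values), n_bins)
  for (ch in seq_len(nrow(amp_z$values))) {
    z <- amp_z$values[ch, (start_sample + 1L):end_sample]
    isna <- !is.finite(z)
    above <- !isna & z > threshold
    r <- rle(above)
    rend <- cumsum(r$lengths)
    rstart <- rend - r$lengths + 1L              # 1-based within epoch
    for (j in which(r$values & r$lengths >= min_run)) {
      b0 <- max(1L, bin_of(rstart[j]))
      b1 <- min(n_bins, bin_of(rend[j]))
      if (b0 <= b1) bits[ch, b0:b1] <- 1L
    }
    if (any(isna)) {
      na_bins <- unique(bin_of(which(isna)))
      na_bins <- na_bins[na_bins >= 1L & na_bins <= n_bins]
      bits[ch, na_bins] <- NA_integer_
    }
  }
  structure(list(bits = bits, bin_duration_s = bin_len / fs,
                 cycle_freq_hz = cycle_freq, band = amp_z$band,
                 labels = amp_z$labels),
            class = "sevo_bursts")
}

#' Plug-in transfer entropy between two binary burst trains
#'
#' TE(src -> dst) = sum over (y_next, y_hist, x) of the joint probability
#' times log2 p(y_next | y_hist, x) / p(y_next | y_hist), with history
#' length `k` and lag one bin, probabilities taken as joint counts over
#' jointly non-missing triplets (0 log 0 = 0). Non-negative by construction
#' of the plug-in estimator.
#'
#' @param src,dst integer/logical vectors of bins (0/1/NA) on the same grid.
#' @param k target history length in bins (default 1).
#' @param min_triplets minimum jointly valid triplets (default 50).
#' @return TE in bits; attribute `degenerate` is TRUE when the target is
#'   constant (TE = 0 by convention).
#' @export
transfer_entropy <- function(src, dst, k = 1L, min_triplets = 50L) {
  src <- as.integer(src); dst <- as.integer(dst)
  if (length(src) != length(dst)) stop("bin grids differ in length")
  n <- length(dst)
  if (n < k + 1L) stop("series shorter than history length")
  t_idx <- (k + 1L):n
  x <- src[t_idx - 1L]
  y1 <- dst[t_idx]
  hist_code <- integer(length(t_idx))
  for (j in seq_len(k)) hist_code <- hist_code * 2L + dst[t_idx - j]
  ok <- !is.na(x) & !is.na(y1) & !is.na(hist_code)
  if (sum(ok) < min_triplets)
    stop("only ", sum(ok), " valid triplets (need ", min_triplets, ")")
  x <- x[ok]; y1 <- y1[ok]; h <- hist_code[ok]
  if (length(unique(y1)) == 1L && length(unique(dst[!is.na(dst)])) == 1L)
    return(structure(0, degenerate = TRUE))
  nh <- 2L^k
  joint <- y1 * (2L * nh) + x * nh + h + 1L      # index over (y1, x, h)
  c_jxh <- tabulate(joint, nbins = 4L * nh)
  arr <- array(c_jxh, dim = c(nh, 2L, 2L))       # [h, x, y1]
  c_xh <- apply(arr, c(1, 2), sum)               # counts (h, x)
  c_h1 <- apply(arr, c(1, 3), sum)               # counts (h, y1)
  c_h <- rowSums(c_xh)
  N <- length(x)
  te <- 0
  for (ih in seq_len(nh)) for (ix in 1:2) for (iy in 1:2) {
    cjoint <- arr[ih, ix, iy]
    if (cjoint == 0) next
    te <- te + cjoint / N *
      log2((cjoint * c_h[ih]) / (c_xh[ih, ix] * c_h1[ih, iy]))
  }
  structure(max(te, 0), degenerate = FALSE)
}

#' Pairwise transfer-entropy matrix
#'
#' @param bursts a [binarize_bursts()] result (>= 2 channels on one grid).
#' @param exclude_pairs optional data.frame/matrix of label pairs to skip
#'   (e.g. bipolar derivations sharing a physical contact); both directions
#'   are excluded and left NA.
#' @param k history length passed to [transfer_entropy()].
#' @param min_triplets minimum valid triplets per pair.
#' @return matrix of TE values (bits), NA on the diagonal and for excluded
#'   or data-starved pairs.
#' @export
ec_matrix <- function(bursts, exclude_pairs = NULL, k = 1L,
                      min_triplets = 50L) {
  bits <- bursts$bits
  n_ch <- nrow(bits)
  if (n_ch < 2L) stop("need at least two channels")
  excl <- matrix(FALSE, n_ch, n_ch)
  if (!is.null(exclude_pairs)) {
    ep <- as.matrix(exclude_pairs)
    for (r in seq_len(nrow(ep))) {
      i <- match(ep[r, 1], bursts$labels); j <- match(ep[r, 2], bursts$labels)
      if (is.na(i) || is.na(j)) next
      excl[i, j] <- excl[j, i] <- TRUE
    }
  }
  te <- matrix(NA_real_, n_ch, n_ch, dimnames = list(bursts$labels,
                                                     bursts$labels))
  for (i in seq_len(n_ch)) for (j in seq_len(n_ch)) {
    if (i == j || excl[i, j]) next
    te[i, j] <- tryCatch(
      as.numeric(transfer_entropy(bits[i, ], bits[j, ], k = k,
                                  min_triplets = min_triplets)),
      error = function(e) NA_real_)
  }
  structure(list(te = te, band = bursts$band, labels = bursts$labels),
            class = "sevo_ec")
}

#' Per-channel effective connectivity summaries
#'
#' Efferent: mean outgoing TE; afferent: mean incoming TE; combined: mean of
#' all 2(n-1) connections of the channel, so combined = (efferent +
#' afferent) / 2 when no pair is missing.
#'
#' @param m a [ec_matrix()] result.
#' @param mode "combined", "efferent" or "afferent".
#' @return named numeric vector, one value per channel.
#' @export
channel_ec <- function(m, mode = c("combined", "efferent", "afferent")) {
  mode <- match.arg(mode)
  te <- m$te
  if (nrow(te) < 2L) stop("need at least two channels")
  eff <- rowMeans(te, na.rm = TRUE)
  aff <- colMeans(te, na.rm = TRUE)
  out <- switch(mode,
                efferent = eff,
                afferent = aff,
                combined = vapply(seq_len(nrow(te)), function(i)
                  mean(c(te[i, ], te[, i]), na.rm = TRUE), 0))
  names(out) <- m$labels
  out[!is.finite(out)] <- NA_real_
  out
}
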