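# Synthetic multi-patient ECoG cohort generator with known phase-amplitude
# coupling depth, directed burst propagation and stage/class gain structure.

.stage_class_table <- function(iso, sws, s2, s3, s4) {
  m <- rbind(Iso = iso, SWS = sws, Sev2 = s2, Sev3 = s3, Sev4 = s4)
  colnames(m) <- c("normative", "epileptogenic")
  m
}

#' Simulation configuration
#'
#' Defaults encode the study conditions: 1000 Hz sampling, 5-min stages at
#' isoflurane then sevoflurane 2/3/4 vol% (plus slow-wave sleep for
#' two-stage patients), 19 patients, roughly 30% of sites epileptogenic,
#' coupling depth and burst rates rising with sevoflurane concentration,
#' and the double dissociation: epileptogenic channels carry higher PAC
#' depth and HFO burst transmission but lower delta burst transmission.
#' Control stages (Iso, SWS) are class-independent so z-score baselines are
#' well defined. Effect magnitudes are free parameters of the generator
#' (documented in the methods vignette); the rates/probabilities below are
#' the package defaults.
#'
#' @param n_patients number of patients.
#' @param n_channels bipolar channels per patient (even; labels pair
#'   consecutive contacts).
#' @param frac_epileptogenic fraction of channels that are resected
#'   (epileptogenic; cohort restricted to seizure-free outcomes).
#' @param fs sampling rate (Hz).
#' @param stage_schedule named numeric vector of stage durations in seconds,
#'   in recording order (Iso, Sev2, Sev3, Sev4).
#' @param sws_duration_s SWS block length for two-stage patients (0 = none).
#' @param frac_two_stage fraction of patients with an SWS block.
#' @param delta_freq_range,hfo_freq_range band limits (Hz).
#' @param kappa 5x2 matrix (stage x class) of PAC coupling depth in [0, 1].
#' @param hfo_burst_rate,delta_burst_rate 5x2 matrices of burst rates (/s).
#' @param p_propagate_hfo,p_propagate_delta 5x2 matrices of per-edge burst
#'   transmission probabilities; an edge uses the "epileptogenic" column
#'   when either endpoint is epileptogenic.
#' @param edge_density fraction of ordered channel pairs with a true edge.
#' @param delta_amp delta oscillation amplitude (uV).
#' @param delta_burst_gain fractional delta amplitude gain during a slow-wave
#'   burst.
#' @param hfo_burst_amp HFO burst envelope SD at unit coupling factor (uV).
#' @param delta_phase_diffusion Brownian phase-diffusion rate of the delta
#'   rhythm (rad^2/s); gives the carrier a physiological linewidth
#'   (~0.1 Hz at the default 0.5).
#' @param noise_sigma 1/f^2 background SD (uV).
#' @param line_noise_amp 60 Hz line amplitude (uV).
#' @param artifact_rate artifact events per minute (applied by
#'   [inject_artifacts()]).
#' @param seed integer RNG seed.
#' @return validated list of class `sevo_simconfig`.
#' @export
sim_config <- function(n_patients = 19L, n_channels = 16L,
                       frac_epileptogenic = 0.3, fs = 1000,
                       stage_schedule = c(Iso = 300, Sev2 = 300,
                                          Sev3 = 300, Sev4 = 300),
                       sws_duration_s = 300, frac_two_stage = 11 / 19,
                       delta_freq_range = c(3, 4),
                       hfo_freq_range = c(80, 300),
                       kappa = .stage_class_table(
                         c(0.10, 0.10), c(0.10, 0.10), c(0.20, 0.35),
                         c(0.30, 0.55), c(0.40, 0.70)),
                       hfo_burst_rate = .stage_class_table(
                         c(1.0, 1.0), c(1.0, 1.0), c(1.4, 1.8),
                         c(1.8, 2.4), c(2.2, 3.0)),
                       delta_burst_rate = .stage_class_table(
                         c(0.15, 0.15), c(0.15, 0.15), c(0.20, 0.15),
                         c(0.25, 0.12), c(0.30, 0.12)),
                       p_propagate_hfo = .stage_class_table(
                         c(0.15, 0.15), c(0.15, 0.15), c(0.30, 0.50),
                         c(0.40, 0.65), c(0.50, 0.80)),
                       p_propagate_delta = .stage_class_table(
                         c(0.40, 0.40), c(0.40, 0.40), c(0.50, 0.30),
                         c(0.60, 0.20), c(0.70, 0.15)),
                       edge_density = 0.2, delta_amp = 50,
                       delta_burst_gain = 1.0, hfo_burst_amp = 10,
                       delta_phase_diffusion = 0.5,
                       noise_sigma = 15, line_noise_amp = 0,
                       artifact_rate = 0, seed = 1L) {
  cfg <- as.list(environment())
  for (nm in c("kappa", "p_propagate_hfo", "p_propagate_delta"))
    if (any(cfg[[nm]] < 0 | cfg[[nm]] > 1) || any(!is.finite(cfg[[nm]])))
      stop(nm, " entries must lie in [0, 1]")
  if (any(hfo_burst_rate < 0) || any(delta_burst_rate < 0))
    stop("burst rates must be non-negative")
  if (any(stage_schedule <= 0)) stop("degenerate schedule: zero-length stage")
  if (frac_epileptogenic < 0 || frac_epileptogenic > 1)
    stop("frac_epileptogenic must lie in [0, 1]")
  sev <- c("Sev2", "Sev3", "Sev4")
  if (any(kappa[sev, "epileptogenic"] < kappa[sev, "normative"]) ||
      any(p_propagate_hfo[sev, "epileptogenic"] <
            p_propagate_hfo[sev, "normative"]) ||
      any(p_propagate_delta[sev, "epileptogenic"] >
            p_propagate_delta[sev, "normative"]))
    stop("class tables must encode the double dissociation: epileptogenic ",
         "kappa and HFO transmission >= normative, delta transmission <=")
  structure(cfg, class = "sevo_simconfig")
}

#' Generate a synthetic ECoG cohort
#'
#' One recording per patient on a bipolar-equivalent montage. Each channel
#' carries: Brownian (1/f^2) background noise; a continuous 3-4 Hz delta
#' oscillation at a channel-specific frequency and phase, with slow-wave
#' burst excursions; and 50-150 ms broadband HFO bursts whose envelope is
#' band-limited 80-300 Hz noise scaled by 1 + kappa * cos(delta phase).
#' Bursts propagate one hop along the true directed edges at a one-bin lag
#' (75 ms for HFO, 2 s for delta) with the stage/class transmission
#' probability. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `recordings` (list of [recording()]) and `truth`
#'   (class `sevo_simtruth`: channel classes, per-stage kappa, edge list
#'   with lags, the gain tables and the seed).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sevo_simconfig"))
  set.seed(cfg$seed)
  fs <- cfg$fs
  recs <- vector("list", cfg$n_patients)
  classes <- list(); edges <- list()
  two_stage <- rep(FALSE, cfg$n_patients)
  if (cfg$sws_duration_s > 0 && cfg$frac_two_stage > 0)
    two_stage[seq_len(round(cfg$frac_two_stage * cfg$n_patients))] <- TRUE
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    sched <- cfg$stage_schedule
    if (two_stage[p]) sched <- c(sched, SWS = cfg$sws_duration_s)
    gen <- .simulate_patient(cfg, pid, sched, two_stage[p])
    recs[[p]] <- gen$rec
    classes[[p]] <- gen$classes
    edges[[p]] <- gen$edges
  }
  truth <- structure(list(
    classes = do.call(rbind, classes),
    edges = do.call(rbind, edges),
    kappa = cfg$kappa, hfo_burst_rate = cfg$hfo_burst_rate,
    delta_burst_rate = cfg$delta_burst_rate,
    p_propagate_hfo = cfg$p_propagate_hfo,
    p_propagate_delta = cfg$p_propagate_delta,
    seed = cfg$seed), class = "sevo_simtruth")
  list(recordings = recs, truth = truth)
}

.simulate_patient <- function(cfg, pid, sched, is_two_stage) {
  fs <- cfg$fs
  n_ch <- cfg$n_channels
  labels <- paste0(sprintf("%s_E%02d", pid, seq(1, 2 * n_ch, by = 2)), "-",
                   sprintf("E%02d", seq(2, 2 * n_ch, by = 2)))
  n_epi <- round(cfg$frac_epileptogenic * n_ch)
  epi <- rep(FALSE, n_ch)
  if (n_epi > 0) epi[sample.int(n_ch, n_epi)] <- TRUE
  soz <- epi & (stats::runif(n_ch) < 0.4)
  age <- sample(4:18, 1L)
  channels <- data.frame(
    label = labels, patient_id = pid, is_resected = epi, is_soz = soz,
    is_lesional = FALSE, has_ied = FALSE,
    surgery_stages = if (is_two_stage) 2L else 1L,
    hemisphere = rep(c("L", "R"), length.out = n_ch),
    age_years = age, sex = sample(c("M", "F"), 1L),
    n_asm = sample(0:5, 1L),
    daily_seizures = stats::runif(1) < 0.3)

  ends <- cumsum(sched) * fs
  starts <- c(0, ends[-length(ends)])
  ann <- data.frame(stage = names(sched), start_sample = as.integer(starts),
                    end_sample = as.integer(ends))
  n <- as.integer(ends[length(ends)])

  # true directed edges among ordered pairs
  pairs <- expand.grid(src = seq_len(n_ch), dst = seq_len(n_ch))
  pairs <- pairs[pairs$src != pairs$dst, ]
  n_edges <- round(cfg$edge_density * nrow(pairs))
  edge_idx <- if (n_edges > 0) sample.int(nrow(pairs), n_edges) else integer()
  ed <- pairs[edge_idx, , drop = FALSE]

  f_delta <- stats::runif(n_ch, cfg$delta_freq_range[1], cfg$delta_freq_range[2])
  phi_ch <- stats::runif(n_ch, 0, 2 * pi)
  lag_hfo <- 6 / cfg$hfo_freq_range[1]          # one HFO bin
  lag_delta <- 6 / cfg$delta_freq_range[1]      # one delta bin

  cls <- ifelse(epi, "epileptogenic", "normative")
  spont <- function(rate_tab, ch) {
    # spontaneous event times for channel ch over all stage segments
    unlist(lapply(seq_len(nrow(ann)), function(b) {
      stg <- ann$stage[b]
      rate <- rate_tab[stg, cls[ch]]
      dur <- (ann$end_sample[b] - ann$start_sample[b]) / fs
      k <- stats::rpois(1L, rate * dur)
      sort(stats::runif(k, ann$start_sample[b] / fs, ann$end_sample[b] / fs))
    }))
  }
  propagate <- function(events_by_ch, p_tab, lag_s) {
    out <- events_by_ch
    if (nrow(ed) == 0L) return(out)
    for (r in seq_len(nrow(ed))) {
      i <- ed$src[r]; j <- ed$dst[r]
      ecls <- if (epi[i] || epi[j]) "epileptogenic" else "normative"
      ev <- events_by_ch[[i]]
      if (!length(ev)) next
      stg <- ann$stage[findInterval(ev * fs, ann$start_sample)]
      keep <- stats::runif(length(ev)) < p_tab[cbind(stg, ecls)]
      out[[j]] <- c(out[[j]], ev[keep] + lag_s)
    }
    lapply(out, function(v) sort(v[v * fs < n - fs]))
  }
  hfo_ev <- propagate(lapply(seq_len(n_ch), spont, rate_tab = cfg$hfo_burst_rate),
                      cfg$p_propagate_hfo, lag_hfo)
  del_ev <- propagate(lapply(seq_len(n_ch), spont, rate_tab = cfg$delta_burst_rate),
                      cfg$p_propagate_delta, lag_delta)

  tt <- seq_len(n) / fs
  stage_of_sample <- ann$stage[findInterval(seq_len(n) - 1L, ann$start_sample)]
  samples <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    bg <- cumsum(stats::rnorm(n))
    bg <- (bg - mean(bg)) / stats::sd(bg) * cfg$noise_sigma
    # Brownian phase diffusion gives the delta rhythm a physiological
    # linewidth (a zero-linewidth carrier would make circular-shift
    # surrogates blind to genuine coupling)
    drift <- cumsum(stats::rnorm(n, 0,
                                 sqrt(cfg$delta_phase_diffusion / fs)))
    phase <- 2 * pi * f_delta[ch] * tt + phi_ch[ch] + drift
    denv <- .event_envelope(del_ev[[ch]], rep(2.0, length(del_ev[[ch]])), n, fs)
    x <- bg + cfg$delta_amp * (1 + cfg$delta_burst_gain * denv) * sin(phase)
    if (length(hfo_ev[[ch]])) {
      ev_idx <- pmin(pmax(as.integer(round(hfo_ev[[ch]] * fs)), 1L), n)
      kap <- cfg$kappa[cbind(stage_of_sample[ev_idx], cls[ch])]
      amp <- 1 + kap * cos(phase[ev_idx])
      durs <- stats::runif(length(hfo_ev[[ch]]), 0.05, 0.15)
      henv <- .event_envelope(hfo_ev[[ch]], durs, n, fs, amps = amp)
      x <- x + cfg$hfo_burst_amp * henv * .bandlimited_noise(n, fs,
                                                             cfg$hfo_freq_range)
    }
    if (cfg$line_noise_amp > 0)
      x <- x + cfg$line_noise_amp * sin(2 * pi * 60 * tt)
    samples[ch, ] <- x
  }
  rec <- recording(samples, fs, channels, ann, montage = "bipolar")
  list(rec = rec,
       classes = data.frame(patient_id = pid, label = labels, class = cls,
                            stringsAsFactors = FALSE),
       edges = if (nrow(ed)) data.frame(patient_id = pid,
                                        src = labels[ed$src],
                                        dst = labels[ed$dst],
                                        lag_bins = 1L)
               else NULL)
}

# sum of Hann windows centred at event times (seconds), optional amplitudes
.event_envelope <- function(times, durs, n, fs, amps = NULL) {
  env <- numeric(n)
  if (!length(times)) return(env)
  if (is.null(amps)) amps <- rep(1, length(times))
  for (e in seq_along(times)) {
    half <- round(durs[e] / 2 * fs)
    c0 <- round(times[e] * fs)
    idx <- max(1L, c0 - half):min(n, c0 + half)
    w <- 0.5 * (1 + cos(pi * (idx - c0) / max(half, 1L)))
    env[idx] <- env[idx] + amps[e] * w
  }
  env
}

# unit-SD band-limited white noise via frequency-domain masking
.bandlimited_noise <- function(n, fs, band) {
  nfft <- 2L^as.integer(ceiling(log2(n)))
  X <- stats::fft(stats::rnorm(nfft))
  f <- (seq_len(nfft) - 1L) * fs / nfft
  f <- pmin(f, fs - f)
  X[f < band[1] | f > band[2]] <- 0
  x <- Re(stats::fft(X, inverse = TRUE) / nfft)[seq_len(n)]
  x / stats::sd(x)
}

#' Inject artifacts into a recording
#'
#' Adds Poisson-timed high-amplitude transients (10x the per-channel SD,
#' 100-300 ms) summed with a 60 Hz sinusoid inside each event window, on
#' every channel, and returns the ground-truth mask.
#'
#' @param rec a [recording()].
#' @param rate events per minute (>= 0).
#' @param seed RNG seed.
#' @return list with `rec` (corrupted recording) and `mask`
#'   ([artifact_mask()] covering the events).
#' @export
inject_artifacts <- function(rec, rate, seed = 1L) {
  stopifnot(rate >= 0)
  n <- ncol(rec$samples)
  bad <- matrix(FALSE, nrow(rec$samples), n)
  if (rate == 0)
    return(list(rec = rec, mask = artifact_mask(bad)))
  set.seed(seed)
  fs <- rec$fs
  out <- rec
  for (ch in seq_len(nrow(rec$samples))) {
    sd_ch <- stats::sd(rec$samples[ch, ])
    k <- stats::rpois(1L, rate * n / fs / 60)
    if (k == 0) next
    centers <- sort(stats::runif(k, 0, n / fs))
    for (tc in centers) {
      half <- round(stats::runif(1, 0.05, 0.15) * fs)
      c0 <- max(1L, min(n, round(tc * fs)))
      idx <- max(1L, c0 - half):min(n, c0 + half)
      w <- 0.5 * (1 + cos(pi * (idx - c0) / max(half, 1L)))
      out$samples[ch, idx] <- out$samples[ch, idx] +
        10 * sd_ch * w + 10 * sd_ch * sin(2 * pi * 60 * idx / fs) * w
      bad[ch, idx] <- TRUE
    }
  }
  list(rec = out, mask = artifact_mask(bad))
}

#' Export / load generator ground truth as JSON
#'
#' `load_truth(export_truth(x, path))` reproduces `x`.
#'
#' @param truth a `sevo_simtruth` from [generate_cohort()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sevo_simtruth"))
  if (any(!is.finite(truth$kappa)))
    stop("non-finite kappa in truth; refusing to write")
  obj <- truth
  class(obj) <- NULL
  for (nm in c("kappa", "hfo_burst_rate", "delta_burst_rate",
               "p_propagate_hfo", "p_propagate_delta")) {
    obj[[nm]] <- list(stages = rownames(truth[[nm]]),
                      classes = colnames(truth[[nm]]),
                      values = unclass(truth[[nm]]))
    dimnames(obj[[nm]]$values) <- NULL
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname export_truth
#' @export
load_truth <- function(path) {
  obj <- jsonlite::fromJSON(path)
  for (nm in c("kappa", "hfo_burst_rate", "delta_burst_rate",
               "p_propagate_hfo", "p_propagate_delta")) {
    m <- obj[[nm]]$values
    dimnames(m) <- list(obj[[nm]]$stages, obj[[nm]]$classes)
    obj[[nm]] <- m
  }
  obj$classes <- as.data.frame(obj$classes)
  obj$edges <- as.data.frame(obj$edges)
  obj$seed <- as.integer(obj$seed)
  structure(obj, class = "sevo_simtruth")
}
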