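# Shared fixtures: all built in code at test time.

make_channels <- function(n, pid = "P01", labels = NULL) {
  if (is.null(labels)) labels <- sprintf("CH%02d", seq_len(n))
  data.frame(label = labels, patient_id = pid, is_resected = FALSE,
             is_soz = FALSE, is_lesional = FALSE, has_ied = FALSE,
             surgery_stages = 1L, hemisphere = "L", age_years = 10,
             sex = "M", n_asm = 1L, daily_seizures = FALSE)
}

# single-channel bipolar recording holding an arbitrary signal
signal_recording <- function(x, fs = 1000, stages = NULL) {
  n <- length(x)
  if (is.null(stages))
    stages <- data.frame(stage = "Iso", start_sample = 0L, end_sample = n)
  recording(matrix(x, 1L), fs, make_channels(1L, labels = "A-B"),
            stages, montage = "bipolar")
}

# delta carrier plus kappa-coupled HFO tone; phase of the carrier's analytic
# signal is (2 pi f t - pi/2), so couple relative to that convention
coupled_signal <- function(dur_s, fs = 1000, kappa = 0.4, phi0 = 0,
                           f_delta = 3.5, f_hfo = 150, delta_amp = 20,
                           noise_sd = 0) {
  t <- seq_len(dur_s * fs) / fs
  phase <- 2 * pi * f_delta * t - pi / 2
  x <- delta_amp * sin(2 * pi * f_delta * t) +
    (1 + kappa * cos(phase - phi0)) * sin(2 * pi * f_hfo * t)
  if (noise_sd > 0) x <- x + rnorm(length(t), sd = noise_sd)
  x
}

# an amplitude series pre-marked as z-scored, for binarization fixtures
zscored_stub <- function(z_matrix, band, fs = 1000,
                         labels = sprintf("C%d-D%d", seq_len(nrow(z_matrix)),
                                          seq_len(nrow(z_matrix)))) {
  structure(list(values = z_matrix, band = band, fs = fs, labels = labels,
                 grid = NULL, zscored_to = "Iso",
                 control_mean = rep(0, nrow(z_matrix)),
                 control_sd = rep(1, nrow(z_matrix))),
            class = "sevo_amp")
}

# exhaustive plug-in transfer-entropy oracle (k = 1): explicit probability
# tables, independent of the package implementation
te_oracle <- function(x, y) {
  n <- length(x)
  te <- 0
  p_jxy <- array(0, c(2, 2, 2))   # [y_next, y, x]
  for (t in 1:(n - 1))
    p_jxy[y[t + 1] + 1, y[t] + 1, x[t] + 1] <-
      p_jxy[y[t + 1] + 1, y[t] + 1, x[t] + 1] + 1
  p_jxy <- p_jxy / (n - 1)
  for (yn in 1:2) for (yy in 1:2) for (xx in 1:2) {
    pj <- p_jxy[yn, yy, xx]
    if (pj == 0) next
    p_yx <- sum(p_jxy[, yy, xx])
    p_y <- sum(p_jxy[, yy, ])
    p_yny <- sum(p_jxy[yn, yy, ])
    te <- te + pj * log2((pj / p_yx) / (p_yny / p_y))
  }
  te
}

# direct biomarker table with a known linear stage effect (no signal chain)
linear_stage_table <- function(n_patients, n_channels, slope,
                               noise_sd = 0, patient_sd = 0.02,
                               biomarker = "MI", seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_patients)) {
    off <- rnorm(1, sd = patient_sd)
    for (code in 0:9) {
      stage <- if (code == 0) "Iso" else c("Sev2", "Sev3",
                                           "Sev4")[(code - 1) %/% 3 + 1]
      ep <- if (code == 0) 1L else (code - 1L) %% 3L + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("P%02d", p),
        channel = sprintf("P%02d_C%02d", p, seq_len(n_channels)),
        stage = stage, epoch_index = ep, biomarker = biomarker,
        value = 0.1 + off + slope * code +
          rnorm(n_channels, sd = noise_sd),
        normative = TRUE, is_resected = FALSE, is_soz = FALSE,
        is_lesional = FALSE, has_ied = FALSE,
        age_years = sample(4:18, 1), sex = sample(c("M", "F"), 1),
        hemisphere = "L", n_asm = sample(0:3, 1),
        daily_seizures = FALSE, surgery_stages = 1L)
    }
  }
  do.call(rbind, rows)
}

# small end-to-end cohort configuration used by the property tests
small_cohort_cfg <- function(seed, ...) {
  sim_config(n_patients = 4L, n_channels = 8L, fs = 1000,
             stage_schedule = c(Iso = 90, Sev2 = 90, Sev3 = 90, Sev4 = 90),
             sws_duration_s = 0, frac_two_stage = 0, seed = seed, ...)
}

quiet_fit <- function(expr) suppressWarnings(suppressMessages(expr))
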