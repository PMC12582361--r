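# Orchestration: preprocessing -> spectral amplitude -> PAC / EC ->
# biomarker table -> mixed models -> hotspots, with a run manifest.

#' Standard preprocessing chain
#'
#' Band-pass (0.016-300 Hz), 60 Hz notch, automated artifact mask.
#'
#' @param rec a [recording()].
#' @param lo,hi band-pass edges (Hz).
#' @param notch_f0 line frequency (Hz).
#' @param z_amp,min_gap artifact-mask parameters (see
#'   [auto_artifact_mask()]).
#' @return filtered [recording()] with mask attached.
#' @export
preprocess_recording <- function(rec, lo = 0.016, hi = 300, notch_f0 = 60,
                                 z_amp = 6, min_gap = 0.5) {
  rec <- bandpass(rec, lo = lo, hi = hi)
  rec <- notch(rec, f0 = notch_f0)
  set_mask(rec, auto_artifact_mask(rec, z_amp = z_amp, min_gap = min_gap))
}

#' Bipolar derivations sharing a physical contact
#'
#' Parses "anode-cathode" labels and returns label pairs of channels that
#' share an electrode contact; these are excluded from the EC matrix to
#' guard against montage-induced spurious coupling.
#'
#' @param labels bipolar channel labels.
#' @return data.frame of label pairs (possibly empty).
#' @export
shared_contact_pairs <- function(labels) {
  contacts <- strsplit(labels, "-", fixed = TRUE)
  out <- list()
  for (i in seq_along(labels)) for (j in seq_along(labels)) {
    if (j <= i) next
    if (length(intersect(contacts[[i]], contacts[[j]])))
      out[[length(out) + 1L]] <- data.frame(a = labels[i], b = labels[j])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(a = character(), b = character())
}

#' Compute the biomarker table for one recording
#'
#' For every analysis epoch: the modulation index per channel from the raw
#' bipolar trace, and combined / efferent / afferent transfer-entropy EC per
#' channel from the binarized z-scored spectral amplitude, in the HFO and
#' delta bands. Delta EC uses a lower triplet floor because a 1-min epoch
#' holds only 29 two-second delta bins.
#'
#' @param rec preprocessed [recording()] (see [preprocess_recording()]).
#' @param control z-score reference stage, "Iso" or "SWS".
#' @param threshold_z,min_cycles,bin_cycles binarization parameters.
#' @param k TE history length (bins).
#' @param min_triplets_hfo,min_triplets_delta TE triplet floors per band.
#' @param exclude_shared_contacts drop bipolar-neighbour pairs from EC.
#' @param epoch_s,n_analysis epoch segmentation parameters.
#' @return long data.frame: patient_id, channel, stage, epoch_index,
#'   biomarker (MI, HFO_EC, DELTA_EC and the afferent/efferent splits),
#'   value, normative and the channel covariates.
#' @export
compute_biomarkers <- function(rec, control = c("Iso", "SWS"),
                               threshold_z = 2, min_cycles = 3,
                               bin_cycles = 6, k = 1L,
                               min_triplets_hfo = 50L,
                               min_triplets_delta = 25L,
                               exclude_shared_contacts = TRUE,
                               epoch_s = 60, n_analysis = 3) {
  control <- match.arg(control)
  if (!control %in% rec$annotations$stage)
    stop("control stage ", control, " absent from recording")
  segs <- segment_stages(rec, epoch_s = epoch_s, n_analysis = n_analysis)
  amp_d <- wavelet_amplitude(rec, "delta")
  amp_h <- wavelet_amplitude(rec, "hfo")
  zd <- zscore_to_control(amp_d, segs, control)
  zh <- zscore_to_control(amp_h, segs, control)
  excl <- if (exclude_shared_contacts) shared_contact_pairs(rec$channels$label)
          else NULL
  usable <- is.finite(zh$control_sd) & is.finite(zd$control_sd)
  if (!is.null(rec$mask)) usable <- usable & !rec$mask$reject

  ep <- segs[segs$is_analysis &
               segs$stage %in% c(control, SEV_STAGES), , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(ep))) {
    s0 <- ep$start_sample[r]; s1 <- ep$end_sample[r]
    mi <- rep(NA_real_, nrow(rec$samples))
    for (ch in which(usable)) {
      msk <- if (is.null(rec$mask)) NULL else rec$mask$bad[ch, (s0 + 1L):s1]
      mi[ch] <- tryCatch(
        modulation_index(rec$samples[ch, (s0 + 1L):s1], rec$fs,
                         mask = msk)$mi,
        error = function(e) NA_real_)
    }
    vals <- list(MI = mi)
    for (band in c("hfo", "delta")) {
      zz <- if (band == "hfo") zh else zd
      floorn <- if (band == "hfo") min_triplets_hfo else min_triplets_delta
      bb <- binarize_bursts(zz, s0, s1, threshold = threshold_z,
                            min_cycles = min_cycles, bin_cycles = bin_cycles)
      bb$bits[!usable, ] <- NA_integer_
      m <- ec_matrix(bb, exclude_pairs = excl, k = k, min_triplets = floorn)
      pre <- if (band == "hfo") "HFO_EC" else "DELTA_EC"
      vals[[pre]] <- channel_ec(m, "combined")
      vals[[paste0(pre, "_EFF")]] <- channel_ec(m, "efferent")
      vals[[paste0(pre, "_AFF")]] <- channel_ec(m, "afferent")
    }
    for (bm in names(vals)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rec$channels$patient_id,
        channel = rec$channels$label,
        stage = ep$stage[r], epoch_index = ep$epoch_index[r],
        biomarker = bm, value = as.numeric(vals[[bm]]),
        normative = is_normative(rec$channels),
        is_resected = rec$channels$is_resected,
        is_soz = rec$channels$is_soz,
        is_lesional = rec$channels$is_lesional,
        has_ied = rec$channels$has_ied,
        age_years = rec$channels$age_years, sex = rec$channels$sex,
        hemisphere = rec$channels$hemisphere,
        n_asm = rec$channels$n_asm,
        daily_seizures = rec$channels$daily_seizures,
        surgery_stages = rec$channels$surgery_stages)
    }
  }
  out <- do.call(rbind, rows)
  out[is.finite(out$value) | is.na(out$value), , drop = FALSE]
}

#' Biomarker table for a cohort
#'
#' Applies [preprocess_recording()] (unless `preprocessed`) and
#' [compute_biomarkers()] per patient; patients lacking the control stage
#' (e.g. one-stage patients under the SWS control) are skipped with a
#' message.
#'
#' @param recordings list of [recording()] objects.
#' @param control "Iso" or "SWS".
#' @param preprocessed set TRUE when recordings are already filtered/masked.
#' @param ... passed to [compute_biomarkers()].
#' @return row-bound biomarker table.
#' @export
cohort_biomarkers <- function(recordings, control = c("Iso", "SWS"),
                              preprocessed = FALSE, ...) {
  control <- match.arg(control)
  tabs <- list()
  for (rec in recordings) {
    if (!control %in% rec$annotations$stage) {
      message("patient ", rec$channels$patient_id[1L],
              " lacks a ", control, " stage; skipped")
      next
    }
    if (!preprocessed) rec <- preprocess_recording(rec)
    tabs[[length(tabs) + 1L]] <- compute_biomarkers(rec, control, ...)
  }
  if (!length(tabs)) stop("no patient provides the ", control, " control")
  do.call(rbind, tabs)
}

#' Full-pipeline run configuration
#'
#' Exactly one of `sim` (a [sim_config()]) or `input` (a data.frame/list of
#' `signal`, `meta`, `annot` path triplets) must be given. `seed` is the
#' root seed for all randomness; it overrides `sim$seed`.
#'
#' @param sim optional [sim_config()].
#' @param input optional ingest paths.
#' @param control "Iso" or "SWS".
#' @param out_dir artifact directory.
#' @param seed root RNG seed.
#' @param glmm_stages stages for the epileptogenicity models.
#' @return list of class `sevo_runconfig`.
#' @export
run_config <- function(sim = NULL, input = NULL, control = c("Iso", "SWS"),
                       out_dir = "sevopact_run", seed = 1L,
                       glmm_stages = c("Sev2", "Sev3", "Sev4")) {
  control <- match.arg(control)
  if (is.null(sim) == is.null(input))
    stop("exactly one of 'sim' and 'input' must be supplied")
  if (!is.null(sim)) stopifnot(inherits(sim, "sevo_simconfig"))
  structure(list(sim = sim, input = input, control = control,
                 out_dir = out_dir, seed = as.integer(seed),
                 glmm_stages = glmm_stages),
            class = "sevo_runconfig")
}

#' Run the full biomarker pipeline
#'
#' Simulate (or ingest) -> preprocess -> spectral -> PAC / EC -> biomarker
#' table -> stage LMMs, epileptogenicity GLMMs, Cohen's d -> hotspot edge
#' lists, writing CSV/JSON artifacts plus a manifest to `cfg$out_dir`.
#' Deterministic for a fixed seed. A failing stage raises an error naming
#' it; artifacts written earlier are left intact.
#'
#' @param cfg a [run_config()].
#' @return invisible list with the table, model results, hotspots and
#'   output paths.
#' @export
run_full <- function(cfg) {
  stopifnot(inherits(cfg, "sevo_runconfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  recs <- step("ingest", {
    if (!is.null(cfg$sim)) {
      sim <- cfg$sim; sim$seed <- cfg$seed
      generate_cohort(sim)$recordings
    } else {
      inp <- as.data.frame(cfg$input)
      lapply(seq_len(nrow(inp)), function(i)
        load_recording(inp$signal[i], inp$meta[i], inp$annot[i]))
    }
  })
  table <- step("biomarkers", cohort_biomarkers(recs, cfg$control))
  tab_path <- file.path(cfg$out_dir, "biomarker_table.csv")
  utils::write.csv(table, tab_path, row.names = FALSE)

  models <- step("stats", {
    res <- list()
    for (bm in c("MI", "HFO_EC", "DELTA_EC")) {
      res[[paste0("lmm_", bm)]] <- fit_stage_lmm(table, bm, cfg$control)
      for (stg in cfg$glmm_stages)
        res[[paste0("glmm_", bm, "_", stg)]] <-
          tryCatch(fit_epi_glmm(table, bm, stg),
                   error = function(e) NULL)
    }
    res
  })
  tls <- Filter(Negate(is.null), lapply(names(models), function(nm) {
    m <- models[[nm]]
    if (is.null(m) || is.null(m$terms)) return(NULL)
    cbind(model = nm, m$terms)
  }))
  cols <- Reduce(union, lapply(tls, names))
  mdl <- do.call(rbind, lapply(tls, function(d) {
    d[setdiff(cols, names(d))] <- NA
    d[cols]
  }))
  utils::write.csv(mdl, file.path(cfg$out_dir, "model_results.csv"),
                   row.names = FALSE)

  hotspots <- step("hotspots", {
    ref_stage <- if ("SWS" %in% table$stage) "SWS" else cfg$control
    out <- list()
    for (bm in c("MI", "HFO_EC")) {
      v <- table$value[table$biomarker == bm & table$stage == ref_stage &
                         table$normative & is.finite(table$value)]
      if (length(v) < 2L || stats::sd(v) == 0) next
      for (stg in cfg$glmm_stages) {
        d <- table[table$biomarker == bm & table$stage == stg &
                     table$normative & is.finite(table$value), , drop = FALSE]
        if (!nrow(d)) next
        sv <- tapply(d$value, d$channel, mean)
        hs <- select_hotspots(sv, mean(v), stats::sd(v), stage = stg,
                              biomarker = bm)
        suppressWarnings(export_edges(
          hs, file.path(cfg$out_dir,
                        sprintf("hotspot_edges_%s_%s.csv", bm, stg))))
        out[[paste(bm, stg, sep = "_")]] <- hs
      }
    }
    out
  })
  manifest <- list(
    package = "sevopact",
    version = as.character(utils::packageVersion("sevopact")),
    seed = cfg$seed, control = cfg$control,
    mode = if (is.null(cfg$sim)) "ingest" else "simulate",
    table_md5 = unname(tools::md5sum(tab_path)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(table = table, models = models, hotspots = hotspots,
                 out_dir = cfg$out_dir))
}
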