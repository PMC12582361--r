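# Anaesthetic-stage segmentation into 1-min epochs and ordinal stage coding.

#' Split annotated stages into 1-min epochs
#'
#' Each annotated stage block is cut into whole epochs of `epoch_s` seconds
#' (a truncated tail is dropped). For each sevoflurane stage the first
#' `n_analysis` artifact-free epochs are flagged as analysis epochs; control
#' stages (Iso, SWS) keep their full span for z-score baselines and likewise
#' get up to `n_analysis` analysis epochs for biomarker rows. An epoch counts
#' artifact-free when the mean masked fraction across non-rejected channels
#' is at most `max_masked_frac`.
#'
#' @param rec a [recording()] with stage annotations (and optionally a mask).
#' @param epoch_s epoch length in seconds (default 60).
#' @param n_analysis analysis epochs per stage (default 3).
#' @param max_masked_frac maximum tolerated masked fraction per epoch.
#' @return data.frame with `stage`, `epoch_index`, `start_sample`,
#'   `end_sample` (0-based half-open), `artifact_free`, `is_analysis`.
#' @export
segment_stages <- function(rec, epoch_s = 60, n_analysis = 3,
                           max_masked_frac = 0.25) {
  ann <- rec$annotations
  if (nrow(ann) == 0L) stop("recording has no stage annotations")
  len <- as.integer(round(epoch_s * rec$fs))
  rows <- list()
  for (stg in unique(ann$stage)) {
    blocks <- ann[ann$stage == stg, , drop = FALSE]
    k <- 0L
    for (b in seq_len(nrow(blocks))) {
      n_ep <- (blocks$end_sample[b] - blocks$start_sample[b]) %/% len
      for (e in seq_len(n_ep)) {
        k <- k + 1L
        s0 <- blocks$start_sample[b] + (e - 1L) * len
        rows[[length(rows) + 1L]] <- data.frame(
          stage = stg, epoch_index = k, start_sample = s0,
          end_sample = s0 + len)
      }
    }
  }
  ep <- do.call(rbind, rows)
  ep$artifact_free <- vapply(seq_len(nrow(ep)), function(i) {
    .epoch_masked_frac(rec, ep$start_sample[i], ep$end_sample[i]) <= max_masked_frac
  }, TRUE)
  ep$is_analysis <- FALSE
  for (stg in unique(ep$stage)) {
    sel <- which(ep$stage == stg & ep$artifact_free)
    if (!length(sel)) {
      warning("stage ", stg, " has no artifact-free epochs; dropped")
      next
    }
    ep$is_analysis[utils::head(sel, n_analysis)] <- TRUE
  }
  ep
}

.epoch_masked_frac <- function(rec, start_sample, end_sample) {
  if (is.null(rec$mask)) return(0)
  idx <- (start_sample + 1L):end_sample
  keep <- !rec$mask$reject
  if (!any(keep)) return(1)
  mean(rec$mask$bad[keep, idx, drop = FALSE])
}

#' Ordinal anaesthetic-stage code
#'
#' Control stages (Iso or SWS) code 0; sevoflurane minutes code 1..9 in the
#' order Sev2_1..Sev2_3, Sev3_1..Sev3_3, Sev4_1..Sev4_3, matching the
#' origin-anchored trend-line parameterization of the stage models.
#'
#' @param stage stage label vector ("Iso", "SWS", "Sev2", ...).
#' @param epoch_index 1-based minute within the stage.
#' @return integer codes.
#' @export
stage_code <- function(stage, epoch_index) {
  base <- c(Iso = 0L, SWS = 0L, Sev2 = 0L, Sev3 = 3L, Sev4 = 6L)[stage]
  ifelse(stage %in% CONTROL_STAGES, 0L, base + as.integer(epoch_index))
}

#' Stage-minute label such as "Sev2_1"
#' @inheritParams stage_code
#' @return character labels; control stages keep their bare name.
#' @export
stage_minute <- function(stage, epoch_index) {
  ifelse(stage %in% CONTROL_STAGES, stage,
         paste0(stage, "_", epoch_index))
}
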