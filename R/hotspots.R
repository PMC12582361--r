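# Selection of significantly co-augmented sites relative to the SWS
# reference and export of candidate edge lists for external tractography.

#' Select biomarker hotspots relative to the SWS reference
#'
#' Channels whose stage value is at least `k` SDs above the SWS mean are
#' selected (boundary included). The reference statistics are typically the
#' pooled normative-channel SWS values (see [sws_reference()]).
#'
#' @param stage_values named numeric vector of per-channel stage values.
#' @param sws_mean,sws_sd reference mean and SD; `sws_sd` must be positive.
#' @param k threshold in SDs (default 3).
#' @param stage,biomarker labels carried into the result.
#' @return object of class `sevo_hotspots`: `members` (data.frame of
#'   channel, value, z), `threshold_sd`, `stage`, `biomarker`.
#' @export
select_hotspots <- function(stage_values, sws_mean, sws_sd, k = 3,
                            stage = NA_character_, biomarker = NA_character_) {
  if (!is.finite(sws_sd) || sws_sd <= 0) stop("sws_sd must be positive")
  z <- (stage_values - sws_mean) / sws_sd
  tol <- 1e-9 * max(1, abs(k))       # keep the boundary inclusive despite fp
  sel <- which(is.finite(z) & z >= k - tol)
  members <- data.frame(channel = names(stage_values)[sel],
                        value = unname(stage_values[sel]),
                        z = unname(z[sel]))
  structure(list(members = members, threshold_sd = k, sws_mean = sws_mean,
                 sws_sd = sws_sd, stage = stage, biomarker = biomarker),
            class = "sevo_hotspots")
}

#' Pooled SWS reference statistics from a biomarker table
#'
#' Mean and SD of the pooled normative-channel SWS values of one biomarker
#' (the group-level reference used for hotspot maps).
#'
#' @param table biomarker table.
#' @param biomarker biomarker name.
#' @return list with `mean` and `sd`.
#' @export
sws_reference <- function(table, biomarker) {
  v <- table$value[table$biomarker == biomarker & table$stage == "SWS" &
                     table$normative & is.finite(table$value)]
  if (!length(v)) stop("no normative SWS values for ", biomarker)
  list(mean = mean(v), sd = stats::sd(v))
}

#' Export hotspot member pairs as a tractography edge list
#'
#' Writes all unordered member pairs as CSV (columns channel_a, channel_b,
#' value_a, value_b, stage, biomarker, plus coordinates when given) for
#' consumption by external tractography software. Fewer than two members
#' yields an empty file with a warning.
#'
#' @param hs a [select_hotspots()] result.
#' @param path output CSV path.
#' @param coords optional data.frame with `channel`, `x`, `y`, `z`.
#' @return the edge data.frame, invisibly.
#' @export
export_edges <- function(hs, path, coords = NULL) {
  m <- hs$members
  cols <- c("channel_a", "channel_b", "value_a", "value_b", "stage",
            "biomarker")
  if (nrow(m) < 2L) {
    warning("fewer than two hotspot members; writing empty edge list")
    edges <- stats::setNames(
      as.data.frame(matrix(nrow = 0L, ncol = length(cols))), cols)
    utils::write.csv(edges, path, row.names = FALSE)
    return(invisible(edges))
  }
  idx <- utils::combn(nrow(m), 2L)
  edges <- data.frame(channel_a = m$channel[idx[1L, ]],
                      channel_b = m$channel[idx[2L, ]],
                      value_a = m$value[idx[1L, ]],
                      value_b = m$value[idx[2L, ]],
                      stage = hs$stage, biomarker = hs$biomarker)
  if (!is.null(coords)) {
    ka <- match(edges$channel_a, coords$channel)
    kb <- match(edges$channel_b, coords$channel)
    edges[c("x_a", "y_a", "z_a")] <- coords[ka, c("x", "y", "z")]
    edges[c("x_b", "y_b", "z_b")] <- coords[kb, c("x", "y", "z")]
  }
  utils::write.csv(edges, path, row.names = FALSE)
  invisible(edges)
}
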