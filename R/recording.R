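# Recording container: channels x samples potential matrix (uV) with channel
# metadata, anaesthetic-stage annotations and (optional) artifact mask.

STAGES <- c("Iso", "SWS", "Sev2", "Sev3", "Sev4")
CONTROL_STAGES <- c("Iso", "SWS")
SEV_STAGES <- c("Sev2", "Sev3", "Sev4")

#' Construct a Recording
#'
#' @param samples numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate (Hz), > 0.
#' @param channels data.frame of per-channel metadata; must contain `label`
#'   and `patient_id`, plus the classification/covariate columns
#'   `is_resected`, `is_soz`, `is_lesional`, `has_ied`, `surgery_stages`,
#'   `hemisphere`, `age_years`, `sex`, `n_asm`, `daily_seizures` (missing
#'   columns are filled with neutral defaults).
#' @param annotations data.frame with `stage`, `start_sample`, `end_sample`
#'   (0-based, half-open); segments must be disjoint and inside the record.
#' @param montage "referential" or "bipolar".
#' @param mask optional [artifact_mask()].
#' @return object of class `sevo_recording`.
#' @export
recording <- function(samples, fs, channels, annotations = NULL,
                      montage = c("referential", "bipolar"), mask = NULL) {
  montage <- match.arg(montage)
  stopifnot(is.matrix(samples), fs > 0)
  channels <- .complete_channel_meta(channels)
  if (nrow(channels) != nrow(samples))
    stop("channel metadata rows (", nrow(channels),
         ") do not match sample matrix channels (", nrow(samples), ")")
  if (anyDuplicated(channels$label)) stop("duplicate channel labels")
  if (is.null(annotations)) {
    annotations <- data.frame(stage = character(), start_sample = integer(),
                              end_sample = integer())
  }
  .validate_annotations(annotations, ncol(samples))
  structure(list(samples = samples, fs = fs, channels = channels,
                 annotations = annotations, montage = montage, mask = mask),
            class = "sevo_recording")
}

.complete_channel_meta <- function(channels) {
  channels <- as.data.frame(channels)
  if (is.null(channels$label)) stop("channel metadata must contain 'label'")
  if (is.null(channels$patient_id)) stop("channel metadata must contain 'patient_id'")
  defaults <- list(is_resected = FALSE, is_soz = FALSE, is_lesional = FALSE,
                   has_ied = FALSE, surgery_stages = 1L, hemisphere = "L",
                   age_years = NA_real_, sex = "M", n_asm = 0L,
                   daily_seizures = FALSE)
  for (nm in names(defaults))
    if (is.null(channels[[nm]])) channels[[nm]] <- defaults[[nm]]
  channels$label <- as.character(channels$label)
  channels
}

.validate_annotations <- function(ann, n_samples) {
  if (nrow(ann) == 0L) return(invisible(TRUE))
  stopifnot(all(c("stage", "start_sample", "end_sample") %in% names(ann)))
  bad <- setdiff(ann$stage, STAGES)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  if (any(ann$start_sample < 0) || any(ann$end_sample > n_samples))
    stop("stage annotation outside the recording (", n_samples, " samples)")
  if (any(ann$end_sample <= ann$start_sample)) stop("empty stage segment")
  o <- order(ann$start_sample)
  if (any(ann$start_sample[o][-1L] < ann$end_sample[o][-nrow(ann)]))
    stop("overlapping stage segments")
  invisible(TRUE)
}

#' @export
print.sevo_recording <- function(x, ...) {
  cat(sprintf("<sevo_recording> %d channels x %d samples @ %g Hz (%s montage)\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$montage))
  if (nrow(x$annotations))
    cat("  stages:", paste(unique(x$annotations$stage), collapse = ", "), "\n")
  invisible(x)
}

#' Channel classification predicates
#'
#' Normative: retained, outside the seizure-onset zone and MRI lesions, free
#' of interictal epileptiform discharges. Epileptogenic: resected in a
#' seizure-free patient (the cohort definition).
#'
#' @param channels channel metadata data.frame.
#' @return logical vector.
#' @export
is_normative <- function(channels) {
  !channels$is_resected & !channels$is_soz & !channels$is_lesional & !channels$has_ied
}

#' @rdname is_normative
#' @export
is_epileptogenic <- function(channels) channels$is_resected

#' Load a recording from an EDF file plus CSV/JSON sidecars
#'
#' @param signal_path EDF file.
#' @param meta_path CSV of channel metadata (one row per channel, joined by
#'   `label`); every EDF channel must be covered.
#' @param annot_path JSON array of stage segments: objects with `stage`,
#'   `start_s`, `end_s` (seconds).
#' @param fs_expected optional sampling rate to cross-check against the file.
#' @return a referential-montage [recording()].
#' @export
load_recording <- function(signal_path, meta_path, annot_path,
                           fs_expected = NULL) {
  edf <- read_edf(signal_path)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  missing_ch <- setdiff(edf$labels, meta$label)
  if (length(missing_ch))
    stop("channel metadata missing for channel(s): ",
         paste(missing_ch, collapse = ", "))
  if (!is.null(fs_expected) && !isTRUE(all.equal(fs_expected, edf$fs)))
    stop("sampling rate mismatch: file ", edf$fs, " Hz vs metadata ",
         fs_expected, " Hz")
  meta <- meta[match(edf$labels, meta$label), , drop = FALSE]
  ann <- jsonlite::fromJSON(annot_path)
  annotations <- data.frame(
    stage = ann$stage,
    start_sample = as.integer(round(ann$start_s * edf$fs)),
    end_sample = as.integer(round(ann$end_s * edf$fs)))
  recording(edf$samples, edf$fs, meta, annotations, montage = "referential")
}

#' Write a recording as EDF + sidecars
#'
#' @param rec a [recording()].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return named list of the three file paths.
#' @export
write_recording <- function(rec, dir, name = "recording") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(signal = file.path(dir, paste0(name, ".edf")),
                meta = file.path(dir, paste0(name, "_channels.csv")),
                annot = file.path(dir, paste0(name, "_stages.json")))
  write_edf(rec$samples, rec$fs, rec$channels$label, paths$signal)
  utils::write.csv(rec$channels, paths$meta, row.names = FALSE)
  ann <- data.frame(stage = rec$annotations$stage,
                    start_s = rec$annotations$start_sample / rec$fs,
                    end_s = rec$annotations$end_sample / rec$fs)
  jsonlite::write_json(ann, paths$annot, digits = NA)
  invisible(paths)
}

#' Derive a bipolar montage
#'
#' Each output channel is anode minus cathode, sample-wise. Classification
#' flags of the derived channel are the OR of its members (a pair touching
#' resected tissue counts as resected); other covariates come from the anode.
#'
#' @param rec referential [recording()].
#' @param pairs data.frame (or 2-column matrix) of ordered label pairs
#'   `anode`, `cathode`.
#' @return bipolar [recording()] with labels `"anode-cathode"`.
#' @export
to_bipolar <- function(rec, pairs) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("anode", "cathode")
  labs <- rec$channels$label
  absent <- setdiff(unique(c(pairs$anode, pairs$cathode)), labs)
  if (length(absent))
    stop("bipolar pair references absent channel(s): ",
         paste(absent, collapse = ", "))
  ia <- match(pairs$anode, labs); ic <- match(pairs$cathode, labs)
  samples <- rec$samples[ia, , drop = FALSE] - rec$samples[ic, , drop = FALSE]
  ch <- rec$channels[ia, , drop = FALSE]
  ch$label <- paste0(pairs$anode, "-", pairs$cathode)
  for (flag in c("is_resected", "is_soz", "is_lesional", "has_ied",
                 "daily_seizures"))
    ch[[flag]] <- rec$channels[[flag]][ia] | rec$channels[[flag]][ic]
  rownames(ch) <- NULL
  recording(samples, rec$fs, ch, rec$annotations, montage = "bipolar")
}

#' Neighbouring-contact bipolar pairs
#'
#' Convenience: chains consecutive labels into anode-cathode pairs, the usual
#' strip/grid dereferencing scheme.
#'
#' @param labels channel labels in physical order.
#' @return data.frame with columns `anode`, `cathode`.
#' @export
adjacent_pairs <- function(labels) {
  n <- length(labels)
  if (n < 2L) stop("need at least two channels")
  data.frame(anode = labels[-n], cathode = labels[-1L])
}
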