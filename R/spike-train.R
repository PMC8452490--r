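#' Spike train for one electrode
#'
#' A spike train holds the ordered spike timestamps (and, optionally, spike
#' amplitudes) detected on a single MEA electrode.  Timestamps are seconds
#' from recording start, zero-based, strictly increasing.
#'
#' @param timestamps Numeric vector of spike times in seconds, strictly
#'   increasing, all within `[0, duration]` of the parent recording.
#' @param amplitudes Optional numeric vector of spike amplitudes in
#'   microvolts, same length as `timestamps`.
#' @param electrode_id Integer electrode label in `1:12`.
#'
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(timestamps = numeric(0), amplitudes = NULL,
                        electrode_id = 1L) {
  timestamps <- as.numeric(timestamps)
  if (anyNA(timestamps)) {
    stop("spike timestamps must not contain NA")
  }
  if (is.unsorted(timestamps, strictly = TRUE)) {
    stop("spike timestamps must be strictly increasing (electrode ",
         electrode_id, ")")
  }
  if (length(timestamps) && timestamps[1] < 0) {
    stop("spike timestamps must be non-negative (electrode ", electrode_id, ")")
  }
  if (!is.null(amplitudes)) {
    amplitudes <- as.numeric(amplitudes)
    if (length(amplitudes) != length(timestamps)) {
      stop("amplitudes must have the same length as timestamps (electrode ",
           electrode_id, ")")
    }
  }
  structure(
    list(timestamps = timestamps, amplitudes = amplitudes,
         electrode_id = as.integer(electrode_id)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train> electrode", x$electrode_id, "-", length(x$timestamps),
      "spikes")
  if (length(x$timestamps)) {
    cat(sprintf(" in [%.3f, %.3f] s", x$timestamps[1],
                x$timestamps[length(x$timestamps)]))
  }
  cat("\n")
  invisible(x)
}

#' Number of spikes in a train
#' @param x A `spike_train`.
#' @return Integer spike count.
#' @export
n_spikes <- function(x) length(x$timestamps)

#' Recording metadata for one well
#'
#' Grouping factors used by the cohort analyses: cell line, culture age
#' (days in vitro), the MEA and astrocyte preparation batches, donor sex and
#' age, disease status and coating substrate.
#'
#' @param well_id Well label.
#' @param line_id Cell-line label (e.g. `"C_1"`).
#' @param DIV Days in vitro, non-negative integer.
#' @param mea_batch,astro_batch Batch labels.
#' @param sex One of `"M"`, `"F"`, `"unknown"`.
#' @param donor_age Donor age at biopsy, years (NA allowed).
#' @param disease_status One of `"control"`, `"MELAS"`, `"KS"`, `"other"`.
#' @param coating One of `"human_laminin"`, `"mouse_laminin"`, `"unknown"`.
#' @param manual_exclude Logical; operator-flagged exclusion (e.g. poor cell
#'   density/clumping judged from microscopy), honoured by QC.
#'
#' @return An object of class `recording_metadata`.
#' @export
recording_metadata <- function(well_id = "well_1", line_id = "unknown",
                               DIV = 30L, mea_batch = "B1", astro_batch = "A1",
                               sex = "unknown", donor_age = NA_real_,
                               disease_status = "control",
                               coating = "unknown",
                               manual_exclude = FALSE) {
  sex <- match.arg(sex, c("M", "F", "unknown"))
  disease_status <- match.arg(disease_status,
                              c("control", "MELAS", "KS", "other"))
  coating <- match.arg(coating, c("human_laminin", "mouse_laminin", "unknown"))
  DIV <- as.integer(DIV)
  if (is.na(DIV) || DIV < 0) stop("DIV must be a non-negative integer")
  structure(
    list(well_id = as.character(well_id), line_id = as.character(line_id),
         DIV = DIV, mea_batch = as.character(mea_batch),
         astro_batch = as.character(astro_batch), sex = sex,
         donor_age = as.numeric(donor_age), disease_status = disease_status,
         coating = coating, manual_exclude = isTRUE(manual_exclude)),
    class = "recording_metadata"
  )
}

#' Well recording: 12 spike trains plus metadata
#'
#' One culture well of a 24-well MEA plate carries 12 recording electrodes.
#' All 12 slots are always present; electrodes with no detected spikes hold
#' empty trains, so that per-well parameters are computed over all electrodes
#' rather than only the active ones.
#'
#' @param trains List of up to 12 `spike_train` objects.  Slots not supplied
#'   become empty trains.
#' @param duration Recording duration in seconds (default 600 s, i.e. the
#'   standard 10-minute session).
#' @param sampling_rate Acquisition sampling rate in Hz (10 kHz standard).
#' @param metadata A `recording_metadata`.
#'
#' @return An object of class `well_recording`.
#' @export
well_recording <- function(trains = list(), duration = 600,
                           sampling_rate = 10000,
                           metadata = recording_metadata()) {
  if (duration <= 0) stop("duration must be positive")
  full <- vector("list", 12L)
  for (k in seq_len(12L)) full[[k]] <- spike_train(electrode_id = k)
  for (tr in trains) {
    if (!inherits(tr, "spike_train")) stop("trains must be spike_train objects")
    k <- tr$electrode_id
    if (k < 1 || k > 12) stop("electrode_id must be in 1:12, got ", k)
    full[[k]] <- tr
  }
  for (tr in full) {
    ts <- tr$timestamps
    if (length(ts) && ts[length(ts)] > duration) {
      stop("electrode ", tr$electrode_id,
           " has spikes beyond the recording duration")
    }
  }
  structure(
    list(trains = full, duration = as.numeric(duration),
         sampling_rate = as.numeric(sampling_rate), metadata = metadata),
    class = "well_recording"
  )
}

#' @export
print.well_recording <- function(x, ...) {
  ns <- vapply(x$trains, n_spikes, integer(1))
  cat("<well_recording>", x$metadata$well_id, "line", x$metadata$line_id,
      "DIV", x$metadata$DIV, "\n")
  cat("  duration:", x$duration, "s;", sum(ns), "spikes on", sum(ns > 0),
      "of 12 electrodes\n")
  invisible(x)
}

#' Total spike count of a well
#' @param well A `well_recording`.
#' @return Integer total number of spikes across all 12 electrodes.
#' @export
well_spike_count <- function(well) {
  sum(vapply(well$trains, n_spikes, integer(1)))
}

#' All spike times of a well, pooled and sorted
#' @param well A `well_recording`.
#' @return Numeric vector of all spike times (seconds), sorted.
#' @keywords internal
pooled_spike_times <- function(well) {
  sort(unlist(lapply(well$trains, `[[`, "timestamps"), use.names = FALSE))
}
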