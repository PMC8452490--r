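#' Single-channel burst-detection settings
#'
#' The max-interval ("string") method: a burst is a maximal run of at least
#' `min_spikes` consecutive spikes in which every inter-spike interval is at
#' most `max_isi`.  Defaults (100 ms, 5 spikes) are the values commonly used
#' for MEA multi-unit activity; both are tunable per recording and should be
#' stored with the results they produced.
#'
#' @param max_isi Maximum intra-burst inter-spike interval, seconds.
#' @param min_spikes Minimum number of spikes per burst (>= 2).
#' @return An object of class `burst_settings`.
#' @export
burst_settings <- function(max_isi = 0.1, min_spikes = 5L) {
  if (max_isi <= 0) stop("max_isi must be positive")
  min_spikes <- as.integer(min_spikes)
  if (min_spikes < 2) stop("min_spikes must be at least 2")
  structure(list(max_isi = as.numeric(max_isi), min_spikes = min_spikes),
            class = "burst_settings")
}

#' Detect single-channel bursts
#'
#' @param train A [spike_train()].
#' @param settings A [burst_settings()].
#' @return A data frame with columns `electrode_id, start, end, n_spikes`,
#'   one row per burst, ordered and non-overlapping.  Burst start/end are the
#'   first/last spike times.  An interval exactly equal to `max_isi` is
#'   within the burst (inclusive comparison).
#' @export
detect_bursts <- function(train, settings = burst_settings()) {
  ts <- train$timestamps
  empty <- data.frame(electrode_id = integer(0), start = numeric(0),
                      end = numeric(0), n_spikes = integer(0))
  if (length(ts) < settings$min_spikes) return(empty)
  ok <- diff(ts) <= settings$max_isi
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= settings$min_spikes - 1L)
  if (!length(qual)) return(empty)
  i0 <- starts[qual]            # index of first spike of the run
  i1 <- ends[qual] + 1L         # index of last spike of the run
  data.frame(electrode_id = train$electrode_id, start = ts[i0], end = ts[i1],
             n_spikes = i1 - i0 + 1L)
}

#' Detect bursts on every electrode of a well
#'
#' @param well A [well_recording()].
#' @param settings A [burst_settings()].
#' @return One data frame of bursts across all 12 electrodes.
#' @export
detect_bursts_well <- function(well, settings = burst_settings()) {
  do.call(rbind, lapply(well$trains, detect_bursts, settings = settings))
}

#' Channel-level burst statistics
#'
#' Computes the per-channel burst parameters: burst rate (BR, bursts/min),
#' mean burst duration (BD, s), burst spike rate (BSR, mean within-burst
#' firing rate, spikes/s) and mean inter-burst interval (IBI, s, measured
#' end of one burst to start of the next).  Means that are undefined (no
#' bursts; fewer than two bursts for IBI) are returned as `NA` with the
#' `defined` flags set accordingly.
#'
#' @param bursts Burst data frame for one electrode ([detect_bursts()]).
#' @param duration Recording duration, seconds.
#' @return A list with elements `BR`, `BD`, `BSR`, `IBI` and a logical
#'   vector `defined`.
#' @export
channel_burst_statistics <- function(bursts, duration) {
  if (duration <= 0) stop("duration must be positive")
  n <- nrow(bursts)
  if (n == 0) {
    return(list(BR = 0, BD = NA_real_, BSR = NA_real_, IBI = NA_real_,
                defined = c(BR = TRUE, BD = FALSE, BSR = FALSE, IBI = FALSE)))
  }
  dur <- bursts$end - bursts$start
  ibi <- if (n >= 2) bursts$start[-1] - bursts$end[-n] else NA_real_
  list(
    BR = n / duration * 60,
    BD = mean(dur),
    BSR = mean(bursts$n_spikes / dur),
    IBI = if (n >= 2) mean(ibi) else NA_real_,
    defined = c(BR = TRUE, BD = TRUE, BSR = TRUE, IBI = n >= 2)
  )
}

#' Mean firing rate of a well
#'
#' Total spike count divided by duration and by the full 12-electrode grid.
#' Silent electrodes are included in the denominator: restricting the
#' analysis to active electrodes inflates activity measures, so per-well
#' parameters are always computed on all electrodes.
#'
#' @param well A [well_recording()].
#' @return Mean firing rate in spikes/s per electrode.
#' @export
mean_firing_rate <- function(well) {
  well_spike_count(well) / well$duration / 12
}

#' Percentage of random spikes
#'
#' Random spikes are isolated, asynchronous spikes: those not contained in
#' any detected single-channel burst.  PRS is their percentage of all spikes
#' in the well.
#'
#' @param well A [well_recording()].
#' @param bursts Burst data frame for the well ([detect_bursts_well()]).
#' @return A list with `PRS` (percent) and `defined` (FALSE when the well
#'   has no spikes, in which case PRS is 0).
#' @export
percentage_random_spikes <- function(well, bursts) {
  total <- well_spike_count(well)
  if (total == 0) return(list(PRS = 0, defined = FALSE))
  in_burst <- 0L
  for (tr in well$trains) {
    if (!length(tr$timestamps)) next
    b <- bursts[bursts$electrode_id == tr$electrode_id, , drop = FALSE]
    if (!nrow(b)) next
    for (i in seq_len(nrow(b))) {
      in_burst <- in_burst +
        sum(tr$timestamps >= b$start[i] & tr$timestamps <= b$end[i])
    }
  }
  list(PRS = 100 * (total - in_burst) / total, defined = TRUE)
}
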