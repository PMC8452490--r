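#' Network-burst detection settings
#'
#' Network bursts are synchronous, rhythmic events in which a sufficient
#' fraction of a well's electrodes fire together.  Detection scans the
#' well-wide binned spike count for contiguous supra-threshold bins, extends
#' each candidate to its first/last spike, merges candidates separated by
#' less than `merge_gap`, and keeps only events in which the participating
#' channel fraction is at least `min_channel_fraction` (the "channels in
#' network burst > 25%" recommendation).
#'
#' The count threshold defaults to
#' `max(baseline_count, peak_fraction * max(binned count))` so that it adapts
#' to the well's own activity level; it can be pinned with `rate_threshold`
#' for per-recording tuning or settings sweeps.
#'
#' @param bin_width Bin width of the well-wide spike count, seconds.
#' @param baseline_count Minimum threshold, spikes per bin (well-wide).
#' @param peak_fraction Threshold as a fraction of the well's peak bin count.
#' @param rate_threshold Optional fixed threshold, spikes per bin; overrides
#'   the adaptive rule when given.
#' @param min_channel_fraction Minimum fraction of the 12 electrodes with at
#'   least one spike inside the event.
#' @param merge_gap Events separated by less than this many seconds are
#'   merged.
#' @param min_nb_spikes Minimum well-wide spike count per network burst;
#'   rejects spurious sub-events from coincident single-channel bursts.
#' @return An object of class `nb_settings`.
#' @export
nb_settings <- function(bin_width = 0.025, baseline_count = 1.5,
                        peak_fraction = 0.05, rate_threshold = NULL,
                        min_channel_fraction = 0.25, merge_gap = 0.1,
                        min_nb_spikes = 30L) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (min_channel_fraction < 0 || min_channel_fraction > 1) {
    stop("min_channel_fraction must be in [0, 1]")
  }
  structure(list(bin_width = bin_width, baseline_count = baseline_count,
                 peak_fraction = peak_fraction,
                 rate_threshold = rate_threshold,
                 min_channel_fraction = min_channel_fraction,
                 merge_gap = merge_gap,
                 min_nb_spikes = as.integer(min_nb_spikes)),
            class = "nb_settings")
}

#' Detect network bursts in a well
#'
#' @param well A [well_recording()].
#' @param settings An [nb_settings()].
#' @return A data frame with one row per network burst: `start`, `end`
#'   (seconds; first/last participating spike), `n_channels` (electrodes
#'   with at least one spike inside the event) and `n_spikes` (well-wide).
#'   Deterministic; an empty well yields an empty data frame.
#' @export
detect_network_bursts <- function(well, settings = nb_settings()) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_channels = integer(0), n_spikes = integer(0))
  pooled <- pooled_spike_times(well)
  if (!length(pooled)) return(empty)
  bw <- settings$bin_width
  n_bins <- ceiling(well$duration / bw)
  counts <- tabulate(pmin(floor(pooled / bw) + 1L, n_bins), nbins = n_bins)
  thr <- settings$rate_threshold
  if (is.null(thr)) {
    thr <- max(settings$baseline_count, settings$peak_fraction * max(counts))
  }
  supra <- counts >= thr
  if (!any(supra)) return(empty)
  r <- rle(supra)
  hi <- which(r$values)
  if (!length(hi)) return(empty)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  lo_t <- (run_start[hi] - 1) * bw
  hi_t <- run_end[hi] * bw
  # snap candidate edges to the actual first/last spike inside them
  starts <- ends <- numeric(length(hi))
  keep <- logical(length(hi))
  for (i in seq_along(hi)) {
    inside <- pooled[pooled >= lo_t[i] & pooled < hi_t[i]]
    if (length(inside)) {
      starts[i] <- inside[1]
      ends[i] <- inside[length(inside)]
      keep[i] <- TRUE
    }
  }
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(empty)
  # merge events separated by less than merge_gap
  m_start <- starts[1]; m_end <- ends[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - m_end < settings$merge_gap) {
      m_end <- ends[i]
    } else {
      out_s <- c(out_s, m_start); out_e <- c(out_e, m_end)
      m_start <- starts[i]; m_end <- ends[i]
    }
  }
  out_s <- c(out_s, m_start); out_e <- c(out_e, m_end)
  # participation filter and spike counts
  min_ch <- settings$min_channel_fraction * 12
  res <- empty
  for (i in seq_along(out_s)) {
    ch <- vapply(well$trains, function(tr) {
      any(tr$timestamps >= out_s[i] & tr$timestamps <= out_e[i])
    }, logical(1))
    n_ch <- sum(ch)
    if (n_ch < min_ch) next
    n_sp <- sum(pooled >= out_s[i] & pooled <= out_e[i])
    if (n_sp < settings$min_nb_spikes) next
    res <- rbind(res, data.frame(start = out_s[i],
                                 end = max(out_e[i], out_s[i] + bw * 1e-9),
                                 n_channels = n_ch, n_spikes = n_sp))
  }
  rownames(res) <- NULL
  res
}

#' Network-burst statistics
#'
#' NBR (network bursts per minute), NBD (mean duration, s), NIBI (mean gap
#' between the end of one network burst and the start of the next, s) and
#' CV_NIBI (coefficient of variation of those gaps, sample SD / mean --
#' the regularity of network bursting).  With fewer than two network bursts
#' NIBI and CV_NIBI are undefined (`NA`, flagged).
#'
#' @param nbs Network-burst data frame ([detect_network_bursts()]).
#' @param duration Recording duration, seconds.
#' @return List with `NBR`, `NBD`, `NIBI`, `CV_NIBI` and `defined` flags.
#' @export
network_burst_statistics <- function(nbs, duration) {
  if (duration <= 0) stop("duration must be positive")
  n <- nrow(nbs)
  if (n == 0) {
    return(list(NBR = 0, NBD = NA_real_, NIBI = NA_real_, CV_NIBI = NA_real_,
                defined = c(NBR = TRUE, NBD = FALSE, NIBI = FALSE,
                            CV_NIBI = FALSE)))
  }
  gaps <- if (n >= 2) nbs$start[-1] - nbs$end[-n] else numeric(0)
  list(
    NBR = n / duration * 60,
    NBD = mean(nbs$end - nbs$start),
    NIBI = if (n >= 2) mean(gaps) else NA_real_,
    CV_NIBI = if (n >= 3) stats::sd(gaps) / mean(gaps) else NA_real_,
    defined = c(NBR = TRUE, NBD = TRUE, NIBI = n >= 2, CV_NIBI = n >= 3)
  )
}

#' Average network-burst shape
#'
#' For each network burst, well-summed spike counts are binned from the
#' burst onset over a fixed window and converted to rate; profiles are then
#' averaged across bursts.  Network bursts whose window would extend beyond
#' the end of the recording are omitted from the average.
#'
#' @param well A [well_recording()].
#' @param nbs Network-burst data frame (must be non-empty).
#' @param bin_width Profile bin width, seconds.
#' @param window Profile length, seconds from burst onset.
#' @param normalization `"none"` (well-wide spikes/s) or `"peak"` (profile
#'   scaled to a maximum of 1).
#' @return An object of class `nb_shape`: list with `bin_width`, `window`,
#'   `profile`, `t` (bin centres from onset), `normalization`, `n_nb`.
#' @export
network_burst_shape <- function(well, nbs, bin_width = 0.005, window = 3,
                                normalization = c("none", "peak")) {
  normalization <- match.arg(normalization)
  if (nrow(nbs) == 0) {
    stop("no network bursts to align; the well likely fails network-burst QC")
  }
  pooled <- pooled_spike_times(well)
  onsets <- nbs$start[nbs$start + window <= well$duration]
  if (!length(onsets)) onsets <- nbs$start[1]
  n_bins <- round(window / bin_width)
  acc <- numeric(n_bins)
  for (t0 in onsets) {
    sel <- pooled[pooled >= t0 & pooled < t0 + window]
    acc <- acc + tabulate(floor((sel - t0) / bin_width) + 1L, nbins = n_bins)
  }
  profile <- acc / length(onsets) / bin_width
  if (normalization == "peak" && max(profile) > 0) {
    profile <- profile / max(profile)
  }
  structure(list(bin_width = bin_width, window = window, profile = profile,
                 t = (seq_len(n_bins) - 0.5) * bin_width,
                 normalization = normalization, n_nb = length(onsets)),
            class = "nb_shape")
}

#' Rise and decay time of a network-burst shape
#'
#' Rise time (RT) is measured from the last upward crossing of
#' `lo_frac * peak` before the peak to the peak; decay time (DT) from the
#' peak to the first downward crossing after it.  Crossing times are
#' linearly interpolated between bin centres.  A peak at the window edge, or
#' a profile that never drops below the threshold on one side, leaves the
#' corresponding time undefined; a profile already above threshold at onset
#' (e.g. a boxcar) is flagged degenerate and measured from the window start.
#'
#' @param shape An [network_burst_shape()] result.
#' @param lo_frac Threshold as a fraction of the peak (default 0.1).
#' @return List with `RT`, `DT` (seconds, `NA` when undefined), `defined`
#'   flags and `degenerate`.
#' @export
rise_decay_times <- function(shape, lo_frac = 0.1) {
  p <- shape$profile
  t <- shape$t
  m <- which.max(p)
  undef <- list(RT = NA_real_, DT = NA_real_,
                defined = c(RT = FALSE, DT = FALSE), degenerate = FALSE)
  if (max(p) <= 0 || m == length(p)) return(undef)
  thr <- lo_frac * p[m]
  degenerate <- FALSE

  below_before <- if (m > 1L) which(p[seq_len(m - 1)] <= thr) else integer(0)
  if (length(below_before)) {
    k <- max(below_before)        # last bin at/below threshold before peak
    t_up <- t[k] + (t[k + 1] - t[k]) * (thr - p[k]) / (p[k + 1] - p[k])
    RT <- t[m] - t_up
    rt_def <- TRUE
  } else {
    RT <- t[m] - (t[1] - shape$bin_width / 2)
    rt_def <- TRUE
    degenerate <- TRUE
  }

  after <- seq(m + 1, length(p))
  below_after <- after[p[after] <= thr]
  if (length(below_after)) {
    k <- min(below_after)         # first bin at/below threshold after peak
    t_dn <- t[k - 1] + (t[k] - t[k - 1]) * (p[k - 1] - thr) / (p[k - 1] - p[k])
    DT <- t_dn - t[m]
    dt_def <- TRUE
  } else {
    DT <- NA_real_
    dt_def <- FALSE
  }
  list(RT = RT, DT = DT, defined = c(RT = rt_def, DT = dt_def),
       degenerate = degenerate)
}
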