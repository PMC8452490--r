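# Independent brute-force oracles and small fixture builders used across the
# suite.  These deliberately re-derive results by direct enumeration so the
# vectorised implementations are checked against something simpler.

# exhaustive scan: all maximal runs of >= min_spikes spikes with every ISI
# <= max_isi
oracle_bursts <- function(ts, max_isi, min_spikes) {
  out <- data.frame(start = numeric(0), end = numeric(0),
                    n_spikes = integer(0))
  n <- length(ts)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ts[j + 1] - ts[j] <= max_isi) j <- j + 1L
    if (j - i + 1L >= min_spikes) {
      out <- rbind(out, data.frame(start = ts[i], end = ts[j],
                                   n_spikes = j - i + 1L))
    }
    i <- j + 1L
  }
  out
}

# O(Na*Nb) pair counting for the cross-correlogram
oracle_xcorr <- function(ta, tb, window, bin) {
  n_lags <- round(window / bin)
  counts <- integer(2L * n_lags + 1L)
  for (x in ta) {
    for (y in tb) {
      k <- round((y - x) / bin)
      if (abs(k) <= n_lags) counts[k + n_lags + 1L] <- counts[k + n_lags + 1L] + 1L
    }
  }
  counts
}

# direct scan of the binned well-wide count array: candidate runs, spike-edge
# snapping, merging, participation and size filters -- written as plain loops
oracle_network_bursts <- function(well, settings) {
  bw <- settings$bin_width
  pooled <- sort(unlist(lapply(well$trains, `[[`, "timestamps")))
  if (!length(pooled)) return(NULL)
  n_bins <- ceiling(well$duration / bw)
  counts <- integer(n_bins)
  for (t in pooled) counts[min(floor(t / bw) + 1L, n_bins)] <-
      counts[min(floor(t / bw) + 1L, n_bins)] + 1L
  thr <- settings$rate_threshold
  if (is.null(thr)) thr <- max(settings$baseline_count,
                               settings$peak_fraction * max(counts))
  intervals <- list()
  k <- 1L
  while (k <= n_bins) {
    if (counts[k] >= thr) {
      k2 <- k
      while (k2 < n_bins && counts[k2 + 1L] >= thr) k2 <- k2 + 1L
      inside <- pooled[pooled >= (k - 1L) * bw & pooled < k2 * bw]
      if (length(inside)) {
        intervals[[length(intervals) + 1L]] <- c(min(inside), max(inside))
      }
      k <- k2 + 1L
    } else {
      k <- k + 1L
    }
  }
  if (!length(intervals)) return(NULL)
  merged <- list(intervals[[1]])
  for (iv in intervals[-1]) {
    last <- merged[[length(merged)]]
    if (iv[1] - last[2] < settings$merge_gap) {
      merged[[length(merged)]] <- c(last[1], iv[2])
    } else {
      merged[[length(merged) + 1L]] <- iv
    }
  }
  keep <- list()
  for (iv in merged) {
    n_ch <- sum(vapply(well$trains, function(tr) {
      any(tr$timestamps >= iv[1] & tr$timestamps <= iv[2])
    }, logical(1)))
    n_sp <- sum(pooled >= iv[1] & pooled <= iv[2])
    if (n_ch >= settings$min_channel_fraction * 12 &&
        n_sp >= settings$min_nb_spikes) {
      keep[[length(keep) + 1L]] <- c(iv, n_ch, n_sp)
    }
  }
  if (!length(keep)) return(NULL)
  do.call(rbind, keep)
}

# random spike train on [0, duration] (grid-quantised, strictly increasing)
rand_train <- function(n, duration = 60, electrode_id = 1L, fs = 10000) {
  ts <- sort(unique(round(runif(n, 0, duration) * fs))) / fs
  spike_train(ts, NULL, electrode_id)
}

# well with synchronized firing windows: each of `channels` fires `n_per`
# spikes inside every [onset, onset + width] interval
sync_well <- function(onsets, width = 0.1, channels = 1:12, n_per = 10,
                      duration = 60) {
  trains <- lapply(channels, function(k) {
    ts <- unlist(lapply(onsets, function(o) {
      o + (seq_len(n_per) - 0.5) / n_per * width + k * 1e-5
    }))
    spike_train(sort(ts), NULL, k)
  })
  well_recording(trains, duration = duration)
}

# one-row parameter list passing every QC criterion
qc_pass_row <- function(...) {
  utils::modifyList(
    list(well_id = "w", MFR = 3.5, BR = 4.8, NBR = 3.2,
         active_fraction = 1.0, nb_channel_fraction = 0.9, DIV = 30,
         manual_exclude = FALSE),
    list(...))
}
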