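#' Connectivity settings
#'
#' @param window Maximum correlogram lag, seconds (symmetric around 0).
#' @param bin Correlogram bin width, seconds.
#' @param n_surrogates Number of dithered surrogates for the link threshold.
#' @param alpha Significance level of the surrogate threshold.
#' @param jitter Half-width of the uniform spike-time dither, seconds.
#' @return An object of class `conn_settings`.
#' @export
conn_settings <- function(window = 0.5, bin = 0.01, n_surrogates = 100,
                          alpha = 0.05, jitter = 0.5) {
  if (window <= 0 || bin <= 0 || bin > window) {
    stop("need 0 < bin <= window")
  }
  structure(list(window = window, bin = bin,
                 n_surrogates = as.integer(n_surrogates), alpha = alpha,
                 jitter = jitter),
            class = "conn_settings")
}

# lag-bin pair counts of (tb - ta); lag centres are k*bin for
# k = -n_lags..n_lags.  Both inputs sorted.
.xcorr_counts <- function(ta, tb, window, bin) {
  n_lags <- round(window / bin)
  n_bins <- 2L * n_lags + 1L
  if (!length(ta) || !length(tb)) return(integer(n_bins))
  half <- n_lags * bin + bin / 2
  lo <- findInterval(ta - half, tb)            # tb[lo] < ta - half <= tb[lo+1]
  hi <- findInterval(ta + half, tb)            # tb[hi] <= ta + half
  ni <- hi - lo
  pos <- ni > 0
  if (!any(pos)) return(integer(n_bins))
  idx <- sequence(ni[pos], from = lo[pos] + 1L)
  diffs <- tb[idx] - rep(ta[pos], ni[pos])
  k <- round(diffs / bin)
  k <- k[abs(k) <= n_lags]
  tabulate(k + n_lags + 1L, nbins = n_bins)
}

#' Cross-correlogram of two spike trains
#'
#' Counts spike-pair lag differences `t_b - t_a` per lag bin (positive lag =
#' the second train fires after the first), normalised by
#' `sqrt(N_a * N_b)` so that an identical sparse pair has value 1 in the
#' zero-lag bin.  `cross_correlogram(a, b)` at lag `tau` equals
#' `cross_correlogram(b, a)` at `-tau`.
#'
#' @param a,b [spike_train()] objects from the same recording.
#' @param window Maximum lag, seconds.
#' @param bin Lag bin width, seconds.
#' @return An object of class `cross_correlogram`: list with `lags` (bin
#'   centres, s), `values`, `pair`, and `flag_empty` when either train has
#'   no spikes (all-zero correlogram).
#' @export
cross_correlogram <- function(a, b, window = 0.5, bin = 0.01) {
  counts <- .xcorr_counts(a$timestamps, b$timestamps, window, bin)
  n_lags <- round(window / bin)
  lags <- seq(-n_lags, n_lags) * bin
  na <- n_spikes(a); nb <- n_spikes(b)
  values <- if (na == 0 || nb == 0) rep(0, length(counts)) else
    counts / sqrt(na * nb)
  structure(list(lags = lags, values = values,
                 pair = c(a$electrode_id, b$electrode_id),
                 flag_empty = (na == 0 || nb == 0)),
            class = "cross_correlogram")
}

#' Pairwise connectivity matrices of a well
#'
#' Computes, for all 66 unordered electrode pairs (including silent
#' electrodes, whose pairs score 0), the zero-lag correlogram value `C_0`
#' (synchronization) and the maximum over lags `C_peak` (correlation).
#'
#' @param well A [well_recording()].
#' @param settings A [conn_settings()].
#' @return An object of class `connectivity_result`: list with symmetric
#'   12x12 `c0_matrix` and `cpeak_matrix` (diagonal `NA`), `links = NULL`
#'   (see [functional_links()]), `flag_silent` when the well has no spikes,
#'   and the settings used.
#' @export
pairwise_connectivity <- function(well, settings = conn_settings()) {
  c0 <- cpk <- matrix(NA_real_, 12, 12)
  zero_idx <- round(settings$window / settings$bin) + 1L
  for (i in 1:11) {
    for (j in (i + 1):12) {
      cc <- cross_correlogram(well$trains[[i]], well$trains[[j]],
                              settings$window, settings$bin)
      c0[i, j] <- c0[j, i] <- cc$values[zero_idx]
      cpk[i, j] <- cpk[j, i] <- max(cc$values)
    }
  }
  structure(list(c0_matrix = c0, cpeak_matrix = cpk, links = NULL,
                 link_weight = NA_real_, n_connections = NA_integer_,
                 threshold = NA_real_,
                 flag_silent = well_spike_count(well) == 0,
                 settings = settings),
            class = "connectivity_result")
}

# uniform +/- jitter dither of one train, reflected into [0, duration]
.dither_train <- function(tr, jitter, duration) {
  ts <- tr$timestamps
  if (!length(ts)) return(tr)
  ts <- ts + stats::runif(length(ts), -jitter, jitter)
  ts <- abs(ts)
  ts <- duration - abs(duration - ts)
  spike_train(sort(ts) + seq_along(ts) * 1e-12, NULL, tr$electrode_id)
}

#' Surrogate-thresholded functional links
#'
#' A pair of electrodes is a functional connection when its `C_peak` exceeds
#' the `(1 - alpha)` quantile of `C_peak` over surrogate pairs, built by
#' dithering every spike with a uniform jitter (which preserves firing rates
#' but destroys fine-timescale correlation).  The seed makes the surrogate
#' ensemble, and hence the link set, fully reproducible.
#'
#' @param result A [pairwise_connectivity()] result.
#' @param well The same [well_recording()].
#' @param n_surrogates Number of surrogate well copies (warning below 20:
#'   the null quantile is unstable).
#' @param alpha Significance level.
#' @param seed Integer seed (mandatory).
#' @return The `connectivity_result` with `links` (data frame `a, b,
#'   c_peak`), `link_weight` (mean `C_peak` over links; `NA` when none),
#'   `n_connections` and the surrogate `threshold` filled in.
#' @export
functional_links <- function(result, well,
                             n_surrogates = result$settings$n_surrogates,
                             alpha = result$settings$alpha, seed) {
  if (missing(seed)) stop("a seed is required for the surrogate ensemble")
  if (n_surrogates < 20) {
    warning("fewer than 20 surrogates gives an unstable null distribution")
  }
  st <- result$settings
  zero_idx <- round(st$window / st$bin) + 1L
  null_cpeak <- numeric(0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (s in seq_len(n_surrogates)) {
    sur <- lapply(well$trains, .dither_train, jitter = st$jitter,
                  duration = well$duration)
    vals <- numeric(66)
    k <- 0L
    for (i in 1:11) {
      for (j in (i + 1):12) {
        k <- k + 1L
        cnt <- .xcorr_counts(sur[[i]]$timestamps, sur[[j]]$timestamps,
                             st$window, st$bin)
        na <- length(sur[[i]]$timestamps); nb <- length(sur[[j]]$timestamps)
        vals[k] <- if (na == 0 || nb == 0) 0 else max(cnt) / sqrt(na * nb)
      }
    }
    null_cpeak <- c(null_cpeak, vals)
  }
  threshold <- stats::quantile(null_cpeak, 1 - alpha, names = FALSE)
  ij <- which(upper.tri(result$cpeak_matrix), arr.ind = TRUE)
  cp <- result$cpeak_matrix[ij]
  is_link <- cp > threshold
  links <- data.frame(a = ij[is_link, 1], b = ij[is_link, 2],
                      c_peak = cp[is_link])
  links <- links[order(links$a, links$b), , drop = FALSE]
  rownames(links) <- NULL
  result$links <- links
  result$link_weight <- if (nrow(links)) mean(links$c_peak) else NA_real_
  result$n_connections <- nrow(links)
  result$threshold <- threshold
  result
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
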