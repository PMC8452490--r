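#' Generative phenotype parameters for the well simulator
#'
#' The simulator emulates the three activity components of an MEA well:
#' rhythmic multi-channel network bursts (a gamma-renewal onset process with
#' mean interval `60/nb_rate` and interval CV `nb_cv`; during each event a
#' random subset of channels, chosen with probability `participation`, emits
#' Poisson spikes whose rate follows a right-skewed gamma-density envelope
#' over `nb_duration`), independent single-channel bursts outside the
#' network events, and asynchronous Poisson background spikes.
#'
#' The envelope is a gamma density with shape `1 + rise_tau/decay_tau` and
#' scale `decay_tau`, truncated at `nb_duration`: its mode sits `rise_tau`
#' seconds after onset and its tail decays with time constant `decay_tau`,
#' matching the asymmetric rise/decay of recorded network bursts.
#'
#' @param nb_rate Network bursts per minute.
#' @param nb_cv CV of inter-network-burst intervals (0 = perfectly regular).
#' @param nb_duration Network-burst emission window, seconds.
#' @param rise_tau,decay_tau Envelope rise/decay time constants, seconds.
#' @param participation Probability that a channel joins a network burst.
#' @param intra_nb_rate Mean within-event firing rate of a participating
#'   channel, spikes/s.
#' @param channel_burst_rate Single-channel bursts per minute outside
#'   network bursts.
#' @param background_rate Asynchronous background rate per channel,
#'   spikes/s.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal spike-amplitude model
#'   (microvolts).
#' @return An object of class `phenotype_params`.
#' @export
phenotype_params <- function(nb_rate = 3.2, nb_cv = 0.3, nb_duration = 1.28,
                             rise_tau = 0.3, decay_tau = 0.3,
                             participation = 0.9, intra_nb_rate = 50,
                             channel_burst_rate = 1.3, background_rate = 0.2,
                             amplitude_meanlog = log(30),
                             amplitude_sdlog = 0.3) {
  if (nb_rate < 0 || intra_nb_rate < 0 || channel_burst_rate < 0 ||
      background_rate < 0 || nb_cv < 0) {
    stop("rates and nb_cv must be non-negative")
  }
  if (participation < 0 || participation > 1) {
    stop("participation must be in [0, 1]")
  }
  if (nb_rate > 0 && nb_duration <= 0) stop("nb_duration must be positive")
  structure(as.list(environment()), class = "phenotype_params")
}

#' Preset phenotypes
#'
#' `control` is calibrated so the analysis pipeline lands near the pooled
#' control values of mature networks (about 3.5 spikes/s, 4.8 bursts/min,
#' 3.2 network bursts/min with ~1.28 s duration).  `melas_like` shifts only
#' the MELAS directions (lower firing and network bursting, more random
#' spikes, shorter channel bursts, weaker correlation); `ks_like` shifts the
#' KS directions (fewer but longer network bursts with a slower decay).
#'
#' @param name `"control"`, `"melas_like"` or `"ks_like"`.
#' @return A [phenotype_params()].
#' @export
preset_phenotype <- function(name = c("control", "melas_like", "ks_like")) {
  name <- match.arg(name)
  switch(name,
    control = phenotype_params(),
    melas_like = phenotype_params(
      nb_rate = 1.6, nb_cv = 0.4, nb_duration = 1.1,
      rise_tau = 0.28, decay_tau = 0.28, participation = 0.55,
      intra_nb_rate = 20, channel_burst_rate = 1.0, background_rate = 0.4),
    ks_like = phenotype_params(
      nb_rate = 1.5, nb_cv = 0.35, nb_duration = 2.2,
      rise_tau = 0.3, decay_tau = 0.55, participation = 0.9,
      intra_nb_rate = 30, channel_burst_rate = 0.6, background_rate = 0.15)
  )
}

# draw spike offsets within one network burst from the truncated gamma
# envelope
.envelope_draw <- function(n, params) {
  shape <- 1 + params$rise_tau / params$decay_tau
  scale <- params$decay_tau
  u_max <- stats::pgamma(params$nb_duration, shape, scale = scale)
  stats::qgamma(stats::runif(n, 0, u_max), shape, scale = scale)
}

#' Simulate one well with ground truth
#'
#' Identical seed gives identical output.  Spike times are quantised to the
#' sampling grid (and de-duplicated), as threshold-detected spikes would be.
#'
#' @param params A [phenotype_params()].
#' @param duration Recording duration, seconds (default 600 = 10 min).
#' @param seed Integer seed (mandatory).
#' @param metadata Optional [recording_metadata()] to attach.
#' @param sampling_rate Sampling grid, Hz.
#' @return List with `recording` (a [well_recording()]) and `ground_truth`:
#'   the generative parameters plus realised values (`nb_onsets`,
#'   `nb_duration`, per-component spike counts `n_nb_spikes`,
#'   `n_burst_spikes`, `n_background_spikes`, realised `true_nbr`,
#'   `true_nbd`, `true_cv_nibi`, `true_mfr` and the number of grid-collision
#'   spikes dropped).
#' @export
simulate_well <- function(params, duration = 600, seed,
                          metadata = recording_metadata(),
                          sampling_rate = 10000) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(inherits(params, "phenotype_params"), duration > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # network-burst onsets: gamma renewal process
  mu <- if (params$nb_rate > 0) 60 / params$nb_rate else Inf
  onsets <- numeric(0)
  if (is.finite(mu)) {
    t <- stats::runif(1, 0, mu)   # stationary start phase
    while (t + params$nb_duration <= duration) {
      onsets <- c(onsets, t)
      dt <- if (params$nb_cv == 0) mu else
        stats::rgamma(1, shape = 1 / params$nb_cv^2,
                      scale = mu * params$nb_cv^2)
      t <- t + dt
    }
  }

  ch_times <- vector("list", 12L)
  for (k in seq_len(12L)) ch_times[[k]] <- list(nb = numeric(0),
                                                cb = numeric(0),
                                                bg = numeric(0))
  # network-burst spikes
  for (t0 in onsets) {
    joins <- stats::runif(12) < params$participation
    for (k in which(joins)) {
      n <- stats::rpois(1, params$intra_nb_rate * params$nb_duration)
      if (n > 0) {
        ch_times[[k]]$nb <- c(ch_times[[k]]$nb, t0 + .envelope_draw(n, params))
      }
    }
  }
  # independent single-channel bursts (6 spikes at ~60 Hz)
  for (k in seq_len(12L)) {
    n_cb <- stats::rpois(1, params$channel_burst_rate * duration / 60)
    if (n_cb > 0) {
      starts <- stats::runif(n_cb, 0, max(duration - 0.2, 0))
      for (s in starts) {
        isis <- stats::rexp(5, rate = 60)
        ch_times[[k]]$cb <- c(ch_times[[k]]$cb,
                              s + cumsum(c(0, pmin(isis, 0.09))))
      }
    }
    # Poisson background
    n_bg <- stats::rpois(1, params$background_rate * duration)
    ch_times[[k]]$bg <- stats::runif(n_bg, 0, duration)
  }

  trains <- vector("list", 12L)
  n_emitted <- c(nb = 0L, cb = 0L, bg = 0L)
  dropped <- 0L
  for (k in seq_len(12L)) {
    comp <- ch_times[[k]]
    n_emitted <- n_emitted + c(nb = length(comp$nb), cb = length(comp$cb),
                               bg = length(comp$bg))
    ts <- c(comp$nb, comp$cb, comp$bg)
    ts <- ts[ts >= 0 & ts <= duration]
    ts <- sort(unique(round(ts * sampling_rate))) / sampling_rate
    ts <- ts[ts <= duration]
    dropped <- dropped +
      (length(comp$nb) + length(comp$cb) + length(comp$bg) - length(ts))
    amp <- -stats::rlnorm(length(ts), params$amplitude_meanlog,
                          params$amplitude_sdlog)
    trains[[k]] <- spike_train(ts, amp, k)
  }

  rec <- well_recording(trains, duration = duration,
                        sampling_rate = sampling_rate, metadata = metadata)
  gaps <- if (length(onsets) >= 2) diff(onsets) - params$nb_duration else
    numeric(0)
  gt <- list(
    params = params, seed = seed, duration = duration,
    nb_onsets = onsets, nb_duration = params$nb_duration,
    n_nb_spikes = unname(n_emitted["nb"]),
    n_burst_spikes = unname(n_emitted["cb"]),
    n_background_spikes = unname(n_emitted["bg"]),
    n_dropped = dropped,
    true_nbr = length(onsets) / duration * 60,
    true_nbd = params$nb_duration,
    true_cv_nibi = if (length(gaps) >= 2) stats::sd(gaps) / mean(gaps) else
      NA_real_,
    true_mfr = well_spike_count(rec) / duration / 12
  )
  list(recording = rec, ground_truth = gt)
}

#' Render a spike train as a raw extracellular trace
#'
#' Superimposes a biphasic spike template (sharp negative deflection followed
#' by a smaller positive rebound) on white Gaussian noise, placing the
#' template's negative extremum at each spike's sample.  Used to exercise the
#' spike-detection front end against known ground truth.
#'
#' @param train A [spike_train()] with the true spike times.
#' @param duration Trace duration, seconds.
#' @param sampling_rate Hz.
#' @param noise_sd Noise standard deviation, microvolts.
#' @param snr Peak template amplitude in units of `noise_sd`.
#' @param seed Integer seed for the noise.
#' @return A [raw_trace()].
#' @export
render_raw_trace <- function(train, duration, sampling_rate = 10000,
                             noise_sd = 3, snr = 10, seed) {
  if (missing(seed)) stop("a seed is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- round(duration * sampling_rate)
  x <- stats::rnorm(n, 0, noise_sd)
  template <- snr * noise_sd * c(0.15, -0.35, -1, 0.45, 0.25, 0.1)
  peak_at <- 3L                     # negative extremum position in template
  for (t in train$timestamps) {
    i0 <- round(t * sampling_rate) + 1L - (peak_at - 1L)
    for (j in seq_along(template)) {
      k <- i0 + j - 1L
      if (k >= 1L && k <= n) x[k] <- x[k] + template[j]
    }
  }
  raw_trace(x, sampling_rate, train$electrode_id)
}

#' Experiment design for a simulated cohort
#'
#' Batch effects are multiplicative log-normal multipliers on the rate
#' parameters (`nb_rate`, `intra_nb_rate`, `background_rate`): each MEA
#' batch and each astrocyte batch draws one multiplier with log-scale SD
#' `batch_effect_sd`, and each well draws an additional multiplier with SD
#' `well_noise_sd`.  Wells are assigned to batches in a balanced rotation.
#'
#' @param lines Named list of [phenotype_params()], one per line.
#' @param wells_per_line Wells per line (>= 1).
#' @param mea_batches,astro_batches Number of batch levels.
#' @param batch_effect_sd Log-scale SD of the per-batch multipliers.
#' @param well_noise_sd Log-scale SD of the per-well multiplier.
#' @param duration Recording duration, seconds.
#' @param DIV Days in vitro stamped on the recordings.
#' @param seed Integer seed (mandatory).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(lines = list(control = preset_phenotype()),
                              wells_per_line = 12, mea_batches = 2,
                              astro_batches = 1, batch_effect_sd = 0.25,
                              well_noise_sd = 0.25, duration = 600,
                              DIV = 30L, seed) {
  if (missing(seed)) stop("a seed is required")
  if (wells_per_line < 1) stop("wells_per_line must be >= 1")
  if (duration <= 0) stop("duration must be positive")
  structure(list(lines = lines, wells_per_line = wells_per_line,
                 mea_batches = mea_batches, astro_batches = astro_batches,
                 batch_effect_sd = batch_effect_sd,
                 well_noise_sd = well_noise_sd, duration = duration,
                 DIV = as.integer(DIV), seed = as.integer(seed)),
            class = "experiment_design")
}

# apply a multiplicative factor to the rate parameters of a phenotype
.scale_rates <- function(params, mult) {
  params$nb_rate <- params$nb_rate * mult
  params$intra_nb_rate <- params$intra_nb_rate * mult
  params$background_rate <- params$background_rate * mult
  params
}

#' Simulate a multiwell experiment
#'
#' Generates every well of the design, optionally writes the dataset to
#' disk (portable peak-train files, `metadata.csv`, `ground_truth.csv`),
#' and returns the recordings with their realised ground truth.  The same
#' seed reproduces the dataset byte for byte.
#'
#' @param design An [experiment_design()].
#' @param dir Optional output directory (created if needed).
#' @return List with `recordings` (list of [well_recording()]),
#'   `ground_truth` (data frame, one row per well) and `dir`.
#' @export
simulate_experiment <- function(design, dir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(design$seed)
  mea_mult <- exp(stats::rnorm(design$mea_batches, 0, design$batch_effect_sd))
  astro_mult <- exp(stats::rnorm(design$astro_batches, 0,
                                 design$batch_effect_sd))
  n_total <- length(design$lines) * design$wells_per_line
  well_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  well_mult <- exp(stats::rnorm(n_total, 0, design$well_noise_sd))

  recordings <- list()
  gt_rows <- list()
  idx <- 0L
  for (ln in names(design$lines)) {
    base_params <- design$lines[[ln]]
    status <- if (grepl("melas", ln, ignore.case = TRUE)) "MELAS" else
      if (grepl("ks", ln, ignore.case = TRUE)) "KS" else "control"
    for (w in seq_len(design$wells_per_line)) {
      idx <- idx + 1L
      mb <- ((w - 1L) %% design$mea_batches) + 1L
      ab <- (((w - 1L) %/% design$mea_batches) %% design$astro_batches) + 1L
      mult <- mea_mult[mb] * astro_mult[ab] * well_mult[idx]
      params_w <- .scale_rates(base_params, mult)
      meta <- recording_metadata(
        well_id = sprintf("%s_w%02d", ln, w), line_id = ln,
        DIV = design$DIV, mea_batch = paste0("MB", mb),
        astro_batch = paste0("AB", ab), disease_status = status)
      sim <- simulate_well(params_w, duration = design$duration,
                           seed = well_seeds[idx], metadata = meta)
      recordings[[meta$well_id]] <- sim$recording
      gt <- sim$ground_truth
      gt_rows[[meta$well_id]] <- data.frame(
        well_id = meta$well_id, line_id = ln, DIV = design$DIV,
        mea_batch = meta$mea_batch, astro_batch = meta$astro_batch,
        batch_multiplier = mult, nb_rate = params_w$nb_rate,
        intra_nb_rate = params_w$intra_nb_rate,
        background_rate = params_w$background_rate,
        true_nbr = gt$true_nbr, true_nbd = gt$true_nbd,
        true_cv_nibi = gt$true_cv_nibi, true_mfr = gt$true_mfr,
        n_nb_spikes = gt$n_nb_spikes, n_burst_spikes = gt$n_burst_spikes,
        n_background_spikes = gt$n_background_spikes,
        stringsAsFactors = FALSE)
    }
  }
  ground_truth <- do.call(rbind, gt_rows)
  rownames(ground_truth) <- NULL

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(recordings)) {
      write_peak_trains(recordings[[id]], file.path(dir, paste0(id, ".csv")),
                        dialect = "portable_csv")
    }
    write_metadata_table(lapply(recordings, `[[`, "metadata"),
                         file.path(dir, "metadata.csv"))
    utils::write.csv(ground_truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(recordings = recordings, ground_truth = ground_truth, dir = dir)
}
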