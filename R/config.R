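#' Default pipeline configuration
#'
#' A nested list mirroring [analysis_settings()], serialisable to YAML.
#' Every numeric value equals the documented stage default.
#'
#' @return Named list of stage blocks.
#' @export
default_config <- function() {
  settings_to_config(analysis_settings(), seed = 1L)
}

#' Convert analysis settings to a serialisable config list
#' @param settings An [analysis_settings()].
#' @param seed Base seed recorded with the config.
#' @return Named list.
#' @export
settings_to_config <- function(settings, seed = 1L) {
  list(
    seed = as.integer(seed),
    spike_detection = list(threshold_sd = 4.5, dead_time_s = 0.002,
                           hp_cutoff_hz = 100, hp_order = 2,
                           lp_cutoff_hz = 3500, lp_order = 4),
    burst_detection = list(max_isi_s = settings$burst$max_isi,
                           min_spikes = settings$burst$min_spikes),
    network_burst_detection = list(
      bin_width_s = settings$network$bin_width,
      baseline_count = settings$network$baseline_count,
      peak_fraction = settings$network$peak_fraction,
      rate_threshold = settings$network$rate_threshold,
      min_channel_fraction = settings$network$min_channel_fraction,
      merge_gap_s = settings$network$merge_gap,
      min_nb_spikes = settings$network$min_nb_spikes),
    shape = list(bin_width_s = settings$shape_bin_width,
                 window_s = settings$shape_window,
                 lo_frac = settings$shape_lo_frac),
    connectivity = list(window_s = settings$connectivity$window,
                        bin_s = settings$connectivity$bin,
                        n_surrogates = settings$connectivity$n_surrogates,
                        alpha = settings$connectivity$alpha,
                        jitter_s = settings$connectivity$jitter,
                        enabled = settings$do_connectivity),
    qc = list(min_mfr = settings$qc$min_mfr, min_br = settings$qc$min_br,
              min_nbr = settings$qc$min_nbr,
              min_active_fraction = settings$qc$min_active_fraction,
              min_nb_participation = settings$qc$min_nb_participation,
              active_rate = settings$qc$active_rate,
              require_nb_at_div27 = settings$qc$require_nb_at_div27)
  )
}

#' Build analysis settings from a config list
#' @param config Nested list as produced by [default_config()] /
#'   [read_config()].  Missing blocks fall back to the defaults.
#' @return An [analysis_settings()].
#' @export
config_to_settings <- function(config) {
  d <- default_config()
  get2 <- function(block, key) {
    (config[[block]] %||% list())[[key]] %||% d[[block]][[key]]
  }
  analysis_settings(
    burst = burst_settings(get2("burst_detection", "max_isi_s"),
                           get2("burst_detection", "min_spikes")),
    network = nb_settings(
      bin_width = get2("network_burst_detection", "bin_width_s"),
      baseline_count = get2("network_burst_detection", "baseline_count"),
      peak_fraction = get2("network_burst_detection", "peak_fraction"),
      rate_threshold = (config[["network_burst_detection"]] %||%
                          list())[["rate_threshold"]],
      min_channel_fraction = get2("network_burst_detection",
                                  "min_channel_fraction"),
      merge_gap = get2("network_burst_detection", "merge_gap_s"),
      min_nb_spikes = get2("network_burst_detection", "min_nb_spikes")),
    connectivity = conn_settings(
      window = get2("connectivity", "window_s"),
      bin = get2("connectivity", "bin_s"),
      n_surrogates = get2("connectivity", "n_surrogates"),
      alpha = get2("connectivity", "alpha"),
      jitter = get2("connectivity", "jitter_s")),
    qc = qc_settings(
      min_mfr = get2("qc", "min_mfr"), min_br = get2("qc", "min_br"),
      min_nbr = get2("qc", "min_nbr"),
      min_active_fraction = get2("qc", "min_active_fraction"),
      min_nb_participation = get2("qc", "min_nb_participation"),
      active_rate = get2("qc", "active_rate"),
      require_nb_at_div27 = get2("qc", "require_nb_at_div27")),
    shape_bin_width = get2("shape", "bin_width_s"),
    shape_window = get2("shape", "window_s"),
    shape_lo_frac = get2("shape", "lo_frac"),
    do_connectivity = isTRUE(get2("connectivity", "enabled"))
  )
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @return For `read_config`, the config list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config Config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12)
  invisible(path)
}
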