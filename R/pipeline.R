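#' Analysis settings for the full pipeline
#'
#' Bundles the per-stage settings.  Every numeric default is the documented
#' package default for that stage; serialise the bundle with the results it
#' produced so an analysis can be reproduced exactly.
#'
#' @param burst A [burst_settings()].
#' @param network An [nb_settings()].
#' @param connectivity A [conn_settings()].
#' @param qc A [qc_settings()].
#' @param shape_bin_width Network-burst shape bin width, seconds.
#' @param shape_window Shape window from burst onset, seconds.
#' @param shape_lo_frac Rise/decay threshold fraction of the shape peak.
#' @param do_connectivity Compute the connectivity stage (the slowest one).
#' @return An object of class `analysis_settings`.
#' @export
analysis_settings <- function(burst = burst_settings(),
                              network = nb_settings(),
                              connectivity = conn_settings(),
                              qc = qc_settings(),
                              shape_bin_width = 0.005, shape_window = 3,
                              shape_lo_frac = 0.1, do_connectivity = TRUE) {
  structure(list(burst = burst, network = network,
                 connectivity = connectivity, qc = qc,
                 shape_bin_width = shape_bin_width,
                 shape_window = shape_window, shape_lo_frac = shape_lo_frac,
                 do_connectivity = do_connectivity),
            class = "analysis_settings")
}

#' Extract the 17 per-well parameters from one recording
#'
#' Runs burst detection, network-burst detection, shape analysis and (when
#' enabled) connectivity on a single well and returns one parameter-table
#' row.  Channel-level parameters follow the all-electrode rule: rates are
#' averaged over all 12 electrode slots; duration-type means (BD, BSR, IBI)
#' are averaged over the electrodes on which they are defined.
#'
#' @param well A [well_recording()].
#' @param settings An [analysis_settings()].
#' @param seed Seed for the connectivity surrogate ensemble.
#' @return A one-row data frame: metadata columns, the 17 parameters, and
#'   the QC metrics `active_fraction` and `nb_channel_fraction`.  A
#'   `shapes` attribute carries the well's [network_burst_shape()] (or
#'   `NULL`).
#' @export
analyze_well <- function(well, settings = analysis_settings(), seed = 1L) {
  m <- well$metadata
  dur <- well$duration

  bursts <- detect_bursts_well(well, settings$burst)
  ch_stats <- lapply(seq_len(12L), function(k) {
    channel_burst_statistics(bursts[bursts$electrode_id == k, , drop = FALSE],
                             dur)
  })
  pick <- function(f) vapply(ch_stats, `[[`, numeric(1), f)
  defined_mean <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else
    NA_real_
  BR <- mean(pick("BR"))                      # silent electrodes count as 0
  BD <- defined_mean(pick("BD"))
  BSR <- defined_mean(pick("BSR"))
  IBI <- defined_mean(pick("IBI"))
  MFR <- mean_firing_rate(well)
  PRS <- percentage_random_spikes(well, bursts)$PRS

  nbs <- detect_network_bursts(well, settings$network)
  nb_stats <- network_burst_statistics(nbs, dur)
  nb_part <- if (nrow(nbs)) mean(nbs$n_channels) / 12 else 0

  RT <- DT <- shape_fwhm <- NA_real_
  shape <- NULL
  if (nrow(nbs)) {
    shape <- network_burst_shape(well, nbs, settings$shape_bin_width,
                                 settings$shape_window)
    rd <- rise_decay_times(shape, settings$shape_lo_frac)
    RT <- rd$RT; DT <- rd$DT
    half <- rise_decay_times(shape, 0.5)
    if (all(half$defined)) shape_fwhm <- half$RT + half$DT
  }

  C0 <- C_peak <- link_weight <- NA_real_
  n_connections <- NA_integer_
  if (isTRUE(settings$do_connectivity)) {
    conn <- pairwise_connectivity(well, settings$connectivity)
    off <- upper.tri(conn$c0_matrix)
    C0 <- mean(conn$c0_matrix[off])
    C_peak <- mean(conn$cpeak_matrix[off])
    conn <- functional_links(conn, well, seed = seed)
    link_weight <- conn$link_weight
    n_connections <- conn$n_connections
  }

  row <- data.frame(
    well_id = m$well_id, line_id = m$line_id, DIV = m$DIV,
    mea_batch = m$mea_batch, astro_batch = m$astro_batch, sex = m$sex,
    age = m$donor_age, status = m$disease_status, coating = m$coating,
    manual_exclude = m$manual_exclude,
    MFR = MFR, PRS = PRS, BR = BR, BD = BD, BSR = BSR, IBI = IBI,
    NBR = nb_stats$NBR, NBD = nb_stats$NBD, NIBI = nb_stats$NIBI,
    CV_NIBI = nb_stats$CV_NIBI, RT = RT, DT = DT, shape_fwhm = shape_fwhm,
    C0 = C0, C_peak = C_peak, link_weight = link_weight,
    n_connections = n_connections,
    active_fraction = active_electrode_fraction(well,
                                                settings$qc$active_rate),
    nb_channel_fraction = nb_part,
    stringsAsFactors = FALSE)
  attr(row, "shape") <- shape
  row
}

#' Run the full analysis pipeline
#'
#' Analyses every well (from a directory of portable peak-train files or an
#' in-memory list of recordings), applies QC, optionally pools the stable
#' developmental window, and writes the parameter table, QC report, batch
#' sufficiency report, the configuration used and a structured run log to
#' `out_dir`.  Deterministic given inputs, settings and seed.
#'
#' @param input Directory containing `*.csv` portable peak-train files, or a
#'   list of [well_recording()] objects.
#' @param settings An [analysis_settings()].
#' @param out_dir Optional output directory.
#' @param seed Base seed; each well's connectivity surrogate seed is derived
#'   from it deterministically.
#' @param pool_div Apply [pool_development_window()] (default TRUE).
#' @param div_lo,div_hi Developmental window bounds.
#' @return List with `table` (all wells, with `qc_included`/`qc_reasons`),
#'   `included` (QC-passing, pooled wells), `shapes` (named list of per-well
#'   shape profiles), `batch_check` and `log` (character vector, one JSON
#'   line per event).
#' @export
run_analyze <- function(input, settings = analysis_settings(), out_dir = NULL,
                        seed = 1L, pool_div = TRUE, div_lo = 27,
                        div_hi = 35) {
  if (is.character(input)) {
    files <- sort(list.files(input, pattern = "\\.csv$", full.names = TRUE))
    files <- files[!basename(files) %in% c("metadata.csv",
                                           "ground_truth.csv")]
    if (!length(files)) stop("no readable peak-train files in ", input)
    recordings <- lapply(files, read_peak_trains, dialect = "portable_csv")
  } else {
    recordings <- input
    if (!length(recordings)) stop("no recordings supplied")
  }

  log_lines <- character(0)
  log_event <- function(...) {
    fields <- list(...)
    json <- paste0("{", paste0('"', names(fields), '":"',
                               unlist(fields), '"', collapse = ","), "}")
    log_lines <<- c(log_lines, json)
  }

  rows <- list()
  shapes <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    row <- analyze_well(rec, settings, seed = seed + i)
    shapes[[row$well_id]] <- attr(row, "shape")
    attr(row, "shape") <- NULL
    rows[[i]] <- row
    log_event(event = "analyzed", well = row$well_id,
              spikes = well_spike_count(rec))
  }
  table <- do.call(rbind, rows)
  table <- qc_parameter_table(table, settings$qc)
  for (i in seq_len(nrow(table))) {
    if (!table$qc_included[i]) {
      log_event(event = "excluded", well = table$well_id[i],
                reasons = table$qc_reasons[i])
    } else {
      log_event(event = "included", well = table$well_id[i])
    }
  }

  included <- table[table$qc_included, , drop = FALSE]
  if (pool_div && nrow(included)) {
    included <- withCallingHandlers(
      pool_development_window(included, div_lo, div_hi),
      warning = function(w) {
        log_event(event = "pooling_warning", message = conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  if (!nrow(included)) {
    warning("all wells were excluded by QC; the included table is empty")
  }
  batch_check <- if (nrow(included)) batch_sufficiency_check(included) else
    NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_parameter_table(table, file.path(out_dir, "parameter_table.csv"))
    write_parameter_table(included,
                          file.path(out_dir, "parameter_table_included.csv"))
    utils::write.csv(table[, c("well_id", "qc_included", "qc_reasons")],
                     file.path(out_dir, "qc_report.csv"), row.names = FALSE)
    yaml::write_yaml(settings_to_config(settings, seed = seed),
                     file.path(out_dir, "config.yaml"), precision = 12)
    writeLines(log_lines, file.path(out_dir, "run_log.jsonl"))
  }
  list(table = table, included = included, shapes = shapes,
       batch_check = batch_check, log = log_lines)
}

#' Human-readable cohort report
#'
#' Per-line mean +/- SEM for every parameter, the parameter-stability (CV)
#' table and a QC summary.  SEM is undefined (`NA`) for a single well.
#'
#' @param result A [run_analyze()] result (or a parameter table).
#' @param file Optional path; when given the text report is also written
#'   there.
#' @return List with `per_line` (data frame `line_id, parameter, mean, sem,
#'   n`), `cv` ([parameter_cv()] output) and `qc_summary`; printed as text.
#' @export
run_report <- function(result, file = NULL) {
  table <- if (is.data.frame(result)) result else result$included
  full <- if (is.data.frame(result)) result else result$table
  params <- intersect(mea_parameters(), names(table))
  if (!nrow(table)) {
    txt <- "MEA cohort report: zero included wells."
    if (!is.null(file)) writeLines(txt, file)
    message(txt)
    return(invisible(list(per_line = NULL, cv = NULL,
                          qc_summary = "zero wells")))
  }
  rows <- list()
  for (ln in unique(table$line_id)) {
    sub <- table[table$line_id == ln, , drop = FALSE]
    for (p in params) {
      x <- sub[[p]][!is.na(sub[[p]])]
      rows[[paste(ln, p)]] <- data.frame(
        line_id = ln, parameter = p, mean = mean(x),
        sem = if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else
          NA_real_,
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  per_line <- do.call(rbind, rows)
  rownames(per_line) <- NULL
  cv <- parameter_cv(table)
  qc_summary <- sprintf("%d of %d wells included", nrow(table), nrow(full))

  txt <- c(sprintf("MEA cohort report (%s)", qc_summary), "")
  for (ln in unique(per_line$line_id)) {
    txt <- c(txt, sprintf("Line %s:", ln))
    sub <- per_line[per_line$line_id == ln, ]
    txt <- c(txt, sprintf("  %-14s %10.4g +/- %-8.3g (n=%d)", sub$parameter,
                          sub$mean, sub$sem, sub$n))
  }
  if (!is.null(file)) writeLines(txt, file)
  message(paste(txt, collapse = "\n"))
  invisible(list(per_line = per_line, cv = cv, qc_summary = qc_summary))
}
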