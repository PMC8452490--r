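#' Quality-control settings
#'
#' Defaults mirror the recommended inclusion criteria for control networks:
#' mean firing rate above 0.1 spike/s, burst rate above 0.4 bursts/min,
#' network-burst rate above 1 per minute, spikes on more than 80% of
#' electrodes, and more than 25% of channels participating in network
#' bursts.  The "active electrode" rate threshold (default 1 spike/min) is
#' an explicit assumption and is reported in every QC report.
#'
#' @param min_mfr Minimum mean firing rate, spikes/s.
#' @param min_br Minimum burst rate, bursts/min.
#' @param min_nbr Minimum network-burst rate, per minute.
#' @param min_active_fraction Minimum fraction of active electrodes.
#' @param min_nb_participation Minimum mean fraction of channels per network
#'   burst.
#' @param active_rate Rate at or above which an electrode counts as active,
#'   spikes/s (default 1/60, i.e. one spike per minute).
#' @param require_nb_at_div27 Exclude wells without network bursts at DIV 27.
#' @return An object of class `qc_settings`.
#' @export
qc_settings <- function(min_mfr = 0.1, min_br = 0.4, min_nbr = 1,
                        min_active_fraction = 0.8,
                        min_nb_participation = 0.25,
                        active_rate = 1 / 60,
                        require_nb_at_div27 = TRUE) {
  structure(list(min_mfr = min_mfr, min_br = min_br, min_nbr = min_nbr,
                 min_active_fraction = min_active_fraction,
                 min_nb_participation = min_nb_participation,
                 active_rate = active_rate,
                 require_nb_at_div27 = require_nb_at_div27),
            class = "qc_settings")
}

#' Fraction of active electrodes
#'
#' An electrode is active when its firing rate is at least `min_rate`
#' (boundary included).
#'
#' @param well A [well_recording()].
#' @param min_rate Activity threshold, spikes/s.
#' @return Fraction of the 12 electrode slots that are active.
#' @export
active_electrode_fraction <- function(well, min_rate = 1 / 60) {
  rates <- vapply(well$trains, n_spikes, integer(1)) / well$duration
  mean(rates >= min_rate)
}

#' Evaluate well-inclusion criteria
#'
#' Applies the five inclusion criteria plus, when the well's DIV is 27 and
#' the rule is enabled, the requirement that network bursts are present.
#' A metadata-level manual exclusion (operator judgement on cell density or
#' clumping, which cannot be computed from spike data) is honoured via the
#' `manual_exclude` field.
#'
#' Reason codes: `LOW_MFR`, `LOW_BR`, `LOW_NBR`, `LOW_ACTIVE_FRACTION`,
#' `LOW_NB_PARTICIPATION`, `NO_NB_AT_DIV27`, `MANUAL_EXCLUDE`.
#'
#' @param params Named list or one-row data frame with `MFR`, `BR`, `NBR`,
#'   `active_fraction`, `nb_channel_fraction`; optionally `DIV`, `well_id`,
#'   `manual_exclude`.
#' @param settings A [qc_settings()].
#' @return An object of class `qc_report`: list with `well_id`, `included`,
#'   `reasons` (character vector of failed-criterion codes), `metrics` and
#'   the settings used.  `included` is `TRUE` iff `reasons` is empty.
#' @export
well_inclusion <- function(params, settings = qc_settings()) {
  p <- as.list(params)
  reasons <- character(0)
  if (p$MFR < settings$min_mfr) reasons <- c(reasons, "LOW_MFR")
  if (p$BR < settings$min_br) reasons <- c(reasons, "LOW_BR")
  if (p$NBR < settings$min_nbr) reasons <- c(reasons, "LOW_NBR")
  if (p$active_fraction < settings$min_active_fraction) {
    reasons <- c(reasons, "LOW_ACTIVE_FRACTION")
  }
  if (p$nb_channel_fraction < settings$min_nb_participation) {
    reasons <- c(reasons, "LOW_NB_PARTICIPATION")
  }
  if (settings$require_nb_at_div27 && !is.null(p$DIV) && !is.na(p$DIV) &&
      p$DIV == 27 && p$NBR <= 0) {
    reasons <- c(reasons, "NO_NB_AT_DIV27")
  }
  if (isTRUE(p$manual_exclude)) reasons <- c(reasons, "MANUAL_EXCLUDE")
  structure(
    list(well_id = p$well_id %||% NA_character_,
         included = length(reasons) == 0, reasons = reasons,
         metrics = p[intersect(c("MFR", "BR", "NBR", "active_fraction",
                                 "nb_channel_fraction"), names(p))],
         settings = settings),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$well_id, if (x$included) "INCLUDED" else
    paste("EXCLUDED:", paste(x$reasons, collapse = ", ")), "\n")
  invisible(x)
}

#' Apply QC to every row of a parameter table
#'
#' @param table Parameter table (one row per well) with the metric columns
#'   required by [well_inclusion()].
#' @param settings A [qc_settings()].
#' @return The table with logical `qc_included` and character `qc_reasons`
#'   (`;`-separated codes) columns appended.
#' @export
qc_parameter_table <- function(table, settings = qc_settings()) {
  reports <- lapply(seq_len(nrow(table)), function(i) {
    well_inclusion(table[i, , drop = FALSE], settings)
  })
  table$qc_included <- vapply(reports, `[[`, logical(1), "included")
  table$qc_reasons <- vapply(reports, function(r) {
    paste(r$reasons, collapse = ";")
  }, character(1))
  table
}

#' Pool wells into the stable developmental window
#'
#' Network parameters are stable from DIV 27 onward, so cohort analyses pool
#' recordings from DIV 27 to 35; earlier recordings cluster away from the
#' mature networks and mixing them in introduces variation.  Rows outside
#' the window are dropped with a warning; mixed coating substrates within
#' the pooled data are retained but flagged, since pooling across coatings
#' can affect comparability.
#'
#' @param table Parameter table with `DIV` (and optionally `coating`)
#'   columns.
#' @param div_lo,div_hi Window bounds, inclusive.
#' @return The filtered table.
#' @export
pool_development_window <- function(table, div_lo = 27, div_hi = 35) {
  keep <- table$DIV >= div_lo & table$DIV <= div_hi
  if (any(!keep)) {
    warning(sum(!keep), " well(s) outside DIV ", div_lo, "-", div_hi,
            " discarded from the pooled window")
  }
  out <- table[keep, , drop = FALSE]
  if (!is.null(out$coating) && length(unique(out$coating)) > 1) {
    warning("pooled wells mix coating substrates (",
            paste(unique(out$coating), collapse = ", "),
            "); comparability may be affected")
  }
  rownames(out) <- NULL
  out
}

#' Check batch sufficiency per line
#'
#' Each condition should contribute at least 12 wells divided over at least
#' two MEA batches; fewer wells or a single batch yields a warning code.
#'
#' @param table Parameter table with `line_id` and `mea_batch` columns.
#' @param min_wells Minimum wells per line.
#' @param min_batches Minimum MEA batches per line.
#' @return Data frame with `line_id`, `n_wells`, `n_batches`, `warnings`
#'   (codes `LOW_N`, `SINGLE_BATCH`; empty string when sufficient).
#' @export
batch_sufficiency_check <- function(table, min_wells = 12, min_batches = 2) {
  lines <- unique(table$line_id)
  out <- data.frame(line_id = lines, n_wells = NA_integer_,
                    n_batches = NA_integer_, warnings = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    sel <- table$line_id == lines[i]
    nw <- sum(sel)
    nb <- length(unique(table$mea_batch[sel]))
    w <- character(0)
    if (nw < min_wells) w <- c(w, "LOW_N")
    if (nb < min_batches) w <- c(w, "SINGLE_BATCH")
    out$n_wells[i] <- nw
    out$n_batches[i] <- nb
    out$warnings[i] <- paste(w, collapse = ";")
  }
  out
}
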