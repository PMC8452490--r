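#' Read a peak-train file into a well recording
#'
#' Peak trains are per-electrode lists of spike times and amplitudes, the
#' portable unit of MEA data used throughout this package.  Two plain-text
#' dialects are supported:
#'
#' * `portable_csv` — this package's own dialect: a commented metadata header
#'   followed by `electrode,time_s,amplitude_uV` rows with times in seconds.
#' * `mcs_csv` — a sample-index dialect mirroring acquisition-system exports:
#'   `channel,sample_index,amplitude_uV` rows with channels named
#'   `ptrain_<k>` and sample indices at the stated sampling rate (10 kHz by
#'   default); indices are divided by the sampling rate to obtain seconds.
#'
#' Electrodes absent from the file become empty trains in the 12-slot grid,
#' with one warning listing the missing slots.
#'
#' @param path Path to the peak-train file.
#' @param dialect `"portable_csv"` or `"mcs_csv"`.
#' @return A [well_recording()].
#' @export
read_peak_trains <- function(path, dialect = c("portable_csv", "mcs_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak-train file does not exist: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], .dialect_signature(dialect))) {
    stop("format error: ", path, " is not a ", dialect, " peak-train file")
  }
  header <- .parse_header(lines)
  body <- lines[!startsWith(lines, "#")]
  tab <- if (length(body) > 1) {
    utils::read.csv(text = body, stringsAsFactors = FALSE)
  } else {
    NULL
  }

  if (dialect == "portable_csv") {
    fs <- as.numeric(header[["sampling_rate_hz"]] %||% "10000")
    duration <- as.numeric(header[["duration_s"]])
    meta <- .metadata_from_header(header)
    present <- as.integer(strsplit(header[["electrodes"]] %||% "", ",")[[1]])
    trains <- list()
    for (k in seq_len(12L)) {
      if (is.null(tab)) {
        ts <- numeric(0); amp <- numeric(0)
      } else {
        sel <- tab$electrode == k
        ts <- tab$time_s[sel]
        amp <- tab$amplitude_uV[sel]
      }
      has_amp <- length(ts) > 0 && !all(is.na(amp))
      trains[[k]] <- spike_train(ts, if (has_amp) amp else NULL, k)
    }
  } else {
    fs <- as.numeric(header[["sampling_rate_hz"]] %||% "10000")
    dur_samples <- as.numeric(header[["duration_samples"]])
    duration <- dur_samples / fs
    meta <- recording_metadata(well_id = header[["well_id"]] %||% basename(path))
    present <- if (!is.null(header[["electrodes"]])) {
      as.integer(strsplit(header[["electrodes"]], ",")[[1]])
    } else if (!is.null(tab)) {
      as.integer(sub("^ptrain_", "", unique(tab$channel)))
    } else {
      integer(0)
    }
    trains <- list()
    for (k in seq_len(12L)) {
      if (is.null(tab)) {
        ts <- numeric(0); amp <- numeric(0)
      } else {
        sel <- tab$channel == paste0("ptrain_", k)
        ts <- tab$sample_index[sel] / fs
        amp <- tab$amplitude_uV[sel]
      }
      has_amp <- length(ts) > 0 && !all(is.na(amp))
      trains[[k]] <- spike_train(ts, if (has_amp) amp else NULL, k)
    }
  }

  missing <- setdiff(seq_len(12L), present)
  if (length(missing) && length(present)) {
    warning("electrodes absent from ", basename(path), ": ",
            paste(missing, collapse = ", "), "; treated as empty trains")
  }
  well_recording(trains, duration = duration, sampling_rate = fs,
                 metadata = meta)
}

#' Write a well recording as a peak-train file
#'
#' Inverse of [read_peak_trains()]; `read_peak_trains(write_peak_trains(x))`
#' reproduces the recording (timestamps to 1e-9 s).  All 12 electrode slots
#' are always listed, so a silent electrode is distinguishable from a missing
#' one.
#'
#' @param rec A [well_recording()].
#' @param path Output path.
#' @param dialect `"portable_csv"` or `"mcs_csv"`.
#' @return `path`, invisibly.
#' @export
write_peak_trains <- function(rec, path,
                              dialect = c("portable_csv", "mcs_csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "well_recording"))
  m <- rec$metadata
  if (dialect == "portable_csv") {
    header <- c(
      .dialect_signature("portable_csv"),
      paste0("# duration_s=", format(rec$duration, digits = 15)),
      paste0("# sampling_rate_hz=", format(rec$sampling_rate, digits = 15)),
      paste0("# well_id=", m$well_id),
      paste0("# line_id=", m$line_id),
      paste0("# DIV=", m$DIV),
      paste0("# mea_batch=", m$mea_batch),
      paste0("# astro_batch=", m$astro_batch),
      paste0("# sex=", m$sex),
      paste0("# donor_age=", m$donor_age),
      paste0("# disease_status=", m$disease_status),
      paste0("# coating=", m$coating),
      paste0("# manual_exclude=", m$manual_exclude),
      paste0("# electrodes=", paste(seq_len(12L), collapse = ","))
    )
    rows <- "electrode,time_s,amplitude_uV"
    for (tr in rec$trains) {
      if (!length(tr$timestamps)) next
      amp <- if (is.null(tr$amplitudes)) rep(NA_real_, n_spikes(tr)) else
        tr$amplitudes
      rows <- c(rows, sprintf("%d,%.14f,%s", tr$electrode_id, tr$timestamps,
                              ifelse(is.na(amp), "NA", sprintf("%.6f", amp))))
    }
  } else {
    fs <- rec$sampling_rate
    header <- c(
      .dialect_signature("mcs_csv"),
      paste0("# sampling_rate_hz=", format(fs, digits = 15)),
      paste0("# duration_samples=", format(round(rec$duration * fs),
                                           scientific = FALSE)),
      paste0("# well_id=", m$well_id),
      paste0("# electrodes=", paste(seq_len(12L), collapse = ","))
    )
    rows <- "channel,sample_index,amplitude_uV"
    for (tr in rec$trains) {
      if (!length(tr$timestamps)) next
      amp <- if (is.null(tr$amplitudes)) rep(NA_real_, n_spikes(tr)) else
        tr$amplitudes
      rows <- c(rows,
                sprintf("ptrain_%d,%d,%s", tr$electrode_id,
                        round(tr$timestamps * fs),
                        ifelse(is.na(amp), "NA", sprintf("%.6f", amp))))
    }
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

.dialect_signature <- function(dialect) {
  switch(dialect,
         portable_csv = "# meaphenotype peak-train portable_csv v1",
         mcs_csv = "# mcs peak-train export v1")
}

.parse_header <- function(lines) {
  h <- lines[startsWith(lines, "# ") & grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)
  vals <- lapply(kv, function(x) paste(x[-1], collapse = "="))
  names(vals) <- vapply(kv, `[[`, "", 1L)
  vals
}

.metadata_from_header <- function(h) {
  recording_metadata(
    well_id = h[["well_id"]] %||% "well_1",
    line_id = h[["line_id"]] %||% "unknown",
    DIV = as.integer(h[["DIV"]] %||% "30"),
    mea_batch = h[["mea_batch"]] %||% "B1",
    astro_batch = h[["astro_batch"]] %||% "A1",
    sex = h[["sex"]] %||% "unknown",
    donor_age = suppressWarnings(as.numeric(h[["donor_age"]] %||% "NA")),
    disease_status = h[["disease_status"]] %||% "control",
    coating = h[["coating"]] %||% "unknown",
    manual_exclude = identical(h[["manual_exclude"]], "TRUE")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a well-metadata table
#'
#' Expects a CSV with columns `well_id, line_id, DIV, mea_batch, astro_batch,
#' sex, age, status, coating` (optional `manual_exclude`).  Coating accepts
#' the short codes `H` (human laminin) and `M` (mouse laminin) as well as the
#' full enumeration values.
#'
#' @param path CSV path.
#' @return A list of [recording_metadata()] objects, one per row.
#' @export
read_metadata_table <- function(path) {
  # colClasses: a bare "F" in the sex column must stay character, not logical
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("well_id", "line_id", "DIV", "mea_batch", "astro_batch",
                "sex", "age", "status", "coating")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("metadata table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!nrow(tab)) return(list())
  coat_map <- c(H = "human_laminin", M = "mouse_laminin",
                human_laminin = "human_laminin",
                mouse_laminin = "mouse_laminin", unknown = "unknown")
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    coat <- as.character(tab$coating[i])
    if (!coat %in% names(coat_map)) {
      stop("row ", i, ": invalid coating value '", coat, "'")
    }
    out[[i]] <- recording_metadata(
      well_id = tab$well_id[i], line_id = tab$line_id[i],
      DIV = as.integer(tab$DIV[i]),
      mea_batch = tab$mea_batch[i], astro_batch = tab$astro_batch[i],
      sex = as.character(tab$sex[i]),
      donor_age = suppressWarnings(as.numeric(tab$age[i])),
      disease_status = as.character(tab$status[i]),
      coating = coat_map[[coat]],
      manual_exclude = if ("manual_exclude" %in% names(tab))
        isTRUE(as.logical(tab$manual_exclude[i])) else FALSE
    )
  }
  out
}

#' Write a well-metadata table
#' @param metas List of [recording_metadata()] objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata_table <- function(metas, path) {
  tab <- do.call(rbind, lapply(metas, function(m) {
    data.frame(well_id = m$well_id, line_id = m$line_id, DIV = m$DIV,
               mea_batch = m$mea_batch, astro_batch = m$astro_batch,
               sex = m$sex, age = m$donor_age, status = m$disease_status,
               coating = m$coating, manual_exclude = m$manual_exclude)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a per-well parameter table as CSV
#'
#' @param table Data frame of per-well parameters plus metadata columns.
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_parameter_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
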