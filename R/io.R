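# File formats: FASTA sequences, CSV traces / I/V sets / events with JSON
# sidecars, JSON metrics tables and reports. Delimited files are
# comma-separated with a mandatory header carrying explicit units
# (time_s, current_pA, voltage_mV, conductance_nS).

read_csv_checked <- function(path, required_cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  for (col in required_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0) {
        stop(sprintf("%s: non-numeric value '%s' in column '%s', data row %d",
                     path, v[bad[1]], col, bad[1]))
      }
      df[[col]] <- num
    }
  }
  df
}

#' Read peptide sequences from a FASTA file
#'
#' Sequences are normalized to single upper-case strings (line wrapping and
#' case are FASTA formatting, not content).
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  names(out) <- vapply(recs, function(r) attr(r, "name"), character(1))
  out
}

#' Write peptide sequences to a FASTA file
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(unname(sequences)),
                      names = names(sequences), file.out = path)
  invisible(path)
}

#' Write a current trace to CSV with a JSON metadata sidecar
#'
#' The CSV holds columns `time_s` and `current_pA` at full precision; the
#' sidecar `<path>.json` holds voltage, sampling rate, salt and filter
#' history, so the round trip through [read_trace()] is lossless.
#'
#' @param trace a [current_trace()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  df <- data.frame(time_s = trace_times(trace), current_pA = trace$samples)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(voltage_mV = trace$holding_voltage,
               sampling_rate_Hz = trace$sampling_rate,
               salt = trace$salt,
               filter_history = trace$filter_history)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a current trace from CSV plus its JSON sidecar
#'
#' @param path CSV path written by [write_trace()] (sidecar expected at
#'   `<path>.json`).
#' @return a [current_trace()].
#' @export
read_trace <- function(path) {
  df <- read_csv_checked(path, c("time_s", "current_pA"))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  current_trace(df$current_pA, meta$sampling_rate_Hz, meta$voltage_mV,
                salt = meta$salt %||% "",
                filter_history = as.character(meta$filter_history %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an I/V point set from CSV
#'
#' @param path CSV with columns `voltage_mV`, `current_pA`, and optionally
#'   `level`.
#' @return data frame of I/V points.
#' @export
read_iv <- function(path) {
  df <- read_csv_checked(path, c("voltage_mV", "current_pA"))
  if (!"level" %in% names(df)) df$level <- "G1"
  df
}

#' Write an I/V point set to CSV
#' @param points I/V data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_iv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multimer metrics table from JSON or CSV
#'
#' @param path file with columns/fields `n`, `iptm`, `ptm`, `mean_plddt`,
#'   and optionally `round`.
#' @return a [multimer_metrics()] table.
#' @export
read_metrics <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read_csv_checked(path, c("n", "iptm", "ptm", "mean_plddt"))
  }
  multimer_metrics(df)
}

#' Write detected step events to CSV
#'
#' @param events a [step_events()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "step_events"))
  df <- data.frame(time_s = events$time,
                   delta_pA = events$delta_current,
                   delta_nS = events$delta_conductance)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON with a provenance block
#'
#' @param result named list of results.
#' @param path output path (or NULL to return the JSON string).
#' @param config named list of run configuration to record.
#' @param seed seed used for any randomness, recorded in provenance.
#' @param inputs character vector of input paths; their MD5 hashes are
#'   recorded.
#' @return the JSON string, invisibly if written to `path`.
#' @export
write_report <- function(result, path = NULL, config = list(), seed = NULL,
                         inputs = character()) {
  prov <- list(
    package = "porescribe",
    version = as.character(utils::packageVersion("porescribe")),
    config = config,
    seed = seed,
    input_hashes = if (length(inputs))
      stats::setNames(as.list(unname(tools::md5sum(inputs))), inputs)
    else NULL
  )
  json <- jsonlite::toJSON(list(result = result, provenance = prov),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
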