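# Serialization: tone sequences and surprisal traces as commented CSV, model
# configurations and experiment reports as JSON. Every artifact embeds the
# configuration and seed needed to regenerate it.

.TRACE_SCHEMA <- "drex-trace/1"
.SEQ_SCHEMA <- "drex-sequence/1"
.REPORT_SCHEMA <- "drex-report/1"

#' Read a tone sequence from CSV
#'
#' The CSV must contain a \code{tone_semitones} column, or a \code{tone_hz}
#' column which is converted via 12 log2(f / 440). A JSON sidecar (by default
#' \code{<path>.json}, if present) supplies annotations
#' (\code{deviant_positions}, \code{condition}, \code{transition_index},
#' \code{metadata}).
#'
#' @param path path to the CSV file.
#' @param sidecar optional explicit path to the annotation JSON.
#' @return a [tone_seq()].
#' @export
read_tone_seq <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("sequence file not found: ", path)
  df <- tryCatch(utils::read.csv(path, comment.char = "#"),
                 error = function(e) stop("could not parse CSV at ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty sequence file: ", path)
  tones <- if ("tone_semitones" %in% names(df)) {
    df$tone_semitones
  } else if ("tone_hz" %in% names(df)) {
    hz <- df$tone_hz
    if (!is.numeric(hz)) stop("non-numeric tone_hz column in ", path)
    hz_to_semitones(hz)
  } else stop("no tone_semitones or tone_hz column in ", path)
  if (!is.numeric(tones) || any(!is.finite(tones)))
    stop("non-numeric or non-finite tone values in ", path)
  if (is.null(sidecar)) {
    cand <- paste0(path, ".json")
    sidecar <- if (file.exists(cand)) cand else NA_character_
  }
  if (!is.na(sidecar) && file.exists(sidecar)) {
    ann <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    tone_seq(tones,
             deviant_positions = if (!is.null(ann$deviant_positions)) ann$deviant_positions else integer(0),
             condition = if (!is.null(ann$condition)) ann$condition else NA_character_,
             transition_index = if (!is.null(ann$transition_index)) ann$transition_index else NA_integer_,
             metadata = if (!is.null(ann$metadata)) ann$metadata else list())
  } else tone_seq(tones)
}

#' Write a tone sequence to CSV (with a JSON annotation sidecar)
#'
#' @param seq a [tone_seq()].
#' @param path output CSV path; annotations go to \code{<path>.json}.
#' @param sidecar write the annotation sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_tone_seq <- function(seq, path, sidecar = TRUE) {
  if (!inherits(seq, "tone_seq")) stop("seq must be a tone_seq")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema: ", .SEQ_SCHEMA), con)
  utils::write.csv(data.frame(tone_semitones = seq$tones), con, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(schema = .SEQ_SCHEMA,
           deviant_positions = seq$deviant_positions,
           condition = seq$condition,
           transition_index = seq$transition_index,
           metadata = seq$metadata),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
      na = "null")
  }
  invisible(path)
}

#' Write a surprisal trace to CSV
#'
#' Columns: \code{t, tone, surprisal, map_run_length, predictive_location,
#' predictive_scale}. Commented header lines carry the schema version and a
#' JSON echo of the configuration. Optionally writes the full per-tone belief
#' matrix as JSON.
#'
#' @param fit a [drex()] fit.
#' @param path output CSV path.
#' @param beliefs_json optional path for the belief-matrix JSON.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(fit, path, beliefs_json = NULL) {
  if (!inherits(fit, "drex")) stop("fit must be a drex object")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema: ", .TRACE_SCHEMA), con)
  writeLines(paste0("# config: ",
                    jsonlite::toJSON(config_to_list(fit$config),
                                     auto_unbox = TRUE, digits = NA)), con)
  utils::write.csv(data.frame(t = seq_along(fit$tones), tone = fit$tones,
                              surprisal = fit$surprisal,
                              map_run_length = fit$map_run_length,
                              predictive_location = fit$predictive_location,
                              predictive_scale = fit$predictive_scale),
                   con, row.names = FALSE)
  if (!is.null(beliefs_json)) {
    if (is.null(fit$beliefs)) stop("fit carries no belief matrix (keep_beliefs = FALSE)")
    jsonlite::write_json(list(schema = .TRACE_SCHEMA,
                              config = config_to_list(fit$config),
                              beliefs = fit$beliefs),
                         beliefs_json, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a surprisal trace written by [write_trace()]
#' @param path trace CSV path.
#' @return a data frame with the trace columns.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  utils::read.csv(path, comment.char = "#")
}

#' Write an experiment report (or list of reports) to JSON
#'
#' @param report a \code{drex_report} or a (possibly nested) list of them.
#' @param path output JSON path.
#' @param seed seed to record alongside the report.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, seed = NA_integer_) {
  strip <- function(r) {
    if (inherits(r, "drex_report")) {
      list(experiment = r$experiment, statistic_name = r$statistic_name,
           statistic = r$statistic, df = r$df, p_value = r$p_value,
           direction = r$direction, descriptives = r$descriptives,
           config = if (!is.null(r$config)) config_to_list(r$config) else NULL,
           base_seed = r$base_seed)
    } else if (is.list(r)) lapply(r, strip) else r
  }
  jsonlite::write_json(list(schema = .REPORT_SCHEMA, seed = seed,
                            report = strip(report)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(path)
}
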