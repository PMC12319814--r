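# Plain-text exchange formats: BIDS-style events TSV per run, parcellated
# BOLD TSV (frames x parcels) with a JSON sidecar, model-series TSV and
# map TSV. "n/a" encodes missing values in events files, per the BIDS
# convention.

na_str <- function(x, digits = 6) {
  ifelse(is.na(x), "n/a", formatC(x, digits = digits, format = "fg"))
}

#' Write a run's trials as a BIDS-style events TSV
#'
#' Columns: `onset` (s), `duration` (s), `trial_type`, `response_time` (s
#' or "n/a"), `correct` (0/1), `ssd` (s or "n/a"). When the run carries
#' generator ground truth, a `*_truth.tsv` sidecar with `true_state` and a
#' JSON of the design parameters are written alongside.
#'
#' @param run A trial data frame (one run).
#' @param path Output TSV path.
#' @param design Optional [sst_design()] written to a JSON sidecar.
#' @param duration_s Stimulus duration written to the `duration` column.
#' @return `path`, invisibly.
#' @export
write_sst_events <- function(run, path, design = NULL, duration_s = 1) {
  df <- data.frame(
    onset = formatC(run$onset_s, digits = 6, format = "fg"),
    duration = duration_s,
    trial_type = run$trial_type,
    response_time = na_str(run$rt_ms / 1000),
    correct = as.integer(run$correct),
    ssd = na_str(run$ssd_ms / 1000)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$true_state)) {
    utils::write.table(data.frame(true_state = run$true_state),
                       sub("\\.tsv$", "_truth.tsv", path), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(design)) {
    jsonlite::write_json(unclass(design),
                         sub("\\.tsv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a BIDS-style events TSV back into a trial table
#'
#' @param path Events TSV path written by [write_sst_events()] (or any
#'   file with the same columns).
#' @return A trial data frame with `index`, `trial_type`, `onset_s`,
#'   `rt_ms`, `responded`, `correct`, `ssd_ms`, and `true_state` if a truth
#'   sidecar exists.
#' @export
read_sst_events <- function(path) {
  df <- utils::read.delim(path, na.strings = "n/a")
  out <- data.frame(
    index = seq_len(nrow(df)) - 1L,
    trial_type = df$trial_type,
    onset_s = df$onset,
    rt_ms = df$response_time * 1000,
    responded = !is.na(df$response_time),
    correct = df$correct == 1,
    ssd_ms = df$ssd * 1000,
    stringsAsFactors = FALSE
  )
  truth <- sub("\\.tsv$", "_truth.tsv", path)
  if (file.exists(truth)) {
    out$true_state <- utils::read.delim(truth)$true_state
  }
  out
}

#' Write a parcellated BOLD run as TSV plus JSON sidecar
#'
#' The TSV holds frames x parcels values; the sidecar records `tr_s`,
#' `t0_s` and the generating coupling when known. Confounds, if present,
#' go to a `*_confounds.tsv` next to the signal.
#'
#' @param run A [bold_run()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bold_run <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  m <- t(run$signal)
  colnames(m) <- paste0("parcel", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(tr_s = run$tr_s, t0_s = run$t0_s, coupling = run$coupling),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE, digits = NA,
    null = "null")
  if (!is.null(run$confounds)) {
    utils::write.table(as.data.frame(run$confounds),
                       sub("\\.tsv$", "_confounds.tsv", path), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a parcellated BOLD run written by [write_bold_run()]
#'
#' @param path TSV path.
#' @return A [bold_run()].
#' @export
read_bold_run <- function(path) {
  m <- as.matrix(utils::read.delim(path))
  side <- sub("\\.tsv$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(tr_s = 0.8, t0_s = 0, coupling = NULL)
  cpath <- sub("\\.tsv$", "_confounds.tsv", path)
  confounds <- if (file.exists(cpath)) as.matrix(utils::read.delim(cpath))
               else NULL
  bold_run(t(m), tr_s = meta$tr_s, confounds = confounds,
           coupling = meta$coupling,
           t0_s = if (is.null(meta$t0_s)) 0 else meta$t0_s)
}

#' Write a subject's model series as TSV
#'
#' One row per trial: `trial`, `run`, `onset_s` and one column per model
#' series supplied.
#'
#' @param series_list Named list of [attention_series()] objects over the
#'   same trials (e.g., `list(vtc = ..., zscore = ..., hmm = ...)`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_model_series <- function(series_list, path) {
  base <- series_list[[1]]
  df <- data.frame(trial = base$trial, run = base$run,
                   onset_s = base$onset_s)
  for (nm in names(series_list)) df[[nm]] <- series_list[[nm]]$value
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-unit statistic map as TSV
#'
#' @param map A `glm_result` or `group_map` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
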