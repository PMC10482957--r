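#' Write a session log to CSV with a JSON sidecar
#'
#' One row per trial with stable column names (`index`, `block`, `choice`,
#' `correct`, `rewarded`, `go_time`, `movement_onset_time`,
#' `outcome_tone_time`, `reward_time`); times are written as decimal seconds
#' with microsecond precision. The sidecar holds the task configuration and
#' policy parameters.
#'
#' @param session A `session_log`.
#' @param csv_path Output CSV path.
#' @param json_path Sidecar path; defaults to `csv_path` with a `.json`
#'   extension.
#' @return Invisibly, the two paths.
#' @export
write_session_log <- function(session, csv_path,
                              json_path = sub("\\.csv$", ".json", csv_path)) {
  tr <- session$trials
  out <- tr
  for (col in c("go_time", "movement_onset_time", "outcome_tone_time",
                "reward_time")) {
    out[[col]] <- ifelse(is.na(tr[[col]]), "",
                         sprintf("%.6f", tr[[col]]))
  }
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  meta <- list(config = unclass(session$config),
               params = unclass(session$params),
               block_boundaries = session$block_boundaries,
               seed = session$seed)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a session log written by [write_session_log()]
#'
#' @param csv_path Trial-table CSV path.
#' @param json_path Sidecar path; defaults alongside the CSV. When absent,
#'   config and params are `NULL`.
#' @return A `session_log`.
#' @export
read_session_log <- function(csv_path,
                             json_path = sub("\\.csv$", ".json", csv_path)) {
  tr <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  for (col in c("go_time", "movement_onset_time", "outcome_tone_time",
                "reward_time")) {
    tr[[col]] <- suppressWarnings(as.numeric(tr[[col]]))
  }
  tr$correct <- as.logical(tr$correct)
  tr$rewarded <- as.logical(tr$rewarded)
  config <- NULL
  params <- NULL
  boundaries <- integer(0)
  seed <- NA_integer_
  if (file.exists(json_path)) {
    meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    config <- structure(as.list(meta$config), class = "task_config")
    params <- structure(as.list(meta$params), class = "policy_params")
    boundaries <- as.integer(meta$block_boundaries)
    seed <- as.integer(meta$seed)
  }
  structure(list(trials = tr, config = config, params = params,
                 block_boundaries = boundaries, seed = seed),
            class = "session_log")
}
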