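trial_csv_columns <- c("participant", "block", "trial", "target_present",
                       "target_side", "cue_present", "cue_side", "soa_ms",
                       "congruency", "response", "rt_ms", "excluded",
                       "exclusion_reason")

#' Read and write the long-format trial CSV
#'
#' One row per trial with the fixed header
#' `participant,block,trial,target_present,target_side,cue_present,cue_side,soa_ms,congruency,response,rt_ms,excluded,exclusion_reason`.
#' Missing values (undefined SOA/congruency, absent RTs) are written as
#' empty fields; RTs are in milliseconds.
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns a
#'   tibble.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(trial_csv_columns, names(trials))
  if (length(missing_cols) > 0) {
    stop_validation(paste("Trial table lacks column(s):",
                          paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(trials[trial_csv_columns], path, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      participant = readr::col_integer(),
      block = readr::col_integer(),
      trial = readr::col_integer(),
      target_present = readr::col_logical(),
      target_side = readr::col_character(),
      cue_present = readr::col_logical(),
      cue_side = readr::col_character(),
      soa_ms = readr::col_double(),
      congruency = readr::col_character(),
      response = readr::col_character(),
      rt_ms = readr::col_double(),
      excluded = readr::col_logical(),
      exclusion_reason = readr::col_character()))
}
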