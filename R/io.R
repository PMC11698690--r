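#' Read and write session tables
#'
#' Sessions round-trip through a tidy CSV, one row per trial, with the
#' documented column set (`subject_id`, `group`, `trial`, `stake`,
#' `start_state`, `action`, `response_key`, `planet`, `base_reward`,
#' `delivered_reward`). Reading is strict: a missing column, an illegal
#' enum value (stake labels are lowercase `low`/`high`), or
#' non-consecutive trial indices raise an error naming the offending row.
#'
#' @param sessions Session tibble.
#' @param path CSV file path.
#' @return `read_sessions()` returns the validated session tibble;
#'   `write_sessions()` returns `path` invisibly.
#' @export
write_sessions <- function(sessions, path) {
  cols <- c("subject_id", "group", "trial", "stake", "start_state",
            "action", "response_key", "planet", "base_reward",
            "delivered_reward")
  missing <- setdiff(cols, names(sessions))
  if (length(missing)) {
    stop("session table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(sessions[, cols], path)
  invisible(path)
}

#' @rdname write_sessions
#' @param config A [task_config()] used for the structural validation of
#'   what was read.
#' @export
read_sessions <- function(path, config = task_config()) {
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      group = readr::col_character(),
      trial = readr::col_integer(),
      stake = readr::col_character(),
      start_state = readr::col_integer(),
      action = readr::col_character(),
      response_key = readr::col_character(),
      planet = readr::col_character(),
      base_reward = readr::col_double(),
      delivered_reward = readr::col_double()
    ),
    show_col_types = FALSE
  ))
  expected <- c("subject_id", "group", "trial", "stake", "start_state",
                "action", "response_key", "planet", "base_reward",
                "delivered_reward")
  missing <- setdiff(expected, names(raw))
  if (length(missing)) {
    stop("session file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_enum <- function(col, allowed) {
    bad <- which(!raw[[col]] %in% allowed)
    if (length(bad)) {
      stop("invalid value \"", raw[[col]][bad[1]], "\" in column `", col,
           "` at row ", bad[1], " of ", path, call. = FALSE)
    }
  }
  if (nrow(raw) > 0) {
    check_enum("stake", c("low", "high"))
    check_enum("action", action_labels())
    check_enum("planet", planet_labels())
    check_enum("response_key", key_labels())
    check_enum("start_state", 1:2)
    by_subj <- split(seq_len(nrow(raw)), raw$subject_id)
    for (id in names(by_subj)) {
      idx <- by_subj[[id]]
      tr <- raw$trial[idx]
      if (!identical(as.integer(tr), seq_along(tr) - 1L)) {
        stop("non-consecutive trial index for subject ", id, " at row ",
             idx[which(as.integer(tr) != seq_along(tr) - 1L)[1]], " of ",
             path, call. = FALSE)
      }
    }
  }
  raw
}

#' Write fit results for a cohort
#'
#' One CSV row per subject and model, with every parameter, the
#' log-likelihood and log-posterior, plus a JSON sidecar recording the
#' priors and seeds so the fit is auditable.
#'
#' @param fits Subject parameter table (from [fit_cohort()] or
#'   [fit_cohort_utility()]).
#' @param path CSV path; the sidecar is written next to it with a
#'   `.meta.json` suffix.
#' @param model Model label stored in the `model` column.
#' @param priors,seed Provenance recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(fits, path, model, priors = NULL,
                              seed = NULL) {
  out <- dplyr::mutate(fits, model = model, .after = "subject_id")
  readr::write_csv(out, path)
  meta <- list(model = model, seed = seed,
               priors = if (!is.null(priors)) unclass(priors) else NULL,
               n_subjects = nrow(fits))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
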