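#' Trial-table schema
#'
#' All behavioural data flow through a single long-format trial table: one
#' row per response event. Columns:
#'
#' * `observer_id` (chr), `task` (chr: naming | rating | afc)
#' * `true_material`, `true_transformation` (chr), `exemplar_id` (int)
#' * `block_scale` (chr): rating-scale label of the block (rating task only)
#' * `response_domain` (chr): for naming rows, whether the response answers
#'   the material or the transformation question
#' * `response_text` (chr, naming), `response_value` (dbl in \[0,1\],
#'   rating), `response_choice` (chr, afc) -- exactly one populated per row
#' * `repetition` (int): repeat index of the stimulus presentation
#'
#' @name trial_table
#' @keywords internal
NULL

trial_cols <- c("observer_id", "task", "true_material",
                "true_transformation", "exemplar_id", "block_scale",
                "response_domain", "response_text", "response_value",
                "response_choice", "repetition")

empty_trials <- function() {
  tibble::tibble(
    observer_id = character(), task = character(),
    true_material = character(), true_transformation = character(),
    exemplar_id = integer(), block_scale = character(),
    response_domain = character(), response_text = character(),
    response_value = double(), response_choice = character(),
    repetition = integer()
  )
}

#' Validate a trial table against a design
#'
#' Checks row-level invariants: known schema, category labels drawn from the
#' design's label sets, response fields matching the task (exactly one of
#' text / value / choice populated), and rating values within \[0, 1\].
#'
#' @param trials A trial-table data frame.
#' @param design An [experiment_design()].
#' @return `trials`, invisibly, as a tibble; errors describe the first
#'   offending rows by number.
#' @export
validate_trials <- function(trials, design) {
  trials <- tibble::as_tibble(trials)
  missing_cols <- setdiff(trial_cols, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(flag, what) {
    if (any(flag, na.rm = TRUE)) {
      stop("invalid trial table: ", what, " (rows ",
           paste(utils::head(which(flag), 5), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  bad_row(!trials$task %in% c("naming", "rating", "afc"), "unknown task")
  bad_row(!trials$true_material %in% design$materials,
          "unknown true_material label")
  bad_row(!trials$true_transformation %in% design$transformations,
          "unknown true_transformation label")
  bad_row(!is.na(trials$response_value) &
            (trials$response_value < 0 | trials$response_value > 1),
          "response_value outside [0, 1]")
  n_resp <- (!is.na(trials$response_text)) +
    (!is.na(trials$response_value)) + (!is.na(trials$response_choice))
  bad_row(n_resp != 1L, "each row must populate exactly one response field")
  bad_row(trials$task == "rating" & is.na(trials$response_value),
          "rating rows must populate response_value")
  bad_row(trials$task == "afc" & is.na(trials$response_choice),
          "afc rows must populate response_choice")
  bad_row(trials$task == "naming" & is.na(trials$response_text),
          "naming rows must populate response_text")
  bad_row(trials$task == "afc" &
            !trials$response_choice %in% design$transformations,
          "afc response_choice outside the transformation labels")
  bad_row(trials$task == "rating" &
            !trials$block_scale %in% design$rating_scales,
          "block_scale outside the design's rating scales")
  invisible(trials)
}

#' Read and write trial tables as CSV
#'
#' The on-disk format is UTF-8 comma-separated with a header and quoted
#' free text. `read_trials()` validates every row against the design on
#' the way in.
#'
#' @param path CSV file path.
#' @param design An [experiment_design()].
#' @return `read_trials()`: a validated trial tibble. `write_trials()`:
#'   `path`, invisibly.
#' @export
read_trials <- function(path, design) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  trials <- utils::read.csv(path, colClasses = "character",
                            na.strings = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(trial_cols, names(trials))
  if (length(missing_cols) > 0) {
    stop("CSV header does not match the trial schema; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials <- tibble::as_tibble(trials)[trial_cols]
  num <- suppressWarnings(as.numeric(trials$response_value))
  if (any(is.na(num) & !is.na(trials$response_value))) {
    stop("malformed response_value at row ",
         which(is.na(num) & !is.na(trials$response_value))[1], call. = FALSE)
  }
  for (col in c("exemplar_id", "repetition")) {
    v <- suppressWarnings(as.integer(trials[[col]]))
    if (any(is.na(v) & !is.na(trials[[col]]))) {
      stop("malformed ", col, " at row ",
           which(is.na(v) & !is.na(trials[[col]]))[1], call. = FALSE)
    }
    trials[[col]] <- v
  }
  trials$response_value <- num
  validate_trials(trials, design)
  trials
}

#' @rdname read_trials
#' @param trials A trial-table tibble.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[trial_cols], path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Check a trial table's coverage of the design grid
#'
#' Report-only comparison of per-observer stimulus counts in every
#' material x transformation cell against the design (e.g. 30 exemplars
#' per cell per observer for a full forced-choice run). Counts distinct
#' stimulus presentations, so naming-response splitting and rating blocks
#' do not distort coverage.
#'
#' @param trials A trial-table data frame (may be empty).
#' @param design An [experiment_design()].
#' @return A tibble with one row per observer x material x transformation
#'   cell: `n_stimuli`, `expected`, and `flag` (`"ok"`, `"missing"`, or
#'   `"count_mismatch"`). Attribute `n_flags` gives the number of
#'   non-`"ok"` rows.
#' @export
validate_design <- function(trials, design) {
  trials <- tibble::as_tibble(trials)
  observers <- unique(trials$observer_id)
  if (length(observers) == 0) observers <- default_observer_ids(design)
  grid <- tidyr::expand_grid(
    observer_id = observers,
    true_material = design$materials,
    true_transformation = design$transformations
  )
  counts <- trials |>
    dplyr::distinct(.data$observer_id, .data$true_material,
                    .data$true_transformation, .data$exemplar_id,
                    .data$repetition) |>
    dplyr::count(.data$observer_id, .data$true_material,
                 .data$true_transformation, name = "n_stimuli")
  expected <- design$exemplars_per_cell * design$repetitions
  report <- grid |>
    dplyr::left_join(counts,
                     by = c("observer_id", "true_material",
                            "true_transformation")) |>
    dplyr::mutate(
      n_stimuli = tidyr::replace_na(.data$n_stimuli, 0L),
      expected = expected,
      flag = dplyr::case_when(
        .data$n_stimuli == expected ~ "ok",
        .data$n_stimuli == 0L ~ "missing",
        TRUE ~ "count_mismatch"
      )
    )
  attr(report, "n_flags") <- sum(report$flag != "ok")
  report
}

#' Code free-naming responses into canonical categories
#'
#' Normalizes each `response_text`, optionally splits multiple responses on
#' a delimiter (observers were allowed to provide several names per
#' stimulus), and maps each piece through the lexicon. Unmapped strings are
#' coded `"OTHER"`; the original string is always retained in
#' `response_text`, so OTHER responses stay reportable verbatim. Each split
#' piece counts as one response event. Re-coding an already coded table is
#' a no-op.
#'
#' @param trials A naming trial table.
#' @param lex A [lexicon()].
#' @param delimiter String separating multiple responses within one field;
#'   default `";"`. Use `NULL` to disable splitting.
#' @return The trial tibble with one row per response event and a
#'   `coded_category` column.
#' @export
code_naming_responses <- function(trials, lex, delimiter = ";") {
  trials <- tibble::as_tibble(trials)
  stopifnot(all(trials$task == "naming"))
  if (!is.null(delimiter)) {
    trials <- trials |>
      dplyr::mutate(response_text = strsplit(.data$response_text,
                                             delimiter, fixed = TRUE)) |>
      tidyr::unnest_longer("response_text")
  }
  trials |>
    dplyr::mutate(
      response_text = stringr::str_trim(.data$response_text),
      coded_category = lookup_category(lex, .data$response_text)
    )
}
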