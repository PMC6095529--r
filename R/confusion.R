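#' Confusion matrices with explicit semantics
#'
#' A `confusion_matrix` is an actual-category x response-category matrix
#' together with a declared semantics:
#'
#' * `percent_of_responses` (naming): entries are percentages of all
#'   responses for the actual category, including responses outside the
#'   category set, so rows need not reach 100; the off-matrix share is
#'   carried per row in `other_mass`.
#' * `mean_rating` (rating): entries are mean ratings in \[0, 1\].
#' * `choice_proportion` (forced choice): rows sum to 1.
#'
#' @param values Numeric matrix with row and column dimnames.
#' @param semantics One of the three semantics above.
#' @param other_mass Optional named per-row vector of percentage mass coded
#'   OTHER (naming only).
#' @param n Number of response events behind the matrix.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(values,
                             semantics = c("percent_of_responses",
                                           "mean_rating",
                                           "choice_proportion"),
                             other_mass = NULL, n = NA_integer_) {
  semantics <- match.arg(semantics)
  stopifnot(is.matrix(values), !is.null(dimnames(values)))
  structure(
    list(values = values, semantics = semantics, other_mass = other_mass,
         n = n),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, digits = 3, ...) {
  cat("<confusion_matrix> semantics:", x$semantics,
      if (!is.na(x$n)) paste0("(n = ", x$n, " responses)"), "\n")
  print(round(x$values, digits))
  if (!is.null(x$other_mass)) {
    cat("OTHER mass per row (%):\n")
    print(round(x$other_mass, digits))
  }
  invisible(x)
}

#' @export
as.matrix.confusion_matrix <- function(x, ...) x$values

#' @export
dim.confusion_matrix <- function(x) dim(x$values)

#' Tidy a confusion matrix into long format
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `actual`, `response`, `value`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(x$values), .name_repair = "minimal") |>
    stats::setNames(c("actual", "response", "value")) |>
    tibble::as_tibble()
}

resolve_labels <- function(trials, design, which) {
  col <- paste0("true_", which)
  if (!is.null(design)) domain_labels(design, which)
  else sort(unique(trials[[col]]))
}

#' Confusion matrix from coded naming responses
#'
#' Entry (i, j) is 100 times the share of responses coded as category j
#' among all responses to stimuli of actual category i. Responses coded
#' OTHER enter the denominator but not the matrix, so rows generally sum
#' to less than 100; their share is reported in `other_mass`.
#'
#' @param trials A coded naming trial table (see
#'   [code_naming_responses()]).
#' @param domain Which naming question to tabulate: `"material"` or
#'   `"transformation"`.
#' @param design Optional [experiment_design()] fixing label order.
#' @return A `confusion_matrix` with `percent_of_responses` semantics.
#' @export
naming_confusion <- function(trials,
                             domain = c("material", "transformation"),
                             design = NULL) {
  domain <- match.arg(domain)
  if (!"coded_category" %in% names(trials)) {
    stop("trials must be coded first; see code_naming_responses()",
         call. = FALSE)
  }
  trials <- dplyr::filter(trials, .data$response_domain == domain)
  if (nrow(trials) == 0) stop("no naming responses to tabulate",
                              call. = FALSE)
  labels <- resolve_labels(trials, design, domain)
  actual_col <- paste0("true_", domain)
  actual <- factor(trials[[actual_col]], levels = labels)
  if (any(table(actual) == 0)) {
    stop("actual category with zero responses: ",
         paste(labels[table(actual) == 0], collapse = ", "), call. = FALSE)
  }
  coded <- factor(trials$coded_category, levels = c(labels, "OTHER"))
  tab <- table(actual, coded)
  pct <- 100 * sweep(tab, 1, rowSums(tab), "/")
  values <- unclass(pct)[, labels, drop = FALSE]
  other <- unclass(pct)[, "OTHER"]
  confusion_matrix(values, "percent_of_responses", other_mass = other,
                   n = nrow(trials))
}

#' Confusion matrix of mean ratings
#'
#' Entry (i, j) is the mean rating on scale j for stimuli whose actual
#' category (in the scale domain) is i, averaged over exemplars,
#' repetitions and -- at group level -- observers.
#'
#' @param trials A rating trial table.
#' @param average `"group"` pools all trials; `"per_observer"` returns a
#'   named list of per-observer matrices.
#' @param design Optional [experiment_design()] fixing label order and the
#'   scale domain; inferred from the data when absent.
#' @return A `confusion_matrix` (`mean_rating` semantics), or a list of
#'   them for `average = "per_observer"`.
#' @export
rating_confusion <- function(trials, average = c("group", "per_observer"),
                             design = NULL) {
  average <- match.arg(average)
  stopifnot(all(trials$task == "rating"))
  if (average == "per_observer") {
    return(per_observer_matrices(trials, rating_confusion, design = design))
  }
  scales <- if (!is.null(design)) design$rating_scales
            else sort(unique(trials$block_scale))
  domain <- if (!is.null(design)) rating_domain(design)
            else if (all(scales %in% unique(trials$true_material)))
              "material" else "transformation"
  actual_col <- paste0("true_", domain)
  labels <- resolve_labels(trials, design, domain)
  cells <- trials |>
    dplyr::group_by(actual = .data[[actual_col]],
                    response = .data$block_scale) |>
    dplyr::summarise(value = mean(.data$response_value), .groups = "drop")
  values <- long_to_matrix(cells, labels, scales)
  if (anyNA(values)) {
    stop("undefined cell: no ratings for some actual category x scale",
         call. = FALSE)
  }
  confusion_matrix(values, "mean_rating", n = nrow(trials))
}

#' Confusion matrix of forced-choice proportions
#'
#' Entry (i, j) is the proportion of stimuli of actual transformation i
#' labeled j; rows sum to 1.
#'
#' @inheritParams rating_confusion
#' @param trials An afc trial table.
#' @return A `confusion_matrix` (`choice_proportion` semantics), or a list
#'   of them for `average = "per_observer"`.
#' @export
afc_confusion <- function(trials, average = c("group", "per_observer"),
                          design = NULL) {
  average <- match.arg(average)
  stopifnot(all(trials$task == "afc"))
  if (average == "per_observer") {
    return(per_observer_matrices(trials, afc_confusion, design = design))
  }
  labels <- resolve_labels(trials, design, "transformation")
  actual <- factor(trials$true_transformation, levels = labels)
  if (any(table(actual) == 0)) {
    stop("undefined cell: actual transformation with no trials: ",
         paste(labels[table(actual) == 0], collapse = ", "), call. = FALSE)
  }
  choice <- factor(trials$response_choice, levels = labels)
  tab <- table(actual, choice)
  values <- unclass(sweep(tab, 1, rowSums(tab), "/"))
  confusion_matrix(values, "choice_proportion", n = nrow(trials))
}

per_observer_matrices <- function(trials, fun, design = NULL) {
  trials |>
    split(trials$observer_id) |>
    lapply(fun, average = "group", design = design)
}

long_to_matrix <- function(cells, row_labels, col_labels) {
  wide <- cells |>
    dplyr::mutate(actual = factor(.data$actual, levels = row_labels),
                  response = factor(.data$response, levels = col_labels)) |>
    tidyr::complete(.data$actual, .data$response) |>
    tidyr::pivot_wider(names_from = "response", values_from = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- as.character(wide$actual)
  m[row_labels, col_labels, drop = FALSE]
}

#' Confusion matrices split by material or transformation class
#'
#' Applies the task-appropriate confusion operation within each level of
#' the grouping factor, e.g. transformation choices per material class.
#' Recombining the subgroup matrices weighted by trial counts reproduces
#' the pooled matrix.
#'
#' @param trials A rating or afc trial table (coded naming tables work for
#'   naming).
#' @param by Split by `"material"` or `"transformation"`.
#' @param design Optional [experiment_design()].
#' @param ... Passed to the underlying confusion operation (e.g. `domain`
#'   for naming).
#' @return A named list of `confusion_matrix` objects, one per level.
#' @export
subgroup_matrices <- function(trials, by = c("material", "transformation"),
                              design = NULL, ...) {
  by <- match.arg(by)
  col <- paste0("true_", by)
  levels <- if (!is.null(design)) domain_labels(design, by)
            else sort(unique(trials[[col]]))
  task <- unique(trials$task)
  stopifnot(length(task) == 1)
  fun <- switch(task, afc = afc_confusion, rating = rating_confusion,
                naming = naming_confusion)
  out <- lapply(levels, function(lv) {
    sub <- trials[trials[[col]] == lv, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop("no trials for ", by, " level '", lv, "'", call. = FALSE)
    }
    fun(sub, design = design, ...)
  })
  stats::setNames(out, levels)
}

#' Write a confusion matrix as labeled CSV
#' @param x A `confusion_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(x, path) {
  df <- data.frame(actual = rownames(x$values), x$values,
                   check.names = FALSE)
  if (!is.null(x$other_mass)) df$OTHER <- x$other_mass
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
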