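#' Default category labels
#'
#' The six material classes and four shape-transformation classes used
#' throughout the package. Transformations are "causal history" categories:
#' the physical process that brought an object into its current shape.
#'
#' @return Character vector of category labels.
#' @export
default_materials <- function() {
  c("wax", "aluminum foil", "gold foil", "wire", "putty", "cardboard")
}

#' @rdname default_materials
#' @export
default_transformations <- function() {
  c("twisted", "crumpled", "bent", "folded")
}

#' Define a categorization-experiment design
#'
#' An experiment design fixes the factor levels (materials and
#' transformations), the number of exemplar photographs per
#' material-by-transformation cell, the number of observers, the task type,
#' and how many stimuli each observer sees. Three tasks are supported:
#'
#' * `"naming"`: free naming of both the material and the transformation;
#'   each observer sees one exemplar per cell (24 stimuli).
#' * `"rating"`: block-wise ratings on a 0-1 bar; in each block all stimuli
#'   are rated against one category label (`rating_scales` is either the
#'   material or the transformation label set); each observer sees 7
#'   exemplars per cell (168 stimuli), once per block.
#' * `"afc"`: four-alternative forced choice among the transformation
#'   labels; each observer sees every exemplar (720 stimuli).
#'
#' @param task One of `"naming"`, `"rating"`, `"afc"`.
#' @param materials,transformations Ordered character vectors of unique
#'   category labels.
#' @param n_exemplars Exemplar photographs per material x transformation
#'   cell (default 30).
#' @param n_observers Number of observers (default 15).
#' @param rating_scales For `task = "rating"`, the block labels; must equal
#'   `materials` or `transformations`.
#' @param stimuli_per_observer Stimuli shown to each observer; must be a
#'   multiple of the number of cells. Defaults to 24 / 168 / 720 for
#'   naming / rating / afc.
#' @param repetitions Independent repeats of each stimulus (and, for rating,
#'   of each stimulus-by-scale block pairing). Default 1.
#'
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design("afc")
#' experiment_design("rating", rating_scales = default_transformations())
#' @export
experiment_design <- function(task = c("naming", "rating", "afc"),
                              materials = default_materials(),
                              transformations = default_transformations(),
                              n_exemplars = 30,
                              n_observers = 15,
                              rating_scales = NULL,
                              stimuli_per_observer = NULL,
                              repetitions = 1) {
  task <- match.arg(task)
  if (anyDuplicated(materials) || anyDuplicated(transformations)) {
    stop("materials and transformations must not contain duplicate labels",
         call. = FALSE)
  }
  n_cells <- length(materials) * length(transformations)
  if (is.null(stimuli_per_observer)) {
    stimuli_per_observer <- switch(task,
      naming = n_cells,                    # one exemplar per cell
      rating = n_cells * 7L,               # seven exemplars per cell
      afc    = n_cells * n_exemplars       # every exemplar
    )
  }
  if (stimuli_per_observer %% n_cells != 0) {
    stop("stimuli_per_observer must be a multiple of the number of cells (",
         n_cells, ")", call. = FALSE)
  }
  exemplars_per_cell <- stimuli_per_observer %/% n_cells
  if (exemplars_per_cell > n_exemplars) {
    stop("stimuli_per_observer implies more exemplars per cell than exist",
         call. = FALSE)
  }
  if (task == "rating") {
    if (is.null(rating_scales)) rating_scales <- materials
    if (!(setequal(rating_scales, materials) ||
          setequal(rating_scales, transformations))) {
      stop("rating_scales must equal the material or transformation labels",
           call. = FALSE)
    }
  } else if (!is.null(rating_scales)) {
    stop("rating_scales only applies to the rating task", call. = FALSE)
  }
  structure(
    list(
      task = task,
      materials = as.character(materials),
      transformations = as.character(transformations),
      n_exemplars = as.integer(n_exemplars),
      n_observers = as.integer(n_observers),
      rating_scales = if (task == "rating") as.character(rating_scales),
      stimuli_per_observer = as.integer(stimuli_per_observer),
      exemplars_per_cell = as.integer(exemplars_per_cell),
      repetitions = as.integer(repetitions)
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>", x$task, "task\n")
  cat("  materials:      ", paste(x$materials, collapse = ", "), "\n")
  cat("  transformations:", paste(x$transformations, collapse = ", "), "\n")
  cat("  ", length(x$materials), "x", length(x$transformations), "x",
      x$n_exemplars, "=", design_n_stimuli(x), "stimuli;",
      x$n_observers, "observers;",
      x$stimuli_per_observer, "stimuli/observer\n")
  if (!is.null(x$rating_scales)) {
    cat("  rating scales:  ", paste(x$rating_scales, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Total number of stimuli implied by a design
#' @param design An [experiment_design()].
#' @return Integer count (materials x transformations x exemplars).
#' @export
design_n_stimuli <- function(design) {
  length(design$materials) * length(design$transformations) *
    design$n_exemplars
}

#' The domain a rating design's scales refer to
#' @param design A rating [experiment_design()].
#' @return `"material"` or `"transformation"`.
#' @export
rating_domain <- function(design) {
  stopifnot(design$task == "rating")
  if (setequal(design$rating_scales, design$materials)) "material"
  else "transformation"
}

#' Labels of a response domain
#' @param design An [experiment_design()].
#' @param domain `"material"` or `"transformation"`.
#' @return Character vector of labels.
#' @export
domain_labels <- function(design, domain = c("material", "transformation")) {
  domain <- match.arg(domain)
  if (domain == "material") design$materials else design$transformations
}

default_observer_ids <- function(design) {
  sprintf("obs%02d", seq_len(design$n_observers))
}
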