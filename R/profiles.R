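#' Rating profiles of stimulus groups
#'
#' Treats each aggregated stimulus group as a point in the space spanned
#' by the rating scales: entry (row, scale) is the mean rating the group's
#' stimuli received on that scale. The default aggregation is one row per
#' transformation x material combination (24 rows for the full design),
#' so each point carries both labels for later coloring.
#'
#' @param trials A rating trial table.
#' @param aggregate_by Character vector of grouping columns; default
#'   `c("true_transformation", "true_material")`.
#' @param design Optional [experiment_design()] fixing scale order.
#' @return A `profile_matrix`: a tibble with the grouping columns plus one
#'   numeric column per rating scale (attribute `"scales"` records which).
#' @export
build_profiles <- function(trials,
                           aggregate_by = c("true_transformation",
                                            "true_material"),
                           design = NULL) {
  stopifnot(all(trials$task == "rating"))
  scales <- if (!is.null(design)) design$rating_scales
            else sort(unique(trials$block_scale))
  prof <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(aggregate_by)),
                    .data$block_scale) |>
    dplyr::summarise(value = mean(.data$response_value), .groups = "drop")
  if (nrow(prof) == 0) stop("empty aggregate", call. = FALSE)
  wide <- prof |>
    tidyr::pivot_wider(names_from = "block_scale",
                       values_from = "value") |>
    dplyr::select(dplyr::all_of(c(aggregate_by, scales)))
  if (anyNA(wide)) {
    stop("empty aggregate cell: some group has no rating on some scale",
         call. = FALSE)
  }
  structure(wide, scales = scales,
            class = c("profile_matrix", class(wide)))
}

#' Principal components of rating profiles
#'
#' Column-mean-centered PCA of the profile matrix via the
#' eigendecomposition of the covariance of the scale columns. Columns are
#' not rescaled: all scales share the \[0, 1\] rating unit. Component
#' signs follow a deterministic convention (the largest-magnitude loading
#' of each component is positive).
#'
#' @param profiles A `profile_matrix` from [build_profiles()].
#' @param n_components Number of components to retain (default: all).
#' @return A `profile_embedding`: list with `scores` (tibble of group
#'   labels plus `PC1`, `PC2`, ...), `loadings` (scales x components
#'   matrix), and `explained_variance` (fractions over all components).
#' @export
pca_profiles <- function(profiles, n_components = NULL) {
  scales <- attr(profiles, "scales")
  x <- as.matrix(profiles[, scales])
  if (nrow(x) < 2) stop("PCA requires at least 2 rows", call. = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(xc), symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  frac <- ev / sum(ev)
  v <- eig$vectors
  for (j in seq_len(ncol(v))) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  k <- if (is.null(n_components)) ncol(v) else min(n_components, ncol(v))
  v <- v[, seq_len(k), drop = FALSE]
  dimnames(v) <- list(scales, paste0("PC", seq_len(k)))
  scores <- xc %*% v
  label_cols <- setdiff(names(profiles), scales)
  structure(
    list(
      scores = dplyr::bind_cols(profiles[label_cols],
                                tibble::as_tibble(scores)),
      loadings = v,
      explained_variance = frac
    ),
    class = "profile_embedding"
  )
}

#' @export
print.profile_embedding <- function(x, ...) {
  cat("<profile_embedding>", nrow(x$scores), "points,",
      ncol(x$loadings), "components\n")
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
tidy.profile_embedding <- function(x, ...) x$scores

#' Silhouette separability of labeled points in PCA space
#'
#' Quantifies how well a labeling groups the embedded points, using the
#' mean silhouette width over the first `k` components with Euclidean
#' distances: for each point, `(b - a) / max(a, b)` where `a` is the mean
#' distance to same-label points and `b` the smallest mean distance to
#' any other label. Scores near 1 mean tight, well-separated label
#' groups; near 0, no organization by that labeling; negative, points sit
#' closer to other labels than their own. Singleton labels score 0, and
#' points whose `max(a, b)` is 0 (all relevant distances zero) score 0 by
#' convention.
#'
#' @param embedding A `profile_embedding`, or a numeric matrix of scores.
#' @param labels A label vector, or the name of a label column of the
#'   embedding's scores.
#' @param k Number of leading components used (default 3).
#' @return Mean silhouette width in \[-1, 1\].
#' @export
label_separability <- function(embedding, labels, k = 3) {
  if (inherits(embedding, "profile_embedding")) {
    if (is.character(labels) && length(labels) == 1) {
      labels <- embedding$scores[[labels]]
    }
    pcs <- grep("^PC", names(embedding$scores), value = TRUE)
    x <- as.matrix(embedding$scores[, utils::head(pcs, k)])
  } else {
    x <- as.matrix(embedding)[, seq_len(min(k, ncol(embedding))),
                              drop = FALSE]
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  if (length(unique(labels)) < 2) {
    stop("separability is undefined for a single label", call. = FALSE)
  }
  d <- as.matrix(stats::dist(x))
  mean(vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) return(0)            # singleton label
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1)))
}
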