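#' Performance statistics against a perfect prediction matrix
#'
#' The core performance measure for a response matrix R and a prediction
#' matrix P (both on the unit scale) is
#' `perf = 1 - mean(abs(R - P))`, the inverse mean elementwise distance:
#' 1 is perfect agreement and, for a binary response matrix compared with
#' uniform random predictions, the expected value is exactly 0.5 (chance).
#' The perfect prediction matrix is the identity: all zeros with a
#' diagonal of ones. A complementary measure is the squared Pearson
#' correlation between the flattened matrices.
#'
#' Percent-scale matrices (`percent_of_responses`) are divided by 100
#' before comparison so all semantics share the unit scale.
#'
#' @param response A `confusion_matrix` or plain numeric matrix.
#' @param prediction A matrix of the same shape; `NULL` means the identity
#'   (perfect prediction).
#' @return `perf_score()`: a number in \[0, 1\].
#' @examples
#' m <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' perf_score(m)
#' r2_to_prediction(m)
#' @export
perf_score <- function(response, prediction = NULL) {
  r <- as_unit_matrix(response)
  p <- resolve_prediction(prediction, r)
  1 - mean(abs(r - p))
}

#' @rdname perf_score
#' @return `r2_to_prediction()`: squared Pearson correlation of the
#'   flattened matrices; errors when either matrix is constant.
#' @export
r2_to_prediction <- function(response, prediction = NULL) {
  r <- as_unit_matrix(response)
  p <- resolve_prediction(prediction, r)
  if (stats::sd(r) == 0 || stats::sd(p) == 0) {
    stop("undefined correlation: matrix has zero variance", call. = FALSE)
  }
  stats::cor(c(r), c(p))^2
}

#' @rdname perf_score
#' @param n Matrix dimension, or a character vector of labels.
#' @export
identity_prediction <- function(n) {
  labels <- if (is.character(n)) n else as.character(seq_len(n))
  diag(length(labels)) |>
    `dimnames<-`(list(labels, labels))
}

as_unit_matrix <- function(x) {
  if (inherits(x, "confusion_matrix")) {
    if (x$semantics == "percent_of_responses") x$values / 100 else x$values
  } else {
    as.matrix(x)
  }
}

resolve_prediction <- function(prediction, r) {
  p <- if (is.null(prediction)) {
    if (nrow(r) != ncol(r)) {
      stop("identity prediction requires a square response matrix",
           call. = FALSE)
    }
    diag(nrow(r))
  } else {
    as_unit_matrix(prediction)
  }
  if (!all(dim(p) == dim(r))) {
    stop("response and prediction shapes differ", call. = FALSE)
  }
  p
}

#' Bootstrap confidence interval for perf
#'
#' Observers are resampled with replacement; each resample's matrices are
#' averaged into a group matrix whose perf against the prediction is
#' recorded. The interval is the percentile interval of that bootstrap
#' distribution.
#'
#' @param matrices A list of per-observer matrices (or `confusion_matrix`
#'   objects) of identical shape.
#' @param prediction Prediction matrix; `NULL` for the identity.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param conf Coverage (default 0.95).
#' @param seed Integer seed.
#' @return A list with `ci_low`, `ci_high`, `n_boot`.
#' @export
bootstrap_perf_ci <- function(matrices, prediction = NULL, n_boot = 10000,
                              conf = 0.95, seed = NULL) {
  if (length(matrices) < 2) {
    stop("bootstrap requires at least 2 observers", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mats <- lapply(matrices, as_unit_matrix)
  p <- resolve_prediction(prediction, mats[[1]])
  arr <- simplify2array(mats)                       # rows x cols x observers
  flat <- matrix(arr, ncol = length(mats))          # cells x observers
  pv <- c(p)
  idx <- matrix(sample.int(length(mats), n_boot * length(mats),
                           replace = TRUE), nrow = n_boot)
  stat <- apply(idx, 1, function(i) 1 - mean(abs(rowMeans(flat[, i]) - pv)))
  alpha <- (1 - conf) / 2
  qs <- unname(stats::quantile(stat, c(alpha, 1 - alpha)))
  list(ci_low = qs[1], ci_high = qs[2], n_boot = n_boot)
}

#' Null distribution of perf under random prediction matrices
#'
#' Compares the observed response matrix with an ensemble of random
#' prediction matrices and summarises the resulting perf distribution.
#' Two null constructions are available:
#'
#' * `"uniform"` (default): predictions with i.i.d. Uniform(0, 1) entries.
#'   For a binary response matrix the analytic mean perf is exactly 0.5.
#' * `"permutation"`: the identity matrix with randomly permuted rows,
#'   i.e. random relabelings of a perfect categorizer.
#'
#' Correlation with the random predictions is summarised two ways. The
#' headline `null_r2` is the square of the mean signed correlation across
#' draws; it is centred at zero under either null, matching the near-zero
#' null R-squared such analyses report. `null_r2_draws_mean`, the mean of
#' the per-draw squared correlations, is also returned for transparency:
#' it is bounded away from zero by construction (approximately
#' `1 / (cells - 1)` for independent entries) and therefore not a
#' chance-level reference.
#'
#' @param response Group response matrix (or `confusion_matrix`).
#' @param n_null Ensemble size (default 10000).
#' @param null_kind `"uniform"` or `"permutation"`.
#' @param conf Coverage of the percentile interval (default 0.95).
#' @param seed Integer seed.
#' @return A list with `null_perf_mean`, `null_ci_low`, `null_ci_high`,
#'   `null_r_mean`, `null_r2`, `null_r2_draws_mean`, `n_null`,
#'   `null_kind`.
#' @export
null_perf <- function(response, n_null = 10000,
                      null_kind = c("uniform", "permutation"),
                      conf = 0.95, seed = NULL) {
  null_kind <- match.arg(null_kind)
  stopifnot(n_null >= 1)
  if (!is.null(seed)) set.seed(seed)
  r <- as_unit_matrix(response)
  rv <- c(r)
  k <- length(rv)
  if (null_kind == "uniform") {
    u <- matrix(stats::runif(k * n_null), nrow = k)
  } else {
    if (nrow(r) != ncol(r)) {
      stop("permutation null requires a square matrix", call. = FALSE)
    }
    u <- vapply(seq_len(n_null), function(i) {
      c(diag(nrow(r))[sample.int(nrow(r)), , drop = FALSE])
    }, numeric(k))
  }
  perf_draws <- 1 - colMeans(abs(u - rv))
  r_draws <- if (stats::sd(rv) == 0) rep(NA_real_, n_null) else {
    keep <- col_sds(u) > 0
    out <- rep(NA_real_, n_null)
    out[keep] <- drop(stats::cor(rv, u[, keep, drop = FALSE]))
    out
  }
  alpha <- (1 - conf) / 2
  qs <- unname(stats::quantile(perf_draws, c(alpha, 1 - alpha)))
  r_mean <- mean(r_draws, na.rm = TRUE)
  list(null_perf_mean = mean(perf_draws), null_ci_low = qs[1],
       null_ci_high = qs[2],
       null_r_mean = r_mean, null_r2 = r_mean^2,
       null_r2_draws_mean = mean(r_draws^2, na.rm = TRUE),
       n_null = n_null, null_kind = null_kind)
}

# column standard deviations without extra dependencies
col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(colSums(sweep(m, 2, mu)^2) / (n - 1))
}

#' Inter-observer consistency of confusion matrices
#'
#' Mean Pearson correlation between the flattened confusion matrices of
#' all unordered observer pairs. Observers with constant matrices are
#' excluded with a warning (their correlation is undefined).
#'
#' @param matrices Named list of per-observer matrices.
#' @return A list with `mean_r`, `n_pairs`, `n_observers`, `excluded`.
#' @export
observer_consistency <- function(matrices) {
  mats <- lapply(matrices, as_unit_matrix)
  const <- vapply(mats, function(m) stats::sd(m) == 0, logical(1))
  if (any(const)) {
    warning("excluding ", sum(const),
            " observer(s) with constant matrices")
    mats <- mats[!const]
  }
  if (length(mats) < 2) {
    stop("consistency requires at least 2 usable observers", call. = FALSE)
  }
  flat <- vapply(mats, c, numeric(length(mats[[1]])))
  cm <- stats::cor(flat)
  rs <- cm[upper.tri(cm)]
  list(mean_r = mean(rs), n_pairs = length(rs),
       n_observers = length(mats),
       excluded = names(matrices)[const %in% TRUE])
}

#' Full performance summary for one experiment
#'
#' Combines the point estimate (perf and squared correlation of the
#' group-average matrix against the perfect prediction), the bootstrap
#' confidence interval over observers, the random-prediction null, and
#' inter-observer consistency.
#'
#' @param matrices Named list of per-observer matrices (see
#'   [rating_confusion()] / [afc_confusion()] with
#'   `average = "per_observer"`).
#' @param prediction Prediction matrix; `NULL` for the identity.
#' @param n_boot,n_null Resampling sizes.
#' @param null_kind Null construction, see [null_perf()].
#' @param seed Integer seed covering both resampling stages.
#' @return A `perf_summary` object; see [tidy.perf_summary()].
#' @export
perf_summary <- function(matrices, prediction = NULL, n_boot = 10000,
                         n_null = 10000,
                         null_kind = c("uniform", "permutation"),
                         seed = NULL) {
  null_kind <- match.arg(null_kind)
  mats <- lapply(matrices, as_unit_matrix)
  group <- Reduce(`+`, mats) / length(mats)
  dimnames(group) <- dimnames(mats[[1]])
  if (!is.null(seed)) set.seed(seed)
  ci <- bootstrap_perf_ci(mats, prediction, n_boot = n_boot)
  nul <- null_perf(group, n_null = n_null, null_kind = null_kind)
  cons <- observer_consistency(mats)
  structure(
    c(list(perf = perf_score(group, prediction),
           r2 = r2_to_prediction(group, prediction)),
      ci, nul,
      list(consistency_r = cons$mean_r, n_observers = length(mats),
           seed = seed, group_matrix = group)),
    class = "perf_summary"
  )
}

#' @export
print.perf_summary <- function(x, ...) {
  cat(sprintf("perf = %.2f, 95%% CI [%.2f, %.2f]; R^2 = %.2f\n",
              x$perf, x$ci_low, x$ci_high, x$r2))
  cat(sprintf(
    "null (%s, n = %d): perf = %.2f, 95%% CI [%.2f, %.2f]; R^2 = %.2f\n",
    x$null_kind, x$n_null, x$null_perf_mean, x$null_ci_low, x$null_ci_high,
    x$null_r2))
  cat(sprintf("inter-observer consistency r = %.2f (%d observers)\n",
              x$consistency_r, x$n_observers))
  invisible(x)
}

#' Tidy and glance methods for performance summaries
#' @param x A `perf_summary`.
#' @param ... Unused.
#' @return A one-row tibble of the summary statistics.
#' @export
tidy.perf_summary <- function(x, ...) {
  tibble::tibble(
    perf = x$perf, r2 = x$r2, ci_low = x$ci_low, ci_high = x$ci_high,
    null_perf_mean = x$null_perf_mean, null_ci_low = x$null_ci_low,
    null_ci_high = x$null_ci_high, null_r_mean = x$null_r_mean,
    null_r2 = x$null_r2, null_r2_draws_mean = x$null_r2_draws_mean,
    consistency_r = x$consistency_r
  )
}

#' @rdname tidy.perf_summary
#' @export
glance.perf_summary <- function(x, ...) {
  tibble::tibble(n_observers = x$n_observers, n_boot = x$n_boot,
                 n_null = x$n_null, null_kind = x$null_kind)
}
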