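#' Per-cell accuracy from a trial table
#'
#' Averages responses into one accuracy value per observer x material x
#' transformation cell, the input expected by [rm_anova()]:
#'
#' * afc: proportion of trials whose choice equals the true
#'   transformation;
#' * rating: mean rating on the true-category scale (the block whose label
#'   matches the stimulus's actual category in the scale domain);
#' * naming (coded): proportion of responses coded as the true category of
#'   `domain`.
#'
#' @param trials A trial table (coded, for naming).
#' @param design Optional [experiment_design()]; required to resolve the
#'   rating-scale domain when the scales are ambiguous.
#' @param domain For naming tables, which question to score.
#' @return A tibble with columns `observer_id`, `true_material`,
#'   `true_transformation`, `accuracy`; errors listing missing cells when
#'   the design is unbalanced.
#' @export
accuracy_cell_means <- function(trials, design = NULL,
                                domain = c("transformation", "material")) {
  domain <- match.arg(domain)
  task <- unique(trials$task)
  stopifnot(length(task) == 1)
  scored <- switch(task,
    afc = dplyr::mutate(trials,
      correct = as.numeric(.data$response_choice ==
                             .data$true_transformation)),
    rating = {
      dom <- if (!is.null(design)) rating_domain(design)
             else if (all(unique(trials$block_scale) %in%
                          unique(trials$true_material)))
               "material" else "transformation"
      tcol <- paste0("true_", dom)
      trials |>
        dplyr::filter(.data$block_scale == .data[[tcol]]) |>
        dplyr::mutate(correct = .data$response_value)
    },
    naming = {
      if (!"coded_category" %in% names(trials)) {
        stop("naming trials must be coded first", call. = FALSE)
      }
      tcol <- paste0("true_", domain)
      trials |>
        dplyr::filter(.data$response_domain == domain) |>
        dplyr::mutate(correct = as.numeric(.data$coded_category ==
                                             .data[[tcol]]))
    }
  )
  cells <- scored |>
    dplyr::group_by(.data$observer_id, .data$true_material,
                    .data$true_transformation) |>
    dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop")
  check_balanced(cells, design)
  cells
}

check_balanced <- function(cells, design = NULL) {
  mats <- if (!is.null(design)) design$materials
          else unique(cells$true_material)
  trans <- if (!is.null(design)) design$transformations
           else unique(cells$true_transformation)
  grid <- tidyr::expand_grid(observer_id = unique(cells$observer_id),
                             true_material = mats,
                             true_transformation = trans)
  miss <- dplyr::anti_join(
    grid, cells,
    by = c("observer_id", "true_material", "true_transformation"))
  if (nrow(miss) > 0) {
    stop("unbalanced cell-means table; missing cells: ",
         paste(utils::head(
           paste(miss$observer_id, miss$true_material,
                 miss$true_transformation, sep = "/"), 5),
           collapse = ", "),
         if (nrow(miss) > 5) " ...", call. = FALSE)
  }
  invisible(cells)
}

# orthonormal polynomial-free contrasts for a k-level factor
orthonormal_contrasts <- function(k) {
  h <- stats::contr.helmert(k)
  sweep(h, 2, sqrt(colSums(h^2)), "/")
}

# Greenhouse-Geisser epsilon from the covariance of contrast scores,
# then the Huynh-Feldt adjustment (n subjects, d contrasts), capped at 1
hf_epsilon <- function(z) {
  n <- nrow(z)
  d <- ncol(z)
  if (d == 1) return(list(gg = 1, hf = 1))
  s <- stats::cov(z)
  if (sum(s^2) == 0) return(list(gg = 1, hf = 1))  # degenerate: no variance
  gg <- sum(diag(s))^2 / (d * sum(s^2))
  hf <- (n * d * gg - 2) / (d * (n - 1 - d * gg))
  list(gg = gg, hf = min(1, hf))
}

#' Two-way repeated-measures ANOVA with Huynh-Feldt correction
#'
#' Fits the within-subject decomposition for a fully crossed two-factor
#' design (every observer contributes one value per cell): sums of squares
#' for each main effect and the interaction, each tested against its
#' effect-by-subject interaction. Because sphericity rarely holds for
#' factors with more than two levels, degrees of freedom are multiplied by
#' the Huynh-Feldt epsilon estimated from the covariance of each effect's
#' orthonormal contrast scores (capped at 1); p-values use the corrected
#' degrees of freedom.
#'
#' @param cells A balanced cell-means tibble from
#'   [accuracy_cell_means()] (or any table with the same columns).
#' @param dv,subject,factors Column names of the response, the subject
#'   identifier, and the two within-subject factors.
#' @return An `rm_anova` object: a per-effect tibble (see
#'   [tidy.rm_anova()]) plus the grand SS decomposition.
#' @examples
#' d <- tidyr::expand_grid(observer_id = paste0("s", 1:8),
#'                         true_material = letters[1:3],
#'                         true_transformation = LETTERS[1:4])
#' d$accuracy <- stats::runif(nrow(d))
#' rm_anova(d)
#' @export
rm_anova <- function(cells, dv = "accuracy", subject = "observer_id",
                     factors = c("true_material", "true_transformation")) {
  stopifnot(length(factors) == 2)
  wide <- cells |>
    dplyr::select(dplyr::all_of(c(subject, factors, dv))) |>
    dplyr::arrange(.data[[subject]], .data[[factors[1]]],
                   .data[[factors[2]]])
  a_lv <- sort(unique(wide[[factors[1]]]))
  b_lv <- sort(unique(wide[[factors[2]]]))
  A <- length(a_lv)
  B <- length(b_lv)
  subj <- sort(unique(wide[[subject]]))
  n <- length(subj)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  if (nrow(wide) != n * A * B) {
    stop("cell-means table is not balanced (expected one row per ",
         "subject x cell)", call. = FALSE)
  }
  # Y: subjects x (A*B) cells, columns ordered a slow, b fast
  y <- matrix(wide[[dv]], nrow = n, byrow = TRUE)

  m_grand <- mean(y)
  m_subj <- rowMeans(y)
  cellm <- colMeans(y)                          # length A*B
  m_ab <- matrix(cellm, nrow = A, byrow = TRUE) # A x B of cell means
  m_a <- rowMeans(m_ab)
  m_b <- colMeans(m_ab)

  ss_subj <- A * B * sum((m_subj - m_grand)^2)
  ss_a <- n * B * sum((m_a - m_grand)^2)
  ss_b <- n * A * sum((m_b - m_grand)^2)
  inter <- sweep(sweep(m_ab, 1, m_a), 2, m_b) + m_grand
  ss_ab <- n * sum(inter^2)

  # subject x effect interactions from subject-level margins
  y_sa <- t(apply(y, 1, function(r) rowMeans(matrix(r, A, byrow = TRUE))))
  y_sb <- t(apply(y, 1, function(r) colMeans(matrix(r, A, byrow = TRUE))))
  ss_as <- B * sum((y_sa - outer(m_subj, rep(1, A)) -
                      outer(rep(1, n), m_a) + m_grand)^2)
  ss_bs <- A * sum((y_sb - outer(m_subj, rep(1, B)) -
                      outer(rep(1, n), m_b) + m_grand)^2)
  ss_total <- sum((y - m_grand)^2)
  ss_abs <- ss_total - ss_subj - ss_a - ss_b - ss_ab - ss_as - ss_bs

  # contrast scores for epsilon estimation
  ha <- orthonormal_contrasts(A)
  hb <- orthonormal_contrasts(B)
  avg_b <- matrix(1 / B, B, 1)
  avg_a <- matrix(1 / A, A, 1)
  z_a <- y %*% kronecker(ha, avg_b)
  z_b <- y %*% kronecker(avg_a, hb)
  z_ab <- y %*% kronecker(ha, hb)

  effect_row <- function(name, ss, df1, ss_err, df2, z) {
    eps <- hf_epsilon(z)
    ms <- ss / df1
    ms_err <- ss_err / df2
    f <- if (ms_err > 0) ms / ms_err else if (ms == 0) 0 else Inf
    if (!is.finite(f)) {
      warning("zero error sum of squares for effect ", name,
              "; F is infinite and p reported as 0")
    }
    p_unc <- if (is.finite(f)) stats::pf(f, df1, df2, lower.tail = FALSE)
             else 0
    p_hf <- if (is.finite(f)) {
      stats::pf(f, df1 * eps$hf, df2 * eps$hf, lower.tail = FALSE)
    } else 0
    tibble::tibble(
      effect = name, ss = ss, df1 = df1, ss_error = ss_err, df2 = df2,
      epsilon_gg = eps$gg, epsilon_hf = eps$hf,
      df1_hf = df1 * eps$hf, df2_hf = df2 * eps$hf,
      statistic = f, p_uncorrected = p_unc, p_value = p_hf
    )
  }

  effects <- dplyr::bind_rows(
    effect_row(factors[1], ss_a, A - 1, ss_as, (A - 1) * (n - 1), z_a),
    effect_row(factors[2], ss_b, B - 1, ss_bs, (B - 1) * (n - 1), z_b),
    effect_row(paste(factors, collapse = ":"), ss_ab, (A - 1) * (B - 1),
               ss_abs, (A - 1) * (B - 1) * (n - 1), z_ab)
  )
  structure(
    list(effects = effects, ss_total = ss_total, ss_subjects = ss_subj,
         n_subjects = n, levels = list(a_lv, b_lv), dv = dv,
         factors = factors),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA (", x$n_subjects, " subjects), ",
      "Huynh-Feldt corrected:\n", sep = "")
  for (i in seq_len(nrow(x$effects))) {
    e <- x$effects[i, ]
    p <- if (e$p_value < 0.001) "p < .001"
         else sprintf("p = %.3f", e$p_value)
    cat(sprintf("  %s: F(%.2f, %.2f) = %.2f, %s\n",
                e$effect, e$df1_hf, e$df2_hf, e$statistic, p))
  }
  invisible(x)
}

#' Tidy and glance methods for repeated-measures ANOVA fits
#' @param x An `rm_anova`.
#' @param ... Unused.
#' @return `tidy()`: one row per effect with SS, uncorrected and
#'   HF-corrected degrees of freedom, epsilon, F, and p-values.
#' @export
tidy.rm_anova <- function(x, ...) x$effects

#' @rdname tidy.rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, ss_total = x$ss_total,
                 ss_subjects = x$ss_subjects)
}

#' Post-hoc paired t-tests between factor levels
#'
#' For every requested pair of levels of one factor, each observer's cell
#' means are averaged across the other factor and compared with a paired
#' two-sided t-test. Raw p-values are reported together with the
#' conventional star flags (`**` for p < .001, `*` for p < .05); no
#' multiplicity correction is applied.
#'
#' @param cells A cell-means tibble (see [accuracy_cell_means()]).
#' @param factor Which factor's levels to compare: `"material"` or
#'   `"transformation"`.
#' @param pairs Optional list of length-2 character vectors; default all
#'   unordered level pairs.
#' @param subject,dv Column names.
#' @return A tibble with `level1`, `level2`, `estimate` (mean difference
#'   level1 - level2), `statistic`, `df`, `p_value`, `signif`.
#' @export
posthoc_paired_t <- function(cells,
                             factor = c("material", "transformation"),
                             pairs = NULL, subject = "observer_id",
                             dv = "accuracy") {
  factor <- match.arg(factor)
  col <- paste0("true_", factor)
  means <- cells |>
    dplyr::group_by(.data[[subject]], .data[[col]]) |>
    dplyr::summarise(m = mean(.data[[dv]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(col),
                       values_from = "m") |>
    dplyr::arrange(.data[[subject]])
  levels <- setdiff(names(means), subject)
  if (is.null(pairs)) {
    pairs <- utils::combn(levels, 2, simplify = FALSE)
  }
  purrr::map_dfr(pairs, function(pr) {
    stopifnot(all(pr %in% levels))
    d <- means[[pr[1]]] - means[[pr[2]]]
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        return(tibble::tibble(level1 = pr[1], level2 = pr[2], estimate = 0,
                              statistic = 0, df = length(d) - 1,
                              p_value = 1, signif = ""))
      }
      stop("undefined t: zero variance of paired differences for ",
           pr[1], " vs ", pr[2], call. = FALSE)
    }
    tt <- stats::t.test(means[[pr[1]]], means[[pr[2]]], paired = TRUE)
    tibble::tibble(
      level1 = pr[1], level2 = pr[2],
      estimate = unname(tt$estimate), statistic = unname(tt$statistic),
      df = unname(tt$parameter), p_value = tt$p.value,
      signif = dplyr::case_when(tt$p.value < 0.001 ~ "**",
                                tt$p.value < 0.05 ~ "*",
                                TRUE ~ "")
    )
  })
}
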