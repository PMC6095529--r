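# small designs and simulated tables shared across tests

small_afc_design <- function(n_exemplars = 5, n_observers = 6) {
  experiment_design("afc", n_exemplars = n_exemplars,
                    n_observers = n_observers)
}

small_rating_design <- function(domain = c("material", "transformation"),
                                n_exemplars = 4, n_observers = 6,
                                exemplars_per_cell = 2) {
  domain <- match.arg(domain)
  scales <- if (domain == "material") default_materials()
            else default_transformations()
  experiment_design("rating", rating_scales = scales,
                    n_exemplars = n_exemplars, n_observers = n_observers,
                    stimuli_per_observer = 24 * exemplars_per_cell)
}

perfect_observers <- function(design, domains = "transformation") {
  kernels <- lapply(domains, function(d) {
    make_default_kernels(design, d, accuracy = 1)
  })
  make_observers(design, stats::setNames(kernels, domains),
                 lapse_rate = 0, oov_rate = 0, rating_noise_sd = 0,
                 observer_jitter_sd = 0, seed = 1)
}

# a balanced random cell-means table
random_cells <- function(n = 8, a = 3, b = 4, seed = 1) {
  set.seed(seed)
  d <- tidyr::expand_grid(
    observer_id = sprintf("s%02d", seq_len(n)),
    true_material = paste0("m", seq_len(a)),
    true_transformation = paste0("t", seq_len(b))
  )
  d$accuracy <- stats::rnorm(nrow(d)) +
    rep(stats::rnorm(n), each = a * b)
  d
}

# independent repeated-measures ANOVA oracle (multivariate lm + car)
car_rm_anova <- function(cells) {
  wide <- tidyr::pivot_wider(
    dplyr::arrange(cells, observer_id, true_material,
                   true_transformation),
    names_from = c(true_material, true_transformation),
    values_from = accuracy)
  y <- as.matrix(wide[, -1])
  a_lv <- sort(unique(cells$true_material))
  b_lv <- sort(unique(cells$true_transformation))
  idata <- data.frame(
    A = factor(rep(a_lv, each = length(b_lv))),
    B = factor(rep(b_lv, length(a_lv)))
  )
  fit <- car::Anova(stats::lm(y ~ 1), idata = idata, idesign = ~ A * B,
                    type = 3)
  s <- suppressWarnings(summary(fit, multivariate = FALSE))
  list(
    f = s$univariate.tests[c("A", "B", "A:B"), "F value"],
    ss = s$univariate.tests[c("A", "B", "A:B"), "Sum Sq"],
    ss_err = s$univariate.tests[c("A", "B", "A:B"), "Error SS"],
    eps_hf = pmin(1, s$pval.adjustments[c("A", "B", "A:B"), "HF eps"]),
    p_hf = s$pval.adjustments[c("A", "B", "A:B"), "Pr(>F[HF])"]
  )
}
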