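#' Construct confusion kernels for simulated observers
#'
#' A kernel set holds, for every material x transformation cell, a
#' probability vector over the response categories of one domain
#' (materials for material tasks, transformations for transformation
#' tasks). The default construction places `accuracy` mass on the correct
#' category and spreads the remainder uniformly; for the transformation
#' domain, the bent-folded cross entries are set to
#' `bentfold_confusability` scaled by a per-material multiplier before
#' row renormalization. This mimics the empirically dominant confusion in
#' causal-history judgments -- bending and folding leave similar shape
#' traces, most strongly for materials such as wire whose local features
#' are hard to resolve.
#'
#' @param design An [experiment_design()].
#' @param domain Response domain of the kernel: `"transformation"` or
#'   `"material"`.
#' @param accuracy Target diagonal probability mass before renormalization,
#'   in \[0, 1\].
#' @param bentfold_confusability Pre-renormalization probability placed on
#'   each bent<->folded cross entry (transformation domain only).
#' @param material_modulation Named non-negative multipliers on
#'   `bentfold_confusability`, by material; unnamed materials get 1.
#' @return A `kernel_set`: 3-d array \[material, transformation,
#'   response category\] of row-stochastic response probabilities (the
#'   response margin of each cell sums to 1).
#' @examples
#' k <- make_default_kernels(experiment_design("afc"), accuracy = 0.8,
#'                           bentfold_confusability = 0.15,
#'                           material_modulation = c(wire = 2))
#' k["wire", "bent", ]
#' @export
make_default_kernels <- function(design,
                                 domain = c("transformation", "material"),
                                 accuracy = 0.8,
                                 bentfold_confusability = 0,
                                 material_modulation = NULL) {
  domain <- match.arg(domain)
  if (accuracy < 0 || accuracy > 1) {
    stop("accuracy must lie in [0, 1]", call. = FALSE)
  }
  if (bentfold_confusability < 0 || any(material_modulation < 0)) {
    stop("confusability parameters must be non-negative", call. = FALSE)
  }
  cats <- domain_labels(design, domain)
  k <- length(cats)
  mods <- stats::setNames(rep(1, length(design$materials)),
                          design$materials)
  if (!is.null(material_modulation)) {
    unknown <- setdiff(names(material_modulation), design$materials)
    if (length(unknown) > 0) {
      stop("material_modulation names not in the design: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    mods[names(material_modulation)] <- material_modulation
  }
  kernels <- array(
    0, dim = c(length(design$materials), length(design$transformations), k),
    dimnames = list(design$materials, design$transformations, cats)
  )
  off <- if (k > 1) (1 - accuracy) / (k - 1) else 0
  for (m in design$materials) {
    for (tr in design$transformations) {
      true_cat <- if (domain == "transformation") tr else m
      row <- rep(off, k)
      names(row) <- cats
      row[true_cat] <- accuracy
      if (domain == "transformation" && bentfold_confusability > 0 &&
          all(c("bent", "folded") %in% cats) &&
          true_cat %in% c("bent", "folded")) {
        other <- setdiff(c("bent", "folded"), true_cat)
        row[other] <- bentfold_confusability * mods[[m]]
      }
      s <- sum(row)
      if (s <= 0) stop("kernel row has no probability mass", call. = FALSE)
      kernels[m, tr, ] <- row / s
    }
  }
  structure(kernels, class = c("kernel_set", "array"), domain = domain)
}

#' Build a panel of simulated observers
#'
#' Each observer carries one kernel set per response domain, a lapse rate
#' (probability of responding uniformly at random), an out-of-vocabulary
#' rate for naming, and Gaussian rating noise. Observer heterogeneity is
#' introduced by jittering kernel rows in log space (adding N(0,
#' `observer_jitter_sd`) to log-probabilities and renormalizing), which
#' keeps every row a valid probability vector.
#'
#' @param design An [experiment_design()].
#' @param kernels A `kernel_set`, or a named list of kernel sets keyed by
#'   domain (naming needs both `material` and `transformation`).
#' @param lapse_rate,oov_rate Probabilities in \[0, 1\].
#' @param rating_noise_sd,observer_jitter_sd Non-negative standard
#'   deviations.
#' @param seed Integer seed controlling the jitter draw.
#' @return A list of `observer_model` objects of length
#'   `design$n_observers`.
#' @export
make_observers <- function(design, kernels,
                           lapse_rate = 0.02, oov_rate = 0.05,
                           rating_noise_sd = 0.1,
                           observer_jitter_sd = 0, seed = NULL) {
  stopifnot(lapse_rate >= 0, lapse_rate <= 1, oov_rate >= 0, oov_rate <= 1,
            rating_noise_sd >= 0, observer_jitter_sd >= 0)
  if (inherits(kernels, "kernel_set")) {
    kernels <- stats::setNames(list(kernels), attr(kernels, "domain"))
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(default_observer_ids(design), function(id) {
    jittered <- lapply(kernels, function(kern) {
      if (observer_jitter_sd > 0) {
        dm <- dim(kern)
        for (i in seq_len(dm[1])) {
          for (j in seq_len(dm[2])) {
            row <- kern[i, j, ]
            lw <- log(row) + stats::rnorm(dm[3], 0, observer_jitter_sd)
            w <- exp(lw - max(lw[is.finite(lw)]))
            w[!is.finite(w)] <- 0
            kern[i, j, ] <- w / sum(w)
          }
        }
      }
      kern
    })
    structure(
      list(observer_id = id, kernels = jittered, lapse_rate = lapse_rate,
           oov_rate = oov_rate, rating_noise_sd = rating_noise_sd),
      class = "observer_model"
    )
  })
}

bind_trial_rows <- function(x) {
  while (is.list(x) && !all(vapply(x, is.data.frame, logical(1)))) {
    x <- purrr::list_flatten(x)
  }
  dplyr::bind_rows(x)
}

observer_kernel <- function(observer, domain) {
  kern <- observer$kernels[[domain]]
  if (is.null(kern)) {
    stop("observer has no kernel for domain '", domain, "'", call. = FALSE)
  }
  kern
}

# exemplars shown to one observer in one cell
draw_exemplars <- function(design) {
  if (design$exemplars_per_cell == design$n_exemplars) {
    seq_len(design$n_exemplars)
  } else {
    sort(sample.int(design$n_exemplars, design$exemplars_per_cell))
  }
}

cell_grid <- function(design) {
  tidyr::expand_grid(true_material = design$materials,
                     true_transformation = design$transformations)
}

#' Simulate a four-alternative forced-choice experiment
#'
#' Every observer classifies their stimuli into the four transformation
#' categories. Choices are drawn from the mixture
#' `(1 - lapse) * kernel + lapse * uniform` for the stimulus cell.
#'
#' @param design An [experiment_design()] with `task = "afc"`.
#' @param observers A list from [make_observers()].
#' @param seed Integer seed; identical inputs give identical tables.
#' @return A trial tibble (see [validate_trials()] for the schema).
#' @export
simulate_afc <- function(design, observers, seed = NULL) {
  stopifnot(design$task == "afc")
  if (!is.null(seed)) set.seed(seed)
  cats <- design$transformations
  grid <- cell_grid(design)
  rows <- purrr::map(observers, function(obs) {
    kern <- observer_kernel(obs, "transformation")
    purrr::pmap(grid, function(true_material, true_transformation) {
      ex <- draw_exemplars(design)
      p <- (1 - obs$lapse_rate) * kern[true_material, true_transformation, ] +
        obs$lapse_rate / length(cats)
      purrr::map(seq_len(design$repetitions), function(rep_i) {
        tibble::tibble(
          observer_id = obs$observer_id, task = "afc",
          true_material = true_material,
          true_transformation = true_transformation,
          exemplar_id = ex, block_scale = NA_character_,
          response_domain = NA_character_, response_text = NA_character_,
          response_value = NA_real_,
          response_choice = sample(cats, length(ex), replace = TRUE,
                                   prob = p),
          repetition = rep_i
        )
      })
    })
  })
  bind_trial_rows(rows)
}

#' Simulate a block-wise rating experiment
#'
#' In each block, every stimulus is rated against one category scale. The
#' rating equals the observer's kernel probability for the scale category
#' in the stimulus cell, plus Gaussian noise, clipped to \[0, 1\]; lapses
#' replace it by a uniform draw.
#'
#' @inheritParams simulate_afc
#' @param design An [experiment_design()] with `task = "rating"`.
#' @return A trial tibble with `block_scale` and `response_value` set.
#' @export
simulate_rating <- function(design, observers, seed = NULL) {
  stopifnot(design$task == "rating")
  if (!is.null(seed)) set.seed(seed)
  domain <- rating_domain(design)
  scales <- design$rating_scales
  grid <- cell_grid(design)
  rows <- purrr::map(observers, function(obs) {
    kern <- observer_kernel(obs, domain)
    purrr::pmap(grid, function(true_material, true_transformation) {
      ex <- draw_exemplars(design)
      p <- kern[true_material, true_transformation, ]
      purrr::map(seq_len(design$repetitions), function(rep_i) {
        purrr::map(scales, function(sc) {
          val <- p[[sc]] + stats::rnorm(length(ex), 0, obs$rating_noise_sd)
          lapse <- stats::runif(length(ex)) < obs$lapse_rate
          val[lapse] <- stats::runif(sum(lapse))
          tibble::tibble(
            observer_id = obs$observer_id, task = "rating",
            true_material = true_material,
            true_transformation = true_transformation,
            exemplar_id = ex, block_scale = sc,
            response_domain = NA_character_, response_text = NA_character_,
            response_value = pmin(1, pmax(0, val)),
            response_choice = NA_character_,
            repetition = rep_i
          )
        })
      })
    })
  })
  bind_trial_rows(rows)
}

#' Simulate a free-naming experiment
#'
#' Each stimulus yields two naming responses: one for the material and one
#' for the transformation (`response_domain` distinguishes them). A
#' category is drawn from the observer's kernel (with lapses as in
#' [simulate_afc()]) and emitted as one of the lexicon strings mapping to
#' that category; with probability `oov_rate` an out-of-lexicon string is
#' emitted instead.
#'
#' @inheritParams simulate_afc
#' @param design An [experiment_design()] with `task = "naming"`.
#' @param lex A [lexicon()] supplying the emission vocabulary.
#' @param oov_strings Candidate out-of-lexicon strings.
#' @return A trial tibble with `response_text` set.
#' @export
simulate_naming <- function(design, observers, lex = default_lexicon(design),
                            seed = NULL,
                            oov_strings = c("kinked", "squeezed together",
                                            "plastic", "smashed",
                                            "metal thing", "pressed")) {
  stopifnot(design$task == "naming")
  if (!is.null(seed)) set.seed(seed)
  strings_for <- function(cat) {
    s <- names(unclass(lex))[unclass(lex) == cat]
    if (length(s) == 0) cat else s
  }
  grid <- cell_grid(design)
  rows <- purrr::map(observers, function(obs) {
    purrr::pmap(grid, function(true_material, true_transformation) {
      ex <- draw_exemplars(design)
      purrr::map(c("material", "transformation"), function(dom) {
        kern <- observer_kernel(obs, dom)
        cats <- dimnames(kern)[[3]]
        p <- (1 - obs$lapse_rate) *
          kern[true_material, true_transformation, ] +
          obs$lapse_rate / length(cats)
        drawn <- sample(cats, length(ex), replace = TRUE, prob = p)
        txt <- vapply(drawn, function(ct) sample(strings_for(ct), 1), "")
        oov <- stats::runif(length(ex)) < obs$oov_rate
        if (any(oov)) {
          txt[oov] <- sample(oov_strings, sum(oov), replace = TRUE)
        }
        tibble::tibble(
          observer_id = obs$observer_id, task = "naming",
          true_material = true_material,
          true_transformation = true_transformation,
          exemplar_id = ex, block_scale = NA_character_,
          response_domain = dom, response_text = unname(txt),
          response_value = NA_real_, response_choice = NA_character_,
          repetition = 1L
        )
      })
    })
  })
  bind_trial_rows(rows)
}
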