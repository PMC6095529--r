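#' Configuration for an end-to-end pipeline run
#'
#' Bundles everything needed to reproduce one analysis: which experiment
#' to run, where trials come from (the simulator or a CSV), the observer
#' model parameters, all seeds, and the resampling sizes. A config
#' round-trips through YAML unchanged, so a saved config re-creates an
#' identical run.
#'
#' @param task One of `"exp1_naming"`, `"exp2_material"`,
#'   `"exp2_transformation"`, `"exp3_afc"`.
#' @param source `"simulate"` or a path to a trial-table CSV.
#' @param accuracy,bentfold_confusability,material_modulation Kernel
#'   parameters, see [make_default_kernels()].
#' @param lapse_rate,oov_rate,rating_noise_sd,observer_jitter_sd Observer
#'   parameters, see [make_observers()].
#' @param seed Master integer seed for simulation and resampling.
#' @param n_boot,n_null,null_kind Resampling settings, see
#'   [perf_summary()].
#' @param output_dir Optional directory; when set, trials, matrices and
#'   summaries are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(task = c("exp3_afc", "exp1_naming",
                                     "exp2_material",
                                     "exp2_transformation"),
                            source = "simulate",
                            accuracy = 0.8, bentfold_confusability = 0.1,
                            material_modulation = list(wire = 2),
                            lapse_rate = 0.02, oov_rate = 0.05,
                            rating_noise_sd = 0.1,
                            observer_jitter_sd = 0.15,
                            seed = 1L, n_boot = 2000, n_null = 2000,
                            null_kind = "uniform", output_dir = NULL) {
  structure(
    list(task = match.arg(task), source = source, accuracy = accuracy,
         bentfold_confusability = bentfold_confusability,
         material_modulation = material_modulation,
         lapse_rate = lapse_rate, oov_rate = oov_rate,
         rating_noise_sd = rating_noise_sd,
         observer_jitter_sd = observer_jitter_sd, seed = as.integer(seed),
         n_boot = n_boot, n_null = n_null, null_kind = null_kind,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

config_design <- function(config) {
  switch(config$task,
    exp1_naming = experiment_design("naming"),
    exp2_material = experiment_design("rating",
                                      rating_scales = default_materials()),
    exp2_transformation = experiment_design(
      "rating", rating_scales = default_transformations()),
    exp3_afc = experiment_design("afc")
  )
}

config_observers <- function(config, design) {
  mods <- unlist(config$material_modulation)
  kernels <- switch(config$task,
    exp1_naming = list(
      material = make_default_kernels(design, "material",
                                      accuracy = config$accuracy),
      transformation = make_default_kernels(
        design, "transformation", accuracy = config$accuracy,
        bentfold_confusability = config$bentfold_confusability,
        material_modulation = mods)
    ),
    exp2_material = list(material = make_default_kernels(
      design, "material", accuracy = config$accuracy)),
    exp2_transformation = list(transformation = make_default_kernels(
      design, "transformation", accuracy = config$accuracy,
      bentfold_confusability = config$bentfold_confusability,
      material_modulation = mods)),
    exp3_afc = list(transformation = make_default_kernels(
      design, "transformation", accuracy = config$accuracy,
      bentfold_confusability = config$bentfold_confusability,
      material_modulation = mods))
  )
  make_observers(design, kernels, lapse_rate = config$lapse_rate,
                 oov_rate = config$oov_rate,
                 rating_noise_sd = config$rating_noise_sd,
                 observer_jitter_sd = config$observer_jitter_sd,
                 seed = config$seed)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, confusion-matrix construction, performance
#' statistics, the repeated-measures ANOVA (rating and forced-choice
#' tasks), and the PCA scission analysis (rating tasks), in one
#' deterministic pass. Any stage failure is reported with the stage name.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return A `pipeline_run` manifest: the config, the design, the trial
#'   table, per-observer and group confusion matrices, a
#'   [perf_summary()], an [rm_anova()] fit where applicable, a
#'   [pca_profiles()] embedding with separability scores for rating
#'   tasks, and a content `hash` over the numerical results (identical
#'   configs give identical hashes).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  design <- config_design(config)
  task <- config$task

  trials <- with_stage("input", {
    if (identical(config$source, "simulate")) {
      observers <- config_observers(config, design)
      sim_seed <- config$seed + 1L
      switch(task,
        exp1_naming = simulate_naming(design, observers, seed = sim_seed),
        exp2_material = ,
        exp2_transformation = simulate_rating(design, observers,
                                              seed = sim_seed),
        exp3_afc = simulate_afc(design, observers, seed = sim_seed)
      )
    } else {
      read_trials(config$source, design)
    }
  })

  coded <- NULL
  if (task == "exp1_naming") {
    coded <- with_stage("coding", {
      code_naming_responses(trials, default_lexicon(design))
    })
  }

  matrices <- with_stage("confusion", {
    switch(task,
      exp1_naming = {
        split(coded, coded$observer_id) |>
          lapply(naming_confusion, domain = "transformation",
                 design = design)
      },
      exp2_material = ,
      exp2_transformation = rating_confusion(trials, "per_observer",
                                             design = design),
      exp3_afc = afc_confusion(trials, "per_observer", design = design)
    )
  })
  group_matrix <- with_stage("confusion", {
    switch(task,
      exp1_naming = naming_confusion(coded, domain = "transformation",
                                     design = design),
      exp2_material = ,
      exp2_transformation = rating_confusion(trials, "group",
                                             design = design),
      exp3_afc = afc_confusion(trials, "group", design = design)
    )
  })

  stats_out <- with_stage("stats", {
    perf_summary(matrices, n_boot = config$n_boot, n_null = config$n_null,
                 null_kind = config$null_kind, seed = config$seed + 2L)
  })

  anova_out <- NULL
  if (task != "exp1_naming") {
    anova_out <- with_stage("anova", {
      rm_anova(accuracy_cell_means(trials, design = design))
    })
  }

  embedding <- NULL
  separability <- NULL
  if (task %in% c("exp2_material", "exp2_transformation")) {
    embedding <- with_stage("pca", {
      pca_profiles(build_profiles(trials, design = design))
    })
    separability <- with_stage("pca", list(
      material = label_separability(embedding, "true_material"),
      transformation = label_separability(embedding,
                                          "true_transformation")
    ))
  }

  run <- structure(
    list(config = config, design = design, trials = trials,
         matrices = matrices, group_matrix = group_matrix,
         perf = stats_out, anova = anova_out, embedding = embedding,
         separability = separability),
    class = "pipeline_run"
  )
  run$hash <- rlang::hash(list(
    unclass(config), group_matrix$values, tidy.perf_summary(stats_out),
    if (!is.null(anova_out)) anova_out$effects, separability
  ))

  if (!is.null(config$output_dir)) {
    with_stage("output", write_run(run, config$output_dir))
  }
  run
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(run$trials, file.path(dir, "trials.csv"))
  write_confusion(run$group_matrix, file.path(dir, "confusion_group.csv"))
  summary <- list(
    task = run$config$task, seed = run$config$seed, hash = run$hash,
    perf = as.list(tidy.perf_summary(run$perf)),
    anova = if (!is.null(run$anova)) run$anova$effects,
    separability = run$separability
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_pipeline_config(run$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>", x$config$task, "seed", x$config$seed, "\n")
  print(x$perf)
  if (!is.null(x$anova)) print(x$anova)
  if (!is.null(x$separability)) {
    cat(sprintf("separability: material %.2f, transformation %.2f\n",
                x$separability$material, x$separability$transformation))
  }
  cat("hash:", x$hash, "\n")
  invisible(x)
}

#' Ingest an externally formatted trial table
#'
#' Adapter for deposited data whose column names differ from the package
#' schema: `mapping` renames external columns to schema columns, missing
#' optional columns are filled with NA, and the result is validated
#' against the design.
#'
#' @param path CSV file path.
#' @param design An [experiment_design()].
#' @param mapping Named character vector `c(schema_column =
#'   external_column, ...)`; unmapped schema columns are taken verbatim
#'   when present.
#' @return A validated trial tibble.
#' @export
ingest_trials <- function(path, design, mapping = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tibble::as_tibble(
    utils::read.csv(path, colClasses = "character", na.strings = "",
                    fileEncoding = "UTF-8"))
  if (!is.null(mapping)) {
    missing_ext <- setdiff(unname(mapping), names(raw))
    if (length(missing_ext) > 0) {
      stop("mapping refers to absent columns: ",
           paste(missing_ext, collapse = ", "), call. = FALSE)
    }
    for (ours in names(mapping)) raw[[ours]] <- raw[[mapping[[ours]]]]
  }
  required <- c("observer_id", "task", "true_material",
                "true_transformation", "exemplar_id")
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req) > 0) {
    stop("unmapped required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(trial_cols, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[trial_cols]
  raw$response_value <- as.numeric(raw$response_value)
  raw$exemplar_id <- as.integer(raw$exemplar_id)
  raw$repetition <- as.integer(tidyr::replace_na(raw$repetition, "1"))
  validate_trials(raw, design)
  tibble::as_tibble(raw)
}
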