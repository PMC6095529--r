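test_that("default kernels realise the requested confusion structure", {
  des <- experiment_design("afc")
  # perfect accuracy, no confusability: identity kernels
  k1 <- make_default_kernels(des, accuracy = 1)
  for (m in des$materials) {
    expect_equal(unname(k1[m, "twisted", ]), c(1, 0, 0, 0))
  }
  # chance accuracy: uniform rows
  k2 <- make_default_kernels(des, accuracy = 0.25)
  expect_equal(unname(k2["wax", "bent", ]), rep(0.25, 4))
  # bent<->folded mass scales with the material multiplier before
  # renormalization: reconstruct the pre-normalization rows
  k3 <- make_default_kernels(des, accuracy = 0.8,
                             bentfold_confusability = 0.15,
                             material_modulation = c(wire = 2))
  pre <- function(m) {
    row <- k3[m, "folded", ]
    row / row[["twisted"]] * ((1 - 0.8) / 3)   # un-normalize via off cell
  }
  expect_equal(pre("wire")[["bent"]], 2 * pre("wax")[["bent"]],
               tolerance = 1e-12)
  expect_equal(pre("wax")[["bent"]], 0.15, tolerance = 1e-12)
  # rows are probability vectors
  expect_true(all(abs(apply(k3, c(1, 2), sum) - 1) < 1e-12))
  expect_error(make_default_kernels(des, accuracy = 1.2), "\\[0, 1\\]")
  expect_error(make_default_kernels(des, material_modulation = c(wax = -1)),
               "non-negative")
})

test_that("increasing accuracy never decreases expected diagonal mass", {
  des <- experiment_design("afc")
  diag_mass <- function(a) {
    k <- make_default_kernels(des, accuracy = a,
                              bentfold_confusability = 0.1)
    mean(vapply(des$transformations,
                function(tr) mean(k[, tr, tr]), numeric(1)))
  }
  masses <- vapply(seq(0, 1, by = 0.1), diag_mass, numeric(1))
  expect_true(all(diff(masses) >= -1e-12))
})

test_that("simulators are deterministic given (design, observers, seed)", {
  des <- small_afc_design()
  obs <- make_observers(des, make_default_kernels(des, accuracy = 0.7),
                        observer_jitter_sd = 0.2, seed = 5)
  expect_equal(simulate_afc(des, obs, seed = 9),
               simulate_afc(des, obs, seed = 9))
  rdes <- small_rating_design("transformation")
  robs <- make_observers(rdes,
                         make_default_kernels(rdes, accuracy = 0.7),
                         seed = 5)
  expect_equal(simulate_rating(rdes, robs, seed = 9),
               simulate_rating(rdes, robs, seed = 9))
  ndes <- experiment_design("naming", n_exemplars = 2, n_observers = 3)
  nobs <- perfect_observers(ndes, c("material", "transformation"))
  expect_equal(simulate_naming(ndes, nobs, seed = 9),
               simulate_naming(ndes, nobs, seed = 9))
})

test_that("afc choices follow the kernel mixture", {
  des <- experiment_design("afc", n_observers = 5)
  # identity kernels, no lapse: confusion matrix is exactly the identity
  tr <- simulate_afc(des, perfect_observers(des), seed = 1)
  cm <- afc_confusion(tr, design = des)
  expect_equal(unname(cm$values), diag(4))
  # uniform kernels: every cell within 3 binomial SEs of 0.25
  uobs <- make_observers(des, make_default_kernels(des, accuracy = 0.25),
                         lapse_rate = 0, seed = 2)
  utr <- simulate_afc(des, uobs, seed = 3)
  ucm <- afc_confusion(utr, design = des)
  n_row <- 5 * 6 * 30                       # observers x materials x ex
  se <- sqrt(0.25 * 0.75 / n_row)
  expect_true(all(abs(ucm$values - 0.25) < 3 * se))
})

test_that("empirical afc confusions recover the generating kernels", {
  des <- experiment_design("afc")    # full size: 450 trials per cell
  k <- make_default_kernels(des, accuracy = 0.8,
                            bentfold_confusability = 0.15,
                            material_modulation = c(wire = 2))
  obs <- make_observers(des, k, lapse_rate = 0, observer_jitter_sd = 0,
                        seed = 1)
  tr <- simulate_afc(des, obs, seed = 2)
  sub <- subgroup_matrices(tr, by = "material", design = des)
  devs <- unlist(lapply(des$materials, function(m) {
    p <- k[m, , ]                     # 4 x 4 kernel for this material
    emp <- sub[[m]]$values
    ok <- abs(emp - p) < 3 * sqrt(p * (1 - p) / 450) + 1e-9
    as.vector(ok)
  }))
  expect_gte(mean(devs), 0.95)
})

test_that("ratings equal kernel probabilities plus bounded noise", {
  rdes <- small_rating_design("material", n_observers = 8,
                              exemplars_per_cell = 3)
  # identity kernels, zero noise: 1 on true-material scales, 0 elsewhere
  obs0 <- perfect_observers(rdes, "material")
  tr0 <- simulate_rating(rdes, obs0, seed = 1)
  on_true <- tr0$block_scale == tr0$true_material
  expect_true(all(tr0$response_value[on_true] == 1))
  expect_true(all(tr0$response_value[!on_true] == 0))
  expect_true(all(table(tr0$observer_id) == 24 * 3 * 6))
  # with noise, cell means stay within 3 SEs of the kernel value
  k <- make_default_kernels(rdes, "material", accuracy = 0.7)
  obs <- make_observers(rdes, k, lapse_rate = 0, rating_noise_sd = 0.1,
                        observer_jitter_sd = 0, seed = 2)
  tr <- simulate_rating(rdes, obs, seed = 3)
  cell <- dplyr::filter(tr, true_material == "wax",
                        block_scale == "wax")
  n <- nrow(cell)
  # clipping at 1 pulls the mean slightly below the kernel value, so
  # allow the clip bias on top of the CLT band
  expect_lt(abs(mean(cell$response_value) - 0.7), 3 * 0.1 / sqrt(n) + 0.01)
})

test_that("naming emission inverts through the lexicon", {
  ndes <- experiment_design("naming", n_exemplars = 4, n_observers = 6)
  lex <- default_lexicon(ndes)
  # oov_rate 0: coding recovers drawn categories exactly, so identity
  # kernels give a perfectly diagonal matrix
  obs <- perfect_observers(ndes, c("material", "transformation"))
  tr <- simulate_naming(ndes, obs, seed = 1)
  coded <- code_naming_responses(tr, lex)
  cm <- naming_confusion(coded, "material", design = ndes)
  expect_equal(unname(cm$values), 100 * diag(6))
  expect_equal(unname(cm$other_mass), rep(0, 6))
  # oov_rate 1: every response lands in OTHER
  obs1 <- make_observers(ndes, list(
    material = make_default_kernels(ndes, "material", accuracy = 1),
    transformation = make_default_kernels(ndes, accuracy = 1)),
    lapse_rate = 0, oov_rate = 1, seed = 2)
  tr1 <- simulate_naming(ndes, obs1, seed = 3)
  cm1 <- naming_confusion(code_naming_responses(tr1, lex),
                          "transformation", design = ndes)
  expect_true(all(cm1$values == 0))
  expect_equal(unname(cm1$other_mass), rep(100, 4))
  # intermediate oov rate: OTHER share within 3 binomial SEs
  obs2 <- make_observers(ndes, list(
    material = make_default_kernels(ndes, "material", accuracy = 1),
    transformation = make_default_kernels(ndes, accuracy = 1)),
    lapse_rate = 0, oov_rate = 0.2, seed = 4)
  tr2 <- simulate_naming(ndes, obs2, seed = 5)
  coded2 <- code_naming_responses(tr2, lex)
  share <- mean(coded2$coded_category == "OTHER")
  expect_lt(abs(share - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(coded2)))
})
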