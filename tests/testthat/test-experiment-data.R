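test_that("design invariants are enforced", {
  d <- experiment_design("afc")
  expect_equal(design_n_stimuli(d), 720)
  expect_equal(d$stimuli_per_observer, 720)
  expect_equal(experiment_design("naming")$stimuli_per_observer, 24)
  expect_equal(
    experiment_design("rating",
                      rating_scales = default_materials())$stimuli_per_observer,
    168)
  expect_error(experiment_design("afc", materials = c("wax", "wax")),
               "duplicate")
  expect_error(experiment_design("rating", rating_scales = c("red", "blue")),
               "rating_scales")
  expect_error(experiment_design("afc", stimuli_per_observer = 7),
               "multiple")
})

test_that("trial tables round-trip through CSV bit-exactly", {
  des <- small_afc_design()
  tr <- simulate_afc(des, perfect_observers(des), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path, des)
  expect_equal(back, tr)
  # free text with commas and umlauts survives quoting
  ndes <- experiment_design("naming", n_exemplars = 2, n_observers = 2)
  nobs <- perfect_observers(ndes, c("material", "transformation"))
  ntr <- simulate_naming(ndes, nobs, seed = 2)
  ntr$response_text[1] <- 'gebogen, geknickt "stark"'
  write_trials(ntr, path)
  expect_equal(read_trials(path, ndes), ntr)
})

test_that("row-level validation catches bad records", {
  des <- small_rating_design("material")
  obs <- perfect_observers(des, "material")
  tr <- simulate_rating(des, obs, seed = 1)
  bad <- tr
  bad$response_value[3] <- 1.3
  expect_error(validate_trials(bad, des), "outside \\[0, 1\\]")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(bad, path)
  expect_error(read_trials(path, des), "outside \\[0, 1\\]")
  bad2 <- tr
  bad2$true_material[5] <- "plastic"
  expect_error(validate_trials(bad2, des), "unknown true_material")
  bad3 <- tr
  bad3$response_choice[2] <- "bent"   # second response field populated
  expect_error(validate_trials(bad3, des), "exactly one response")
})

test_that("validate_design counts coverage against the design grid", {
  des <- small_afc_design(n_exemplars = 3, n_observers = 4)
  tr <- simulate_afc(des, perfect_observers(des), seed = 1)
  rep_ok <- validate_design(tr, des)
  expect_equal(attr(rep_ok, "n_flags"), 0)
  expect_equal(nrow(rep_ok), 4 * 24)

  # drop one observer's wax/bent cell entirely -> exactly one flag
  drop <- !(tr$observer_id == "obs01" & tr$true_material == "wax" &
              tr$true_transformation == "bent")
  rep_one <- validate_design(tr[drop, ], des)
  expect_equal(attr(rep_one, "n_flags"), 1)
  flagged <- dplyr::filter(rep_one, flag != "ok")
  expect_equal(flagged$flag, "missing")
  expect_equal(flagged$observer_id, "obs01")

  # dropping a single exemplar is a count mismatch, not missing
  drop2 <- !(tr$observer_id == "obs02" & tr$true_material == "wax" &
               tr$true_transformation == "bent" & tr$exemplar_id == 1)
  rep_two <- validate_design(tr[drop2, ], des)
  expect_equal(dplyr::filter(rep_two, flag != "ok")$flag, "count_mismatch")

  # empty table: every design cell flagged missing
  rep_empty <- validate_design(tr[0, ], des)
  expect_true(all(rep_empty$flag == "missing"))
  expect_equal(nrow(rep_empty), des$n_observers * 24)
})

test_that("lexicon lookup normalizes and falls through to OTHER", {
  lex <- lexicon(c("twisted" = "twisted", "twist" = "twisted"))
  expect_equal(lookup_category(lex, "Twisted "), "twisted")
  expect_equal(lookup_category(lex, "  TWIST"), "twisted")
  expect_equal(lookup_category(lex, "kinked"), "OTHER")
  expect_error(lexicon(c(foo = "bar"), design = experiment_design("afc")),
               "not in the design")
  # YAML round-trip
  path <- withr::local_tempfile(fileext = ".yaml")
  write_lexicon(lex, path)
  expect_equal(read_lexicon(path), lex)
})

test_that("naming responses are coded, split, and re-coded idempotently", {
  des <- experiment_design("naming", n_exemplars = 2, n_observers = 2)
  lex <- default_lexicon(des)
  tr <- simulate_naming(des, perfect_observers(des, c("material",
                                                      "transformation")),
                        seed = 1)
  tr$response_text[1] <- "bent; folded"
  tr$response_text[2] <- "kinked"
  coded <- code_naming_responses(tr, lex)
  # splitting adds exactly one row and both pieces are coded
  expect_equal(nrow(coded), nrow(tr) + 1)
  expect_equal(coded$coded_category[1:2], c("bent", "folded"))
  expect_equal(coded$coded_category[3], "OTHER")
  expect_equal(coded$response_text[3], "kinked")  # original retained
  # idempotent
  expect_equal(code_naming_responses(coded, lex), coded)
  # splitting never changes stimulus coverage
  cover <- function(x) dplyr::distinct(x, observer_id, true_material,
                                       true_transformation, exemplar_id)
  expect_equal(cover(coded), cover(tr))
})

test_that("ingest adapter maps external columns and validates", {
  des <- small_afc_design(n_exemplars = 2, n_observers = 2)
  tr <- simulate_afc(des, perfect_observers(des), seed = 1)
  ext <- dplyr::rename(tr, subject = observer_id, chosen = response_choice)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ext, path, row.names = FALSE, na = "")
  got <- ingest_trials(path, des, mapping = c(observer_id = "subject",
                                              response_choice = "chosen"))
  expect_equal(got[trial_order <- names(tr)], tr)
  expect_equal(attr(validate_design(got, des), "n_flags"), 0)
  expect_error(ingest_trials(path, des), "unmapped required")
  expect_error(ingest_trials(path, des, mapping = c(observer_id = "nope")),
               "absent columns")
})
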