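lab4 <- function(m) `dimnames<-`(m, list(paste0("c", 1:4), paste0("c", 1:4)))

test_that("perf matches its closed-form identities", {
  id <- identity_prediction(4)
  expect_equal(perf_score(id, id), 1)
  expect_equal(perf_score(matrix(0.5, 4, 4) |> lab4(), id), 0.5)
  # diagonal 0.7 / off-diagonal 0.1 against the identity:
  # (4 * 0.3 + 12 * 0.1) / 16 = 0.15
  m <- lab4(matrix(0.1, 4, 4) + diag(0.6, 4))
  expect_equal(perf_score(m), 0.85)
  # symmetry and joint permutation invariance
  r <- lab4(matrix(runif(16, 0, 1), 4))
  p <- lab4(matrix(runif(16, 0, 1), 4))
  expect_equal(perf_score(r, p), perf_score(p, r))
  i <- sample(4)
  expect_equal(perf_score(r[i, i], p[i, i]), perf_score(r, p))
  expect_error(perf_score(r, matrix(0, 2, 2)), "shapes differ")
  # percent-scale confusion matrices are rescaled before comparison
  cm <- confusion_matrix(lab4(100 * diag(4)), "percent_of_responses",
                         other_mass = rep(0, 4))
  expect_equal(perf_score(cm), 1)
})

test_that("r2 against the perfect prediction matches a hand Pearson", {
  expect_equal(r2_to_prediction(identity_prediction(3)), 1)
  m <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  v <- c(m); u <- c(diag(2))
  hand <- (sum((v - mean(v)) * (u - mean(u))) /
             sqrt(sum((v - mean(v))^2) * sum((u - mean(u))^2)))^2
  expect_equal(r2_to_prediction(m), hand)
  expect_gt(hand, 0.97)
  expect_error(r2_to_prediction(matrix(0.3, 2, 2)), "zero variance")
})

test_that("bootstrap CI over observers behaves at the degenerate limits", {
  m <- lab4(matrix(0.1, 4, 4) + diag(0.6, 4))
  same <- replicate(6, m, simplify = FALSE)
  ci <- bootstrap_perf_ci(same, n_boot = 200, seed = 1)
  expect_equal(ci$ci_low, perf_score(m))
  expect_equal(ci$ci_high, perf_score(m))
  expect_error(bootstrap_perf_ci(same[1], n_boot = 10), "at least 2")
  # ordered and bounded with heterogeneous observers
  mats <- lapply(1:8, function(i) lab4(matrix(runif(16), 4)))
  ci2 <- bootstrap_perf_ci(mats, n_boot = 500, seed = 2)
  expect_lte(ci2$ci_low, ci2$ci_high)
  expect_true(ci2$ci_low >= 0 && ci2$ci_high <= 1)
})

test_that("bootstrap CI covers the population perf at roughly 95%", {
  # observer population with known group matrix; reduced replications
  base <- lab4(matrix(0.08, 4, 4) + diag(0.48, 4))
  pop_perf <- perf_score(base)
  set.seed(31)
  cover <- vapply(1:60, function(r) {
    mats <- lapply(1:12, function(i) {
      lab4(matrix(pmin(1, pmax(0, base + rnorm(16, 0, 0.05))), 4))
    })
    ci <- bootstrap_perf_ci(mats, n_boot = 400)
    ci$ci_low <= pop_perf && pop_perf <= ci$ci_high
  }, logical(1))
  # clipping at [0,1] barely bites here; binomial 3-SE band around 0.95
  expect_gt(mean(cover), 0.95 - 3 * sqrt(0.95 * 0.05 / 60))
})

test_that("uniform null recovers the analytic chance level", {
  id <- identity_prediction(4)
  nul <- null_perf(id, n_null = 10000, seed = 1)
  # E|b - U| = 0.5 exactly for binary b, so mean perf = 0.5; the spread
  # of each draw's perf is Var(|b-U|)/16 per cell
  se <- sqrt(1 / 12 / 16 / 10000)
  expect_lt(abs(nul$null_perf_mean - 0.5), 3 * se)
  # signed correlations with 16-cell random matrices have sd ~ 1/sqrt(15)
  expect_lt(abs(nul$null_r_mean), 3 / sqrt(15) / sqrt(10000))
  expect_equal(round(nul$null_r2, 2), 0)
  # per-draw squared correlations are bounded away from zero (~ 1/15)
  expect_gt(nul$null_r2_draws_mean, 0.03)
  expect_lte(nul$null_ci_low, nul$null_ci_high)
})

test_that("permutation null enumerates to the fixed-point pattern", {
  # brute-force oracle: all 24 row permutations of the 4x4 identity;
  # perf = 1 - 2 * (4 - fixed points) / 16
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) all(sort(p) == 1:4)), ]
  oracle <- sort(unique(apply(perms, 1, function(p) {
    1 - mean(abs(diag(4) - diag(4)[p, ]))
  })))
  expect_equal(oracle, c(0.5, 0.625, 0.75, 1))
  nul <- null_perf(identity_prediction(4), n_null = 2000,
                   null_kind = "permutation", seed = 1)
  draws_ok <- nul$null_perf_mean > 0.5 && nul$null_perf_mean < 0.75
  expect_true(draws_ok)
  # expected mean: sum over permutations weighted by their counts
  counts <- table(apply(perms, 1, function(p) sum(p == 1:4)))
  exp_mean <- sum((1 - 2 * (4 - as.numeric(names(counts))) / 16) *
                    counts) / 24
  expect_lt(abs(nul$null_perf_mean - exp_mean), 3 * 0.15 / sqrt(2000))
})

test_that("observer consistency is the mean pairwise correlation", {
  m <- lab4(matrix(runif(16), 4))
  same <- replicate(5, m, simplify = FALSE)
  cons <- observer_consistency(same)
  expect_equal(cons$mean_r, 1)
  expect_equal(cons$n_pairs, choose(5, 2))
  anti <- list(a = matrix(c(1, 0, 0, 1), 2), b = matrix(c(0, 1, 1, 0), 2))
  expect_equal(observer_consistency(anti)$mean_r, -1)
  # constant observers are excluded with a warning
  with_const <- c(same, list(const = lab4(matrix(0.5, 4, 4))))
  expect_warning(cons2 <- observer_consistency(with_const), "excluding")
  expect_equal(cons2$n_observers, 5)
})

test_that("perf summary assembles all statistics coherently", {
  des <- small_afc_design(n_exemplars = 3, n_observers = 5)
  obs <- make_observers(des, make_default_kernels(des, accuracy = 0.8),
                        lapse_rate = 0, observer_jitter_sd = 0.1, seed = 1)
  tr <- simulate_afc(des, obs, seed = 2)
  ps <- perf_summary(afc_confusion(tr, "per_observer", design = des),
                     n_boot = 300, n_null = 300, seed = 3)
  td <- tidy(ps)
  expect_equal(nrow(td), 1)
  expect_true(all(c(td$perf, td$r2) >= 0 & c(td$perf, td$r2) <= 1))
  expect_lte(td$ci_low, td$ci_high)
  expect_gt(td$perf, td$null_perf_mean)   # far above chance here
  expect_equal(glance(ps)$n_observers, 5)
})
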