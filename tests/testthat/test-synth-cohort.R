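test_that("an all-healthy cohort is fully NODR with six captures per patient", {
  spec <- cohort_spec(n_patients = 100,
                      stage_distribution = c(NODR = 1, MILD = 0, MOD = 0,
                                             SEV = 0, PROL = 0),
                      ung_rate = 0, seed = 5)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh$manifest), 600)
  expect_true(all(coh$truth$status == "NODR"))
  expect_true(all(table(coh$manifest$patient_id) == 6))
  expect_true(all(coh$manifest$capture %in% 1:3))
})

test_that("the ungradable rate matches its configured probability", {
  spec <- cohort_spec(n_patients = 2000, ung_rate = 0.116, seed = 11)
  coh <- generate_cohort(spec)
  band <- binom_band(2000, 0.116)
  expect_gte(sum(coh$truth$status == "UNG"), band[1])
  expect_lte(sum(coh$truth$status == "UNG"), band[2])
})

test_that("the STDR fraction matches the configured stage mix", {
  spec <- cohort_spec(n_patients = 2000, ung_rate = 0, seed = 12)
  coh <- generate_cohort(spec)
  p <- spec$stage_distribution
  p_stdr <- p[["SEV"]] + p[["PROL"]] +
    p[["MOD"]] * spec$dme_rate_given_mod_or_worse
  band <- binom_band(2000, p_stdr)
  expect_gte(sum(coh$truth$stdr), band[1])
  expect_lte(sum(coh$truth$stdr), band[2])
})

test_that("worst-eye stage equals the patient stage in the manifest", {
  coh <- generate_cohort(cohort_spec(n_patients = 50, seed = 3))
  worst <- vapply(split(coh$manifest$stage_truth, coh$manifest$patient_id),
                  function(s) max(match(s, c("NODR", "MILD", "MOD", "SEV",
                                             "PROL"))), 0)
  truth_rank <- match(coh$truth$stage,
                      c("NODR", "MILD", "MOD", "SEV", "PROL"))
  expect_equal(unname(worst[coh$truth$patient_id]), truth_rank)
})

test_that("a perfect rater reproduces truth with kappa 1", {
  truth <- c(rep("DR", 40), rep("NODR", 160))
  calls <- simulate_rater(truth, list(se = 1, sp = 1, p_ung = 0), seed = 1)
  expect_identical(calls, truth)
  k <- cohen_kappa(unclass(crosstab_raters(calls, truth))[1:2, 1:2])
  expect_equal(k$kappa, 1)
})

test_that("an always-ungradable rater emits only UNG", {
  calls <- simulate_rater(rep(c("DR", "NODR"), 50),
                          list(se = 0.9, sp = 0.9, p_ung = 1), seed = 2)
  expect_true(all(calls == "UNG"))
})

test_that("a noisy rater's sensitivity is recovered within sampling error", {
  spec <- cohort_spec(n_patients = 2000, ung_rate = 0,
                      rater_models = list(R = list(se = 0.85, sp = 0.81,
                                                   p_ung = 0)),
                      seed = 21)
  coh <- generate_cohort(spec)
  calls <- coh$rater_calls$diagnosis
  truth <- coh$truth$underlying
  n_dr <- sum(truth == "DR")
  band <- binom_band(n_dr, 0.85)
  expect_gte(sum(calls == "DR" & truth == "DR"), band[1])
  expect_lte(sum(calls == "DR" & truth == "DR"), band[2])
})

test_that("cohorts are reproducible and reject invalid specifications", {
  spec <- cohort_spec(n_patients = 30, seed = 7)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  expect_error(cohort_spec(n_patients = 0), "positive")
  expect_error(cohort_spec(stage_distribution = c(NODR = 0.5, MILD = 0.2,
                                                  MOD = 0.2, SEV = 0.05,
                                                  PROL = 0.1)), "sum to 1")
  expect_error(simulate_rater(c("DR", "UNG"), list(se = 1, sp = 1, p_ung = 0)),
               "DR/NODR")
})
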