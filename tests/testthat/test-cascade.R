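cfg <- cascade_config()

test_that("case classification honours thresholds, conjunction and drug clause", {
  expect_true(classify_case(make_record(fbg = 126, hba1c = 6.5), cfg))
  expect_false(classify_case(make_record(fbg = 180, hba1c = 6.0), cfg))
  expect_false(classify_case(make_record(fbg = 100, hba1c = 7.0), cfg))
  # drug use makes a case irrespective of biomarker values
  expect_true(classify_case(make_record(fbg = 100, hba1c = 5.6,
                                        drugs = TRUE), cfg))
  expect_true(classify_case(make_record(fbg = NA, hba1c = NA,
                                        insulin = TRUE), cfg))
  # missing biomarkers fail the biomarker clause
  expect_false(classify_case(make_record(fbg = NA, hba1c = 7.0), cfg))
})

test_that("stages are nested conjunctions", {
  full <- make_record(fbg = 150, hba1c = 7.2, drugs = TRUE, tested = TRUE,
                      told = TRUE, care = TRUE)
  for (s in c("tested", "diagnosed", "in_care", "in_treatment",
              "under_control")) {
    expect_true(classify_stage(full, s, cfg), label = s)
  }
  # told but never tested does not count as diagnosed
  skip_test <- make_record(fbg = 150, hba1c = 9, told = TRUE, care = TRUE)
  expect_false(classify_stage(skip_test, "diagnosed", cfg))
  expect_false(classify_stage(skip_test, "in_care", cfg))
  # in treatment but HbA1c at the control threshold is not controlled
  at_thr <- make_record(fbg = 150, hba1c = 8, drugs = TRUE, tested = TRUE,
                        told = TRUE, care = TRUE)
  expect_true(classify_stage(at_thr, "in_treatment", cfg))
  expect_false(classify_stage(at_thr, "under_control", cfg))
  expect_error(classify_stage(full, "cured", cfg), "unknown cascade stage")
})

test_that("the advice bundle is the conjunction of all four items", {
  expect_true(advice_bundle(make_record(advice = rep(TRUE, 4))))
  for (i in 1:4) {
    a <- rep(TRUE, 4); a[i] <- FALSE
    expect_false(advice_bundle(make_record(advice = a)))
  }
})

test_that("the fixture cascade reproduces the printed bars and percentages", {
  d <- reconstruct_fixture(survey_fixture_spec())
  cc <- build_cascade(d, cfg)
  expect_equal(cc$bars$count, c(560L, 353L, 309L, 279L, 273L, 60L))
  expect_equal(round_half_up(cc$bars$percent, 1),
               c(100, 63.0, 55.2, 49.8, 48.8, 10.7))
  expect_equal(round_half_up(cc$prevalence_pct, 2), 11.04)
  expect_equal(cc$advice_bundle$count, 130L)
  expect_equal(round_half_up(cc$advice_bundle$percent, 1), 47.6)
})

test_that("bars are monotone for adversarial (non-nested) flag data", {
  for (seed in 1:5) {
    d <- random_flag_data(400L, seed)
    cc <- build_cascade(d, cfg)
    expect_true(all(diff(cc$bars$count) <= 0L))
    expect_equal(cc$bars$percent, 100 * cc$bars$count / cc$denominator)
  }
})

test_that("threshold changes move counts in the expected direction", {
  d <- random_flag_data(600L, seed = 9L)
  base <- build_cascade(d, cfg)
  stricter_ctl <- build_cascade(d, cascade_config(hba1c_control_threshold = 7))
  expect_lte(stricter_ctl$bars$count[6], base$bars$count[6])
  lower_fbg <- build_cascade(d, cascade_config(fbg_threshold = 110))
  expect_gte(lower_fbg$denominator, base$denominator)
})

test_that("per-setting bars add up to the overall bars", {
  d <- generate_population(generator_params(n_per_setting = 600L, seed = 4L))
  set <- build_cascade(d, cfg, stratify_by = "setting")
  expect_named(set, c("overall", setting_levels()))
  per_setting <- sapply(set[-1], function(r) r$bars$count)
  expect_equal(unname(rowSums(per_setting)), set$overall$bars$count)
  expect_equal(sum(sapply(set[-1], `[[`, "denominator")),
               set$overall$denominator)
})

test_that("zero-case populations are flagged, empty input is an error", {
  d <- generate_population(generator_params(n_per_setting = 50L,
                                            prevalence = 0, seed = 2L))
  cc <- build_cascade(d, cfg)
  expect_true(cc$all_zero)
  expect_true(all(cc$bars$count == 0L))
  expect_true(all(cc$bars$percent == 0))
  expect_error(build_cascade(d[0, ], cfg), "non-empty")
})

test_that("invalid configurations are rejected", {
  expect_error(cascade_config(hba1c_control_threshold = 6),
               "must exceed")
  expect_error(cascade_config(fbg_threshold = -1), "positive")
})
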