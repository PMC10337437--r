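test_that("identical seed and parameters give byte-identical output", {
  p <- generator_params(n_per_setting = 50L, seed = 7L)
  expect_identical(generate_population(p), generate_population(p))
  p2 <- generator_params(n_per_setting = 50L, seed = 8L)
  expect_false(identical(generate_population(p), generate_population(p2)))
})

test_that("zero prevalence yields no cases and full retention collapses the chain", {
  p0 <- generator_params(n_per_setting = 200L, prevalence = 0, seed = 1L)
  d0 <- generate_population(p0)
  expect_equal(sum(classify_case(d0)), 0L)

  p1 <- generator_params(n_per_setting = 2000L, prevalence = 0.1,
                         p_tested_given_case = 1, p_diagnosed_given_tested = 1,
                         p_care_given_diagnosed = 1, p_treated_given_care = 1,
                         p_control_given_treated = 1, seed = 2L)
  d1 <- generate_population(p1)
  cc <- build_cascade(d1)
  expect_true(cc$denominator > 0L)
  expect_true(all(cc$bars$count == cc$denominator))
})

test_that("stage flags are monotone (nested) for every generated individual", {
  for (seed in 1:4) {
    p <- generator_params(n_per_setting = 300L, prevalence = 0.3,
                          undiagnosed_logodds = c(age_40_49 = 0.8,
                                                  male = -0.4),
                          seed = seed)
    d <- generate_population(p)
    treat <- d$takes_t2d_drugs | d$takes_insulin
    expect_true(all(!d$care_past_12m | d$ever_told_t2d))
    expect_true(all(!d$ever_told_t2d | d$ever_tested_3y))
    expect_true(all(!treat | d$care_past_12m))
  }
})

test_that("generated biomarkers recover exactly the simulated case set", {
  p <- generator_params(n_per_setting = 1000L, seed = 5L)
  d <- generate_population(p)
  # non-cases all have HbA1c below the case threshold; cases all qualify
  case <- classify_case(d)
  expect_true(all(d$hba1c_pct[case] >= 6.5))
  expect_true(all(d$fbg_mg_dl[case] >= 126))
  expect_true(all(d$hba1c_pct[!case] < 6.5))
})

test_that("simulated bar proportions track the configured retention products", {
  p <- generator_params(n_per_setting = 8000L, seed = 9L)
  d <- generate_population(p)
  cc <- build_cascade(d)
  prods <- c(353, 309, 279, 273, 60) / 560
  props <- cc$bars$count[-1] / cc$denominator
  # denominator ~ 4400 cases; 4 binomial SEs ~ 0.03
  expect_true(all(abs(props - prods) < 0.03))
})

test_that("invalid generator parameters are rejected", {
  expect_error(generator_params(prevalence = 1.2), "probability")
  expect_error(generator_params(p_tested_given_case = -0.1), "probability")
  expect_error(generator_params(n_per_setting = 0), ">= 1")
  expect_error(generator_params(undiagnosed_logodds = c(0.5, 0.2)), "named")
})

test_that("requested biomarker missingness blanks both biomarkers", {
  p <- generator_params(n_per_setting = 400L, prop_missing_biomarkers = 0.2,
                        seed = 3L)
  d <- generate_population(p)
  miss <- is.na(d$fbg_mg_dl)
  expect_identical(miss, is.na(d$hba1c_pct))
  expect_gt(mean(miss), 0.1)
  expect_lt(mean(miss), 0.3)
})
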