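fixture_cases <- local({
  d <- add_wealth_quintile(reconstruct_fixture(survey_fixture_spec()))
  d[classify_case(d), ]
})

test_that("cross-tabs partition the cases with correct margins", {
  tab <- case_crosstab(fixture_cases, "sex")
  expect_equal(unname(tab["male", ]), c(67L, 75L))
  expect_equal(unname(tab["female", ]), c(242L, 176L))
  expect_equal(unname(attr(tab, "col_margin")), c(309L, 251L))
  expect_error(case_crosstab(fixture_cases[0, ], "sex"), "empty")
})

test_that("cross-tab cells equal brute-force per-record counts", {
  d <- add_wealth_quintile(
    generate_population(generator_params(n_per_setting = 400L, seed = 6L)))
  cases <- d[classify_case(d), ]
  for (cov in c("age_group", "sex", "wealth_quintile", "setting")) {
    tab <- case_crosstab(cases, cov)
    expect_equal(unclass(tab)[, 1:2], oracle_crosstab(cases, cov),
                 ignore_attr = TRUE, label = cov)
  }
})

test_that("chi-square test matches its contract", {
  sex_p <- crosstab_test(case_crosstab(fixture_cases, "sex"))
  expect_equal(sex_p$df, 1L)
  expect_equal(round_half_up(sex_p$p_value, 2), 0.03)
  age_p <- crosstab_test(case_crosstab(fixture_cases, "age_group"))
  expect_lt(age_p$p_value, 0.001)

  # identical row distributions: statistic 0, p 1
  even <- matrix(c(10L, 20L, 5L, 10L), nrow = 2,
                 dimnames = list(c("a", "b"), c("diagnosed", "undiagnosed")))
  r <- crosstab_test(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  expect_error(crosstab_test(matrix(c(3L, 4L, 0L, 0L), nrow = 2)),
               "degenerate")
  expect_warning(crosstab_test(matrix(c(2L, 3L, 4L, 30L), nrow = 2)),
                 "expected cell count")
  fr <- crosstab_test(matrix(c(2L, 3L, 4L, 30L), nrow = 2),
                      method = "fisher")
  expect_true(fr$p_value >= 0 && fr$p_value <= 1)
})

test_that("a single binary covariate reproduces the cross-product odds ratio", {
  cases <- fixture_cases
  fit <- fit_undiagnosed_model(cases, covariates = "sex", alpha = 1)
  tab <- case_crosstab(cases, "sex")
  # odds of undiagnosed for males over females
  or <- (tab["male", "undiagnosed"] / tab["male", "diagnosed"]) /
    (tab["female", "undiagnosed"] / tab["female", "diagnosed"])
  aor <- fit$table$aor[fit$table$level == "male"]
  expect_equal(aor, unname(or), tolerance = 1e-6)
})

test_that("backward elimination is deterministic and traces are ordered", {
  d <- add_wealth_quintile(
    generate_population(generator_params(
      n_per_setting = 1000L,
      undiagnosed_logodds = c(age_40_49 = log(3.2)), seed = 13L)))
  cases <- d[classify_case(d), ]
  f1 <- fit_undiagnosed_model(cases)
  f2 <- fit_undiagnosed_model(cases)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$retained, f2$retained)
  expect_true("age_group" %in% f1$retained)
  if (nrow(f1$trace) > 0) {
    expect_identical(f1$trace$step, seq_len(nrow(f1$trace)))
  }
  # every retained block is significant, references are pinned at OR 1
  expect_true(all(f1$block_p < 0.05))
  refs <- f1$table[f1$table$reference, ]
  expect_true(all(refs$aor == 1))
  non_ref <- f1$table[!f1$table$reference, ]
  expect_true(all(non_ref$ci_low <= non_ref$aor &
                    non_ref$aor <= non_ref$ci_high))
})

test_that("Wald block tests are available and broadly agree with LRT", {
  f_lrt <- fit_undiagnosed_model(fixture_cases, test = "LRT")
  f_wald <- fit_undiagnosed_model(fixture_cases, test = "Wald")
  expect_true(length(f_wald$retained) >= 0)
  expect_setequal(f_lrt$retained, f_wald$retained)
})

test_that("perfect separation is reported with the offending level", {
  n <- 40L
  cases <- tibble::tibble(
    ever_told_t2d = rep(c(TRUE, FALSE), each = n / 2),
    sex = factor(rep(c("female", "male"), each = n / 2),
                 levels = c("male", "female")))
  expect_error(fit_undiagnosed_model(cases, covariates = "sex"),
               "separation")
})
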