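#' Parameters for the synthetic survey population generator
#'
#' Defaults are calibrated to a 2020 five-district Cambodian population-based
#' survey of adults aged 40+: a total of ~5070 participants (1014 per
#' care-initiative setting), T2D prevalence 11.04%, and stage retention
#' probabilities equal to the printed cascade ratios (tested 353/560,
#' diagnosed-given-tested 309/353, in-care-given-diagnosed 279/309,
#' treated-given-care 273/279, controlled-given-treated 60/273).
#'
#' @param n_per_setting Participants per care-initiative setting (5 settings).
#' @param prevalence Probability that a participant is a true T2D case.
#' @param p_tested_given_case,p_diagnosed_given_tested,p_care_given_diagnosed,p_treated_given_care,p_control_given_treated
#'   Stage retention probabilities along the nested cascade.
#' @param undiagnosed_logodds Named numeric vector of log-odds offsets applied
#'   to the probability that a case is undiagnosed (never told). Recognised
#'   names: `age_40_49`, `age_50_59`, `male`, `wealth_q1`, and
#'   `setting_<level>` for the non-reference settings. Unlisted names default
#'   to 0. The baseline (all offsets zero) is calibrated so that the marginal
#'   probability of being diagnosed equals
#'   `p_tested_given_case * p_diagnosed_given_tested`.
#' @param background_tested_rate Probability a non-case reports a blood
#'   glucose test in the last 3 years.
#' @param p_advice_bundle Probability that a treated case reports all four
#'   lifestyle-advice items.
#' @param prop_missing_biomarkers Proportion of participants whose FBG and
#'   HbA1c are blanked to `NA` (default 0; no missingness protocol is
#'   emulated by default).
#' @param seed Integer seed; identical seed and parameters give
#'   byte-identical output.
#' @return A validated list of class `generator_params`.
#' @export
generator_params <- function(n_per_setting = 1014L,
                             prevalence = 560 / 5072,
                             p_tested_given_case = 353 / 560,
                             p_diagnosed_given_tested = 309 / 353,
                             p_care_given_diagnosed = 279 / 309,
                             p_treated_given_care = 273 / 279,
                             p_control_given_treated = 60 / 273,
                             undiagnosed_logodds = numeric(0),
                             background_tested_rate = 0.25,
                             p_advice_bundle = 130 / 273,
                             prop_missing_biomarkers = 0,
                             seed = 1L) {
  params <- list(
    n_per_setting = as.integer(n_per_setting),
    prevalence = prevalence,
    p_tested_given_case = p_tested_given_case,
    p_diagnosed_given_tested = p_diagnosed_given_tested,
    p_care_given_diagnosed = p_care_given_diagnosed,
    p_treated_given_care = p_treated_given_care,
    p_control_given_treated = p_control_given_treated,
    undiagnosed_logodds = undiagnosed_logodds,
    background_tested_rate = background_tested_rate,
    p_advice_bundle = p_advice_bundle,
    prop_missing_biomarkers = prop_missing_biomarkers,
    seed = as.integer(seed)
  )
  probs <- c("prevalence", "p_tested_given_case", "p_diagnosed_given_tested",
             "p_care_given_diagnosed", "p_treated_given_care",
             "p_control_given_treated", "background_tested_rate",
             "p_advice_bundle", "prop_missing_biomarkers")
  for (p in probs) {
    v <- params[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("parameter '%s' must be a probability in [0, 1]", p),
           call. = FALSE)
    }
  }
  if (is.na(params$n_per_setting) || params$n_per_setting < 1L) {
    stop("parameter 'n_per_setting' must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(params$undiagnosed_logodds) ||
      (length(params$undiagnosed_logodds) > 0L &&
       is.null(names(params$undiagnosed_logodds)))) {
    stop("parameter 'undiagnosed_logodds' must be a named numeric vector",
         call. = FALSE)
  }
  structure(params, class = "generator_params")
}

# log-odds offset applicable to one covariate profile
logodds_lookup <- function(offsets, name) {
  if (name %in% names(offsets)) unname(offsets[[name]]) else 0
}

#' Generate a synthetic survey population
#'
#' Simulates one participant per household under the structure the cascade
#' analysis assumes: covariates are drawn first (age, sex, education, marital
#' status, a one-factor latent-wealth asset model, and an equal allocation
#' over the five care-initiative settings); T2D case status is Bernoulli with
#' the configured prevalence; stage flags follow a nested chain in which a
#' stage can only be reached from the preceding one; and diagnosis status is
#' the single covariate-dependent stage, with planted log-odds offsets on the
#' probability of remaining undiagnosed. True cases receive biomarkers above
#' the case thresholds; treated-and-controlled cases receive HbA1c below the
#' control threshold; non-cases receive HbA1c below the case threshold so the
#' biomarker case definition recovers exactly the simulated case set.
#'
#' @param params A [generator_params()] object.
#' @return A validated microdata tibble (one row per participant) with the
#'   latent case/stage indicators recoverable through the cascade engine.
#' @export
generate_population <- function(params) {
  if (!inherits(params, "generator_params")) {
    params <- do.call(generator_params, as.list(params))
  }
  withr::with_seed(params$seed, generate_population_impl(params))
}

generate_population_impl <- function(params) {
  n_set <- params$n_per_setting
  n <- 5L * n_set
  setting <- factor(rep(setting_levels(), each = n_set),
                    levels = setting_levels())

  # demographics: age decays over 40..89; survey samples skew female
  ages <- 40:89
  age_years <- sample(ages, n, replace = TRUE, prob = exp(-0.035 * (ages - 40)))
  age_group <- age_to_group(age_years)
  sex <- factor(ifelse(stats::runif(n) < 0.60, "female", "male"),
                levels = c("male", "female"))
  education <- factor(sample(c("none_or_less_than_primary", "primary",
                               "secondary_or_higher"),
                             n, replace = TRUE, prob = c(0.33, 0.52, 0.15)),
                      levels = microdata_schema()$education)
  marital <- factor(sample(c("married_or_with_spouse",
                             "widowed_or_not_with_spouse", "never"),
                           n, replace = TRUE, prob = c(0.66, 0.31, 0.03)),
                    levels = microdata_schema()$marital)

  # one-factor latent wealth; quintile from theoretical N(0,1) quantiles
  z <- stats::rnorm(n)
  alpha <- seq(-2.2, 2.2, length.out = 20L)
  assets <- matrix(0L, nrow = n, ncol = 20L,
                   dimnames = list(NULL, asset_columns()))
  for (j in seq_len(20L)) {
    assets[, j] <- as.integer(stats::runif(n) <
                                stats::plogis(alpha[j] + 1.2 * z))
  }
  latent_quintile <- findInterval(z, stats::qnorm(c(0.2, 0.4, 0.6, 0.8))) + 1L

  is_case <- stats::runif(n) < params$prevalence

  # marginal targets implied by the retention chain
  p_tested <- params$p_tested_given_case
  p_diag_marg <- p_tested * params$p_diagnosed_given_tested
  off <- params$undiagnosed_logodds
  eta <- stats::qlogis(1 - p_diag_marg) +
    logodds_lookup(off, "age_40_49") * (age_group == "40-49") +
    logodds_lookup(off, "age_50_59") * (age_group == "50-59") +
    logodds_lookup(off, "male") * (sex == "male") +
    logodds_lookup(off, "wealth_q1") * (latent_quintile == 1L)
  for (lev in setting_levels()[-1L]) {
    eta <- eta + logodds_lookup(off, paste0("setting_", lev)) * (setting == lev)
  }
  undiag <- is_case & (stats::runif(n) < stats::plogis(eta))
  told <- is_case & !undiag

  # probability an undiagnosed case was nonetheless tested, chosen so the
  # marginal tested proportion matches p_tested at zero planted offsets
  p_t_u <- if (p_diag_marg >= 1) 1 else {
    min(max((p_tested - p_diag_marg) / (1 - p_diag_marg), 0), 1)
  }
  tested <- told | (undiag & stats::runif(n) < p_t_u)
  care <- told & stats::runif(n) < params$p_care_given_diagnosed
  treat <- care & stats::runif(n) < params$p_treated_given_care
  control <- treat & stats::runif(n) < params$p_control_given_treated

  # biomarkers consistent with case and control status
  fbg <- stats::rnorm(n, 98, 13)
  fbg[is_case] <- stats::runif(sum(is_case), 130, 280)
  fbg <- pmin(pmax(fbg, 55), 450)
  hba1c <- pmin(pmax(stats::rnorm(n, 5.6, 0.45), 3.5), 6.49)
  hba1c[is_case] <- stats::runif(sum(is_case), 6.6, 13)
  hba1c[control] <- stats::runif(sum(control), 6.6, 7.9)
  hba1c[treat & !control] <- stats::runif(sum(treat & !control), 8.2, 13)

  insulin <- treat & stats::runif(n) < 0.10
  drugs <- treat

  bundle <- treat & stats::runif(n) < params$p_advice_bundle
  adv <- matrix(stats::runif(4L * n) < 0.6, nrow = n)
  adv[bundle, ] <- TRUE
  adv[!treat, ] <- FALSE
  partial <- treat & !bundle
  all4 <- partial & adv[, 1L] & adv[, 2L] & adv[, 3L] & adv[, 4L]
  adv[all4, 3L] <- FALSE   # a non-bundle participant must miss >=1 item

  provider <- rep("none", n)
  n_told <- sum(told)
  if (n_told > 0L) {
    provider[told] <- sample(c("public", "private", "other"), n_told,
                             replace = TRUE, prob = c(0.39, 0.57, 0.04))
  }

  tested_bg <- stats::runif(n) < params$background_tested_rate
  tested <- ifelse(is_case, tested, tested_bg)

  if (params$prop_missing_biomarkers > 0) {
    blank <- stats::runif(n) < params$prop_missing_biomarkers
    fbg[blank] <- NA_real_
    hba1c[blank] <- NA_real_
  }

  data <- tibble::tibble(
    participant_id = sprintf("P%06d", seq_len(n)),
    household_id = sprintf("H%06d", seq_len(n)),
    setting = setting,
    age_years = as.integer(age_years),
    age_group = age_group,
    sex = sex,
    education = education,
    marital = marital
  )
  for (j in seq_len(20L)) data[[asset_columns()[j]]] <- assets[, j]
  data$fbg_mg_dl <- fbg
  data$hba1c_pct <- hba1c
  data$takes_t2d_drugs <- drugs
  data$takes_insulin <- insulin
  data$ever_tested_3y <- tested
  data$ever_told_t2d <- told
  data$care_past_12m <- care
  data$advice_diet <- adv[, 1L]
  data$advice_weight <- adv[, 2L]
  data$advice_smoking <- adv[, 3L]
  data$advice_exercise <- adv[, 4L]
  data$provider_of_diagnosis <- factor(provider,
                                       levels = c("public", "private",
                                                  "other", "none"))
  validate_microdata(data)
  data
}
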