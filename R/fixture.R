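#' Fixture specification: aggregate counts for deterministic reconstruction
#'
#' A fixture spec holds the aggregate counts a survey report prints — the six
#' fixed-denominator cascade bars, the advice bundle count, the raised-FBG
#' count, one-way covariate tables split by diagnosed/undiagnosed status, and
#' diagnosing-provider counts — from which [reconstruct_fixture()] builds an
#' individual-level dataset reproducing every count exactly.
#'
#' @param total_n Total survey size.
#' @param raised_fbg Participants with FBG at or above the case threshold.
#' @param cascade Named list/vector of the six bar counts, in order:
#'   `prevalence`, `tested`, `diagnosed`, `in_care`, `in_treatment`,
#'   `under_control`.
#' @param advice_bundle Count of treated participants reporting all four
#'   advice items.
#' @param provider Named counts (`public`, `private`, `other`) of diagnosing
#'   providers among the diagnosed.
#' @param covariates Named list; each element has `levels`, `diagnosed` and
#'   `undiagnosed` count vectors for one covariate.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(total_n, raised_fbg, cascade, advice_bundle,
                         provider, covariates) {
  spec <- list(
    total_n = as.integer(total_n),
    raised_fbg = as.integer(raised_fbg),
    cascade = lapply(cascade, as.integer),
    advice_bundle = as.integer(advice_bundle),
    provider = lapply(provider, as.integer),
    covariates = covariates
  )
  stages <- c("prevalence", "tested", "diagnosed", "in_care",
              "in_treatment", "under_control")
  if (!identical(names(spec$cascade), stages)) {
    stop("fixture spec: cascade counts must be named ",
         paste(stages, collapse = ", "), " in that order", call. = FALSE)
  }
  bars <- unlist(spec$cascade)
  if (any(diff(bars) > 0L)) {
    stop("fixture spec: cascade bar counts must be non-increasing ",
         "(violated at '", stages[which(diff(bars) > 0L)[1L] + 1L], "')",
         call. = FALSE)
  }
  if (any(bars < 0L) || spec$total_n < 0L) {
    stop("fixture spec: counts must be non-negative", call. = FALSE)
  }
  if (bars[["prevalence"]] > spec$total_n) {
    stop("fixture spec: prevalence count exceeds total_n", call. = FALSE)
  }
  if (spec$advice_bundle > spec$cascade$in_treatment) {
    stop("fixture spec: advice_bundle count exceeds in_treatment count",
         call. = FALSE)
  }
  if (spec$raised_fbg < spec$cascade$prevalence ||
      spec$raised_fbg > spec$total_n) {
    stop("fixture spec: raised_fbg must lie between the prevalence count ",
         "and total_n", call. = FALSE)
  }
  if (sum(unlist(spec$provider)) != spec$cascade$diagnosed) {
    stop("fixture spec: provider counts must sum to the diagnosed count",
         call. = FALSE)
  }
  n_diag <- spec$cascade$diagnosed
  n_undiag <- spec$cascade$prevalence - n_diag
  for (cov in names(spec$covariates)) {
    tab <- spec$covariates[[cov]]
    if (!all(c("levels", "diagnosed", "undiagnosed") %in% names(tab))) {
      stop(sprintf("fixture spec: covariate '%s' needs levels/diagnosed/%s",
                   cov, "undiagnosed"), call. = FALSE)
    }
    if (sum(tab$diagnosed) != n_diag || sum(tab$undiagnosed) != n_undiag) {
      stop(sprintf(paste0("fixture spec: covariate '%s' column sums (%d, %d) ",
                          "do not match diagnosed/undiagnosed totals (%d, %d)"),
                   cov, sum(tab$diagnosed), sum(tab$undiagnosed),
                   n_diag, n_undiag), call. = FALSE)
    }
  }
  structure(spec, class = "fixture_spec")
}

#' Read a fixture specification from YAML
#'
#' @param path Path to a YAML file with fields `total_n`, `raised_fbg`,
#'   `cascade`, `advice_bundle`, `provider` and `covariates`.
#' @return A validated `fixture_spec`.
#' @export
read_fixture_spec <- function(path) {
  y <- yaml::read_yaml(path)
  fixture_spec(total_n = y$total_n, raised_fbg = y$raised_fbg,
               cascade = y$cascade, advice_bundle = y$advice_bundle,
               provider = y$provider, covariates = y$covariates)
}

#' The packaged survey fixture specification
#'
#' Aggregate counts transcribed from a 2020 population-based T2D survey of
#' 5072 adults aged 40+ across five Cambodian operational districts: cascade
#' 560/353/309/279/273/60, advice bundle 130 of 273 treated, 614 participants
#' with raised FBG, provider counts 121/177/11, and one-way diagnosed vs
#' undiagnosed tables for age, sex, marital status, education, wealth
#' quintile and care-initiative setting.
#'
#' @return A validated `fixture_spec`.
#' @export
survey_fixture_spec <- function() {
  read_fixture_spec(system.file("extdata", "survey2020_fixture.yaml",
                                package = "carecascade", mustWork = TRUE))
}

# deterministic "first k of the group get this level" fill
greedy_fill <- function(counts, levels, n) {
  stopifnot(sum(counts) == n)
  factor(rep(levels, times = counts), levels = levels)
}

# deterministic strided fill: same level counts, but levels are laid out
# along a stride-permuted order so that fills of different covariates cross
# rather than align (aligned fills make the covariates collinear, which
# degenerates any joint model fitted to the reconstruction)
strided_fill <- function(counts, levels, n, stride) {
  v <- as.character(greedy_fill(counts, levels, n))
  if (n < 2L) return(v)
  while (gcd(stride, n) != 1L) stride <- stride + 1L
  pos <- ((seq_len(n) - 1L) * stride) %% n
  out <- character(n)
  out[order(pos)] <- v
  out
}

gcd <- function(a, b) if (b == 0L) a else gcd(b, a %% b)

# partition sizes used by rank-based quintile assignment (see wealth module)
quintile_capacity <- function(n) {
  tabulate(floor((seq_len(n) - 1L) * 5L / n) + 1L, nbins = 5L)
}

#' Deterministically reconstruct individual-level data from printed counts
#'
#' Builds exactly `total_n` participant records such that the cascade engine,
#' the wealth-index quintiles, the covariate cross-tabulations and the
#' provider counts reproduce every count in the spec. The construction is
#' seed-free: cases are laid out in a fixed stage order (controlled, treated
#' uncontrolled, in care untreated, diagnosed not in care, then undiagnosed
#' tested and untested), and each covariate is filled greedily along that
#' order within the diagnosed and undiagnosed groups (order: age, sex,
#' marital, education, wealth, setting). Only the printed one-way margins are
#' guaranteed; higher-order joints are arbitrary. Biomarker values are
#' synthetic representatives consistent with each record's stage membership
#' (cases FBG 150 with HbA1c 9, controlled cases HbA1c 7.2, raised-FBG
#' non-cases FBG 140 with HbA1c 6.0, remaining non-cases FBG 95, HbA1c 5.4).
#' Household asset patterns are nested by intended wealth quintile so the
#' principal-component wealth index recovers the intended quintiles exactly.
#'
#' @param spec A `fixture_spec`.
#' @return A validated microdata tibble with `total_n` rows.
#' @export
reconstruct_fixture <- function(spec) {
  if (!inherits(spec, "fixture_spec")) {
    stop("reconstruct_fixture() needs a fixture_spec", call. = FALSE)
  }
  n <- spec$total_n
  n_case <- spec$cascade$prevalence
  n_diag <- spec$cascade$diagnosed
  n_undiag <- n_case - n_diag
  n_noncase <- n - n_case

  # --- stage layout among cases (diagnosed block first, then undiagnosed)
  n_control <- spec$cascade$under_control
  n_treat <- spec$cascade$in_treatment
  n_care <- spec$cascade$in_care
  n_tested <- spec$cascade$tested
  n_tested_undiag <- n_tested - n_diag   # tested but never told
  if (n_tested_undiag > n_undiag) {
    stop("fixture spec: tested count exceeds diagnosed + undiagnosed capacity",
         call. = FALSE)
  }

  told <- c(rep(TRUE, n_diag), rep(FALSE, n_undiag))
  tested <- c(rep(TRUE, n_diag),
              rep(TRUE, n_tested_undiag),
              rep(FALSE, n_undiag - n_tested_undiag))
  care <- c(rep(TRUE, n_care), rep(FALSE, n_case - n_care))
  treat <- c(rep(TRUE, n_treat), rep(FALSE, n_case - n_treat))
  control <- c(rep(TRUE, n_control), rep(FALSE, n_case - n_control))

  advice <- matrix(FALSE, nrow = max(n_case, 0L), ncol = 4L)
  if (n_treat > 0L) {
    advice[seq_len(spec$advice_bundle), ] <- TRUE
    if (spec$advice_bundle < n_treat) {
      partial <- (spec$advice_bundle + 1L):n_treat
      advice[partial, c(1L, 2L, 4L)] <- TRUE   # three of four: no smoking item
    }
  }

  provider <- factor(
    c(as.character(greedy_fill(unlist(spec$provider), names(spec$provider),
                               n_diag)),
      rep("none", n_undiag)),
    levels = c("public", "private", "other", "none"))

  # --- covariates: greedy fill per status group, then a fixed plausible
  #     cycling pattern for non-cases
  strides <- c(age_group = 1L, sex = 7L, marital = 11L, education = 13L,
               wealth_quintile = 17L, setting = 19L)
  cov_fill <- function(cov) {
    st <- if (cov %in% names(strides)) strides[[cov]] else 23L
    tab <- spec$covariates[[cov]]
    c(strided_fill(tab$diagnosed, tab$levels, n_diag, st),
      strided_fill(tab$undiagnosed, tab$levels, n_undiag, st))
  }
  schema <- microdata_schema()
  default_levels <- list(age_group = age_group_levels(),
                         sex = c("male", "female"),
                         marital = schema$marital,
                         education = schema$education,
                         setting = setting_levels())
  cov_case <- list()
  for (cov in c("age_group", "sex", "marital", "education", "setting")) {
    cov_case[[cov]] <- if (cov %in% names(spec$covariates)) {
      cov_fill(cov)
    } else {
      # no table printed for this covariate: cycle levels deterministically
      default_levels[[cov]][((seq_len(n_case) - 1L) %%
                               length(default_levels[[cov]])) + 1L]
    }
  }

  # non-case settings top the per-setting totals up to a near-equal split
  set_lv <- setting_levels()
  set_target <- rep(n %/% 5L, 5L)
  if (n %% 5L > 0L) set_target[seq_len(n %% 5L)] <- set_target[seq_len(n %% 5L)] + 1L
  names(set_target) <- set_lv
  case_set <- table(factor(cov_case$setting, levels = set_lv))
  noncase_set <- set_target - as.integer(case_set)
  if (any(noncase_set < 0L)) {
    stop("fixture spec: per-setting case counts exceed a near-equal ",
         "allocation of total_n", call. = FALSE)
  }
  cyc <- function(levels, m) levels[((seq_len(m) - 1L) %% length(levels)) + 1L]
  noncase <- list(
    age_group = cyc(age_group_levels(), n_noncase),
    sex = cyc(c("female", "male"), n_noncase),
    marital = cyc(schema$marital, n_noncase),
    education = cyc(schema$education, n_noncase),
    setting = rep(set_lv, times = noncase_set)
  )

  # --- wealth: intended quintile per record; asset patterns nested so the
  #     PCA index recovers them (asset j owned iff quintile >= threshold_j)
  cap <- quintile_capacity(n)
  wl <- spec$covariates$wealth_quintile
  case_q <- if (!is.null(wl) && n_case > 0L) {
    as.integer(c(strided_fill(wl$diagnosed, wl$levels, n_diag, 17L),
                 strided_fill(wl$undiagnosed, wl$levels, n_undiag, 17L)))
  } else {
    rep(1:5, length.out = n_case)   # no wealth table printed: spread evenly
  }
  noncase_q_counts <- cap - tabulate(case_q, nbins = 5L)
  if (any(noncase_q_counts < 0L)) {
    stop("fixture spec: case wealth-quintile counts exceed the rank-partition",
         " capacity of total_n", call. = FALSE)
  }
  noncase_q <- rep(1:5, times = noncase_q_counts)
  quintile <- c(case_q, noncase_q)
  thresholds <- rep(2:5, each = 5L)
  assets <- outer(quintile, thresholds, ">=") * 1L
  colnames(assets) <- asset_columns()

  # --- biomarkers
  n_raised_noncase <- spec$raised_fbg - n_case
  fbg <- c(rep(150, n_case), rep(140, n_raised_noncase),
           rep(95, n_noncase - n_raised_noncase))
  hba1c_case <- rep(9, n_case)
  if (n_control > 0L) hba1c_case[seq_len(n_control)] <- 7.2
  hba1c <- c(hba1c_case, rep(6.0, n_raised_noncase),
             rep(5.4, n_noncase - n_raised_noncase))

  age_group <- factor(c(cov_case$age_group, noncase$age_group),
                      levels = age_group_levels())
  age_years <- c(45L, 55L, 67L)[as.integer(age_group)]

  pad <- function(x, filler) c(x, rep(filler, n_noncase))
  data <- tibble::tibble(
    participant_id = sprintf("P%06d", seq_len(n)),
    household_id = sprintf("H%06d", seq_len(n)),
    setting = factor(c(cov_case$setting, noncase$setting), levels = set_lv),
    age_years = age_years,
    age_group = age_group,
    sex = factor(c(cov_case$sex, noncase$sex), levels = c("male", "female")),
    education = factor(c(cov_case$education, noncase$education),
                       levels = schema$education),
    marital = factor(c(cov_case$marital, noncase$marital),
                     levels = schema$marital)
  )
  for (j in seq_len(20L)) data[[asset_columns()[j]]] <- assets[, j]
  data$fbg_mg_dl <- fbg
  data$hba1c_pct <- hba1c
  data$takes_t2d_drugs <- pad(treat, FALSE)
  data$takes_insulin <- rep(FALSE, n)
  data$ever_tested_3y <- pad(tested, FALSE)
  data$ever_told_t2d <- pad(told, FALSE)
  data$care_past_12m <- pad(care, FALSE)
  data$advice_diet <- pad(advice[, 1L], FALSE)
  data$advice_weight <- pad(advice[, 2L], FALSE)
  data$advice_smoking <- pad(advice[, 3L], FALSE)
  data$advice_exercise <- pad(advice[, 4L], FALSE)
  data$provider_of_diagnosis <- factor(pad(as.character(provider), "none"),
                                       levels = c("public", "private",
                                                  "other", "none"))
  validate_microdata(data)
  data
}
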