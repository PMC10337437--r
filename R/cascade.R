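#' Cascade configuration: thresholds and recall windows
#'
#' Case definition: FBG >= `fbg_threshold` (capillary plasma, mg/dL) and
#' HbA1c >= `hba1c_case_threshold` (%), or reported use of T2D drugs or
#' insulin irrespective of biomarker values. Glycaemic control among the
#' treated requires HbA1c < `hba1c_control_threshold`. The recall windows
#' (testing 3 years, care 12 months, treatment 2 weeks) document the
#' self-report questions behind the flags; the flags in the microdata are
#' already window-specific.
#'
#' @param fbg_threshold FBG case threshold, mg/dL.
#' @param hba1c_case_threshold HbA1c case threshold, %.
#' @param hba1c_control_threshold HbA1c control threshold, %; must exceed the
#'   case threshold.
#' @param testing_window_years,care_window_months,treatment_window_weeks
#'   Recall windows of the self-report questions.
#' @param denominator_mode `"fixed"`: all percentages use the prevalence bar
#'   as denominator.
#' @return A validated list of class `cascade_config`.
#' @export
cascade_config <- function(fbg_threshold = 126,
                           hba1c_case_threshold = 6.5,
                           hba1c_control_threshold = 8,
                           testing_window_years = 3,
                           care_window_months = 12,
                           treatment_window_weeks = 2,
                           denominator_mode = "fixed") {
  cfg <- list(fbg_threshold = fbg_threshold,
              hba1c_case_threshold = hba1c_case_threshold,
              hba1c_control_threshold = hba1c_control_threshold,
              testing_window_years = testing_window_years,
              care_window_months = care_window_months,
              treatment_window_weeks = treatment_window_weeks,
              denominator_mode = match.arg(denominator_mode, "fixed"))
  thr <- c(cfg$fbg_threshold, cfg$hba1c_case_threshold,
           cfg$hba1c_control_threshold)
  if (any(!is.finite(thr)) || any(thr <= 0)) {
    stop("cascade thresholds must be positive", call. = FALSE)
  }
  if (cfg$hba1c_control_threshold <= cfg$hba1c_case_threshold) {
    stop("hba1c_control_threshold must exceed hba1c_case_threshold",
         call. = FALSE)
  }
  structure(cfg, class = "cascade_config")
}

cascade_stages <- function() {
  c("tested", "diagnosed", "in_care", "in_treatment", "under_control")
}

#' Classify participants as prevalent T2D cases
#'
#' A case has both biomarkers non-missing and at or above the case thresholds
#' (FBG >= 126 mg/dL and HbA1c >= 6.5% by default), or reports taking T2D
#' drugs or insulin irrespective of biomarker values. A missing biomarker
#' fails the biomarker clause; no imputation is attempted.
#'
#' @param data Microdata tibble.
#' @param config A [cascade_config()].
#' @return Logical vector, one element per row of `data`.
#' @export
classify_case <- function(data, config = cascade_config()) {
  biomarker <- !is.na(data$fbg_mg_dl) & !is.na(data$hba1c_pct) &
    data$fbg_mg_dl >= config$fbg_threshold &
    data$hba1c_pct >= config$hba1c_case_threshold
  biomarker | data$takes_t2d_drugs | data$takes_insulin
}

#' Classify cases into a nested cascade stage
#'
#' Stages are nested conjunctions evaluated per participant:
#' `tested` = blood glucose test in the last 3 years; `diagnosed` = tested
#' and ever told by a health worker; `in_care` = diagnosed and care in the
#' past 12 months; `in_treatment` = in care and taking T2D drugs or insulin
#' (past 2 weeks); `under_control` = in treatment and HbA1c (non-missing)
#' below the control threshold. A respondent reporting a diagnosis but no
#' test does not count as diagnosed.
#'
#' @param data Microdata tibble (rows need not be pre-filtered to cases; the
#'   returned flags are stage memberships given case status).
#' @param stage One of `"tested"`, `"diagnosed"`, `"in_care"`,
#'   `"in_treatment"`, `"under_control"`.
#' @param config A [cascade_config()].
#' @return Logical vector, one element per row of `data`.
#' @export
classify_stage <- function(data, stage, config = cascade_config()) {
  if (length(stage) != 1L || !(stage %in% cascade_stages())) {
    stop("unknown cascade stage: ", paste(stage, collapse = ", "),
         " (expected one of ", paste(cascade_stages(), collapse = ", "), ")",
         call. = FALSE)
  }
  tested <- data$ever_tested_3y
  diagnosed <- tested & data$ever_told_t2d
  in_care <- diagnosed & data$care_past_12m
  in_treatment <- in_care & (data$takes_t2d_drugs | data$takes_insulin)
  under_control <- in_treatment & !is.na(data$hba1c_pct) &
    data$hba1c_pct < config$hba1c_control_threshold
  switch(stage,
         tested = tested,
         diagnosed = diagnosed,
         in_care = in_care,
         in_treatment = in_treatment,
         under_control = under_control)
}

#' Advice bundle indicator
#'
#' TRUE iff all four lifestyle-advice items are reported: prescribed diet,
#' advice to lose weight, to stop smoking, and to start or increase physical
#' exercise. Reported among the treated as a secondary indicator, not a
#' cascade bar.
#'
#' @param data Microdata tibble.
#' @return Logical vector, one element per row of `data`.
#' @export
advice_bundle <- function(data) {
  data$advice_diet & data$advice_weight & data$advice_smoking &
    data$advice_exercise
}

cascade_one <- function(data, config, stratum = NA_character_) {
  case <- classify_case(data, config)
  denom <- sum(case)
  counts <- unname(vapply(cascade_stages(),
                          function(s) sum(case & classify_stage(data, s,
                                                                config)),
                          integer(1L)))
  raw_counts <- c(
    tested = sum(case & data$ever_tested_3y),
    told = sum(case & data$ever_told_t2d),
    in_care = sum(case & data$care_past_12m),
    on_medication = sum(case & (data$takes_t2d_drugs | data$takes_insulin))
  )
  pct <- if (denom > 0L) 100 * counts / denom else rep(0, length(counts))
  treated <- case & classify_stage(data, "in_treatment", config)
  n_treated <- sum(treated)
  n_bundle <- sum(treated & advice_bundle(data))
  structure(list(
    stratum = stratum,
    total_n = nrow(data),
    denominator = denom,
    prevalence_pct = if (nrow(data) > 0L) 100 * denom / nrow(data) else 0,
    raised_fbg = sum(!is.na(data$fbg_mg_dl) &
                       data$fbg_mg_dl >= config$fbg_threshold),
    bars = tibble::tibble(stage = c("prevalence", cascade_stages()),
                          count = c(denom, counts),
                          percent = c(if (denom > 0L) 100 else 0, pct)),
    advice_bundle = list(count = n_bundle, n_treated = n_treated,
                         percent = if (n_treated > 0L)
                           100 * n_bundle / n_treated else 0),
    undiagnosed = list(count = denom - sum(case & data$ever_told_t2d),
                       percent = if (denom > 0L)
                         100 * (denom - sum(case & data$ever_told_t2d)) /
                           denom else 0),
    raw_counts = raw_counts,
    all_zero = denom == 0L,
    config = config
  ), class = "cascade_result")
}

#' Build fixed-denominator cascade(s) of care
#'
#' The denominator is the prevalence-bar count ([classify_case()]); each bar
#' counts the cases passing the corresponding nested stage; every percentage,
#' including *under control*, is computed against the fixed denominator.
#' Non-nested (raw) flag counts are kept in `raw_counts` for diagnostics.
#' With `stratify_by = "setting"`, returns one result per care-initiative
#' setting plus the overall result.
#'
#' @param data Microdata tibble.
#' @param config A [cascade_config()].
#' @param stratify_by Optional stratification column (currently `"setting"`).
#' @return A `cascade_result`, or a named list of class `cascade_set`
#'   (element `"overall"` first) when stratified. Populations with zero
#'   cases yield all-zero bars with `all_zero = TRUE` and percentages
#'   defined as 0.
#' @export
build_cascade <- function(data, config = cascade_config(),
                          stratify_by = NULL) {
  if (nrow(data) == 0L) {
    stop("build_cascade() needs a non-empty collection of individuals",
         call. = FALSE)
  }
  if (is.null(stratify_by)) {
    return(cascade_one(data, config, stratum = "overall"))
  }
  stratify_by <- match.arg(stratify_by, "setting")
  strata <- levels(data[[stratify_by]])
  out <- c(list(overall = cascade_one(data, config, "overall")),
           stats::setNames(
             lapply(strata, function(s) {
               cascade_one(data[data[[stratify_by]] == s, , drop = FALSE],
                           config, s)
             }),
             strata))
  structure(out, class = "cascade_set")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("T2D cascade of care (%s): %d of %d participants (%.2f%%)\n",
              x$stratum, x$denominator, x$total_n, x$prevalence_pct))
  bars <- x$bars
  bars$percent <- round_half_up(bars$percent, 1)
  print(bars, n = nrow(bars))
  cat(sprintf("advice bundle: %d of %d treated (%.1f%%)\n",
              x$advice_bundle$count, x$advice_bundle$n_treated,
              round_half_up(x$advice_bundle$percent, 1)))
  if (x$all_zero) cat("note: zero cases; all bars are zero\n")
  invisible(x)
}

#' @export
print.cascade_set <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Cascade results as a long tibble
#'
#' @param results A `cascade_result` or `cascade_set`.
#' @return Tibble with columns `stratum`, `stage`, `count`, `percent`
#'   (percent of the fixed denominator), six bars per stratum, overall
#'   stratum first.
#' @export
cascade_table <- function(results) {
  if (inherits(results, "cascade_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    tibble::tibble(stratum = r$stratum, stage = r$bars$stage,
                   count = r$bars$count, percent = r$bars$percent)
  })
  do.call(rbind, rows)
}
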