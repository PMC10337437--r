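# Independent brute-force oracles. These deliberately re-derive every
# quantity record by record with plain loops and ifs, sharing no code with
# the package implementation.

oracle_cascade_counts <- function(data, fbg_thr = 126, case_thr = 6.5,
                                  ctl_thr = 8) {
  counts <- c(prevalence = 0L, tested = 0L, diagnosed = 0L, in_care = 0L,
              in_treatment = 0L, under_control = 0L)
  df <- as.data.frame(data)
  for (i in seq_len(nrow(df))) {
    fbg <- df$fbg_mg_dl[i]; a1c <- df$hba1c_pct[i]
    bio <- !is.na(fbg) && !is.na(a1c) && fbg >= fbg_thr && a1c >= case_thr
    case <- bio || df$takes_t2d_drugs[i] || df$takes_insulin[i]
    if (!case) next
    counts["prevalence"] <- counts["prevalence"] + 1L
    if (!df$ever_tested_3y[i]) next
    counts["tested"] <- counts["tested"] + 1L
    if (!df$ever_told_t2d[i]) next
    counts["diagnosed"] <- counts["diagnosed"] + 1L
    if (!df$care_past_12m[i]) next
    counts["in_care"] <- counts["in_care"] + 1L
    if (!(df$takes_t2d_drugs[i] || df$takes_insulin[i])) next
    counts["in_treatment"] <- counts["in_treatment"] + 1L
    if (!is.na(a1c) && a1c < ctl_thr) {
      counts["under_control"] <- counts["under_control"] + 1L
    }
  }
  counts
}

oracle_crosstab <- function(cases, covariate) {
  df <- as.data.frame(cases)
  lv <- levels(df[[covariate]])
  out <- matrix(0L, nrow = length(lv), ncol = 2L,
                dimnames = list(lv, c("diagnosed", "undiagnosed")))
  for (i in seq_len(nrow(df))) {
    l <- as.character(df[[covariate]][i])
    j <- if (df$ever_told_t2d[i]) 1L else 2L
    out[l, j] <- out[l, j] + 1L
  }
  out
}

# Conditional permutation null for the Pearson statistic: permute the column
# labels against the row labels, keeping both margins fixed.
oracle_permutation_p <- function(tab, B = 20000) {
  nr <- nrow(tab); nc <- ncol(tab)
  rows <- rep(seq_len(nr), times = rowSums(tab))
  cols <- rep(rep(seq_len(nc), times = nr), times = as.vector(t(tab)))
  pearson <- function(t) {
    E <- outer(rowSums(t), colSums(t)) / sum(t)
    sum((t - E)^2 / E)
  }
  obs <- pearson(tab)
  hits <- 0L
  for (b in seq_len(B)) {
    t2 <- table(factor(rows, seq_len(nr)), factor(sample(cols), seq_len(nc)))
    if (pearson(t2) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / B
}

# First-principal-component scores via an explicit eigendecomposition of the
# correlation matrix.
oracle_pc1_scores <- function(x) {
  s <- scale(x)
  e <- eigen(stats::cor(x), symmetric = TRUE)
  drop(s %*% e$vectors[, 1L])
}

# minimal single participant record for classification tests
make_record <- function(fbg = 95, hba1c = 5.5, drugs = FALSE,
                        insulin = FALSE, tested = FALSE, told = FALSE,
                        care = FALSE, advice = c(FALSE, FALSE, FALSE, FALSE),
                        setting = "hospital_based") {
  tibble::tibble(
    setting = factor(setting, levels = carecascade::setting_levels()),
    fbg_mg_dl = fbg, hba1c_pct = hba1c,
    takes_t2d_drugs = drugs, takes_insulin = insulin,
    ever_tested_3y = tested, ever_told_t2d = told, care_past_12m = care,
    advice_diet = advice[1], advice_weight = advice[2],
    advice_smoking = advice[3], advice_exercise = advice[4])
}

# adversarial microdata with arbitrary flag combinations (nesting NOT
# enforced), sufficient for the cascade engine
random_flag_data <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    setting = factor(sample(carecascade::setting_levels(), n, TRUE),
                     levels = carecascade::setting_levels()),
    fbg_mg_dl = ifelse(runif(n) < 0.05, NA, runif(n, 60, 300)),
    hba1c_pct = ifelse(runif(n) < 0.05, NA, runif(n, 4, 13)),
    takes_t2d_drugs = runif(n) < 0.3,
    takes_insulin = runif(n) < 0.1,
    ever_tested_3y = runif(n) < 0.5,
    ever_told_t2d = runif(n) < 0.5,
    care_past_12m = runif(n) < 0.5,
    advice_diet = runif(n) < 0.5, advice_weight = runif(n) < 0.5,
    advice_smoking = runif(n) < 0.5, advice_exercise = runif(n) < 0.5))
}
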