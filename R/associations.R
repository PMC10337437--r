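#' Cross-tabulate diagnosed vs undiagnosed cases by a covariate
#'
#' Restricted to prevalent cases, a case counts as *diagnosed* if ever told
#' by a health worker and *undiagnosed* otherwise. Rows are covariate levels,
#' columns diagnosed/undiagnosed; column sums equal the diagnosed and
#' undiagnosed totals.
#'
#' @param cases Microdata tibble restricted to cases (add `wealth_quintile`
#'   with [add_wealth_quintile()] before tabulating on wealth).
#' @param covariate One of `age_group`, `sex`, `marital`, `education`,
#'   `wealth_quintile`, `setting`, `provider_of_diagnosis`.
#' @return An object of class `case_crosstab`: integer matrix (levels x
#'   {diagnosed, undiagnosed}) with `row_margin`/`col_margin` attributes.
#' @export
case_crosstab <- function(cases, covariate) {
  allowed <- c("age_group", "sex", "marital", "education",
               "wealth_quintile", "setting", "provider_of_diagnosis")
  covariate <- match.arg(covariate, allowed)
  if (nrow(cases) == 0L) {
    stop("case_crosstab() called on an empty case set", call. = FALSE)
  }
  if (!covariate %in% names(cases)) {
    stop("covariate column not present: ", covariate, call. = FALSE)
  }
  status <- factor(ifelse(cases$ever_told_t2d, "diagnosed", "undiagnosed"),
                   levels = c("diagnosed", "undiagnosed"))
  tab <- table(cases[[covariate]], status)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  structure(counts,
            row_margin = rowSums(counts),
            col_margin = colSums(counts),
            covariate = covariate,
            class = c("case_crosstab", "matrix"))
}

#' Test independence in a case cross-tabulation
#'
#' Default is the Pearson chi-square test without continuity correction;
#' degrees of freedom `(rows-1)(cols-1)` and the p-value from the chi-square
#' upper tail. A warning is emitted when any expected cell count is below 5;
#' Fisher's exact test is available for such sparse tables.
#'
#' @param tab A `case_crosstab` or plain count matrix with at least 2 rows
#'   and 2 columns.
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return A list with `statistic`, `df`, `p_value`, `method` and the
#'   `expected` counts (`statistic`/`df`/`expected` are `NA` for Fisher).
#' @export
crosstab_test <- function(tab, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  counts <- unclass(tab)
  attributes(counts)[setdiff(names(attributes(counts)),
                             c("dim", "dimnames"))] <- NULL
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) < 2L || ncol(counts) < 2L || any(colSums(counts) == 0)) {
    stop("degenerate table: need >=2 rows and >=2 columns with positive ",
         "margins", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (method == "fisher") {
    ft <- stats::fisher.test(counts)
    return(list(statistic = NA_real_, df = NA_integer_,
                p_value = ft$p.value, method = "fisher",
                expected = expected))
  }
  if (any(expected < 5)) {
    warning("expected cell count below 5; chi-square approximation may be ",
            "poor (consider method = \"fisher\")", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, method = "chisq", expected = expected)
}

# block-level p-values for every covariate currently in the model
block_pvalues <- function(fit, blocks, data, test) {
  if (test == "LRT") {
    d <- stats::drop1(fit, test = "LRT")
    p <- d[["Pr(>Chi)"]]
    names(p) <- rownames(d)
    p <- p[blocks]
  } else {
    # block Wald chi-square: b' V^{-1} b over the block's coefficients
    cf <- stats::coef(fit)
    V <- stats::vcov(fit)
    asg <- attr(stats::model.matrix(fit), "assign")
    terms_lab <- attr(stats::terms(fit), "term.labels")
    p <- vapply(blocks, function(b) {
      j <- which(asg == match(b, terms_lab))
      j <- j[!is.na(cf[j])]
      b_hat <- cf[j]
      stat <- drop(t(b_hat) %*% solve(V[j, j, drop = FALSE], b_hat))
      stats::pchisq(stat, df = length(j), lower.tail = FALSE)
    }, numeric(1L))
  }
  p
}

#' Logistic model for undiagnosed status with backward elimination
#'
#' Fits a maximum-likelihood logistic regression of undiagnosed status (case
#' never told of the condition) on categorical covariate blocks, then removes
#' whole blocks by largest block p-value — likelihood-ratio tests by default —
#' until every remaining block is significant at `alpha`. Ties in p are
#' broken by the covariate order given. Reference levels follow the
#' convention: age 60+, female, richest quintile, hospital-based setting,
#' married, and no-formal-education. Adjusted odds ratios are
#' `exp(coefficient)` with Wald 95% CIs `exp(coefficient +/- 1.96 * SE)`.
#'
#' @param cases Microdata tibble restricted to cases, with `wealth_quintile`
#'   attached where used.
#' @param covariates Character vector of covariate blocks, in elimination
#'   tie-break order.
#' @param alpha Retention threshold on the block p-value.
#' @param test `"LRT"` (default) or `"Wald"` block tests.
#' @return An object of class `undiagnosed_fit`: `table` (level, AOR, CI,
#'   p-value, reference flags), `retained` blocks, `trace` of eliminations
#'   (step, variable removed, p at removal), `block_p` for the final model,
#'   and the final `fit`.
#' @export
fit_undiagnosed_model <- function(cases,
                                  covariates = c("age_group", "sex",
                                                 "marital", "education",
                                                 "wealth_quintile",
                                                 "setting"),
                                  alpha = 0.05,
                                  test = c("LRT", "Wald")) {
  test <- match.arg(test)
  if (nrow(cases) == 0L) {
    stop("fit_undiagnosed_model() called on an empty case set", call. = FALSE)
  }
  refs <- c(age_group = "60+", sex = "female", wealth_quintile = "5",
            setting = "hospital_based", marital = "married_or_with_spouse",
            education = "none_or_less_than_primary")
  df <- data.frame(undiagnosed = as.integer(!cases$ever_told_t2d))
  for (cov in covariates) {
    if (!cov %in% names(cases)) {
      stop("covariate column not present: ", cov, call. = FALSE)
    }
    x <- droplevels(factor(cases[[cov]]))
    if (cov %in% names(refs) && refs[[cov]] %in% levels(x)) {
      x <- stats::relevel(x, ref = refs[[cov]])
    }
    df[[cov]] <- x
  }
  # single-level blocks carry no contrast; drop them up front
  degenerate <- covariates[vapply(covariates,
                                  function(cv) nlevels(df[[cv]]) < 2L,
                                  logical(1L))]
  blocks <- setdiff(covariates, degenerate)

  fit_model <- function(blocks) {
    rhs <- if (length(blocks) == 0L) "1" else paste(blocks, collapse = " + ")
    f <- stats::as.formula(paste("undiagnosed ~", rhs))
    fit <- withCallingHandlers(
      stats::glm(f, family = stats::binomial(), data = df,
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")   # handled by the final-model check
        }
      })
    if (!fit$converged) {
      stop("logistic fit did not converge after ", fit$iter, " iterations",
           call. = FALSE)
    }
    fit
  }

  # separation makes a level's coefficient diverge; only the final model's
  # estimates are reported, so only there is it an error
  check_separation <- function(fit) {
    cf <- stats::coef(fit)
    big <- which(!is.na(cf) & abs(cf) > 12)
    big <- setdiff(names(cf)[big], "(Intercept)")
    if (length(big) > 0L) {
      stop("perfect separation detected at level(s): ",
           paste(big, collapse = ", "), call. = FALSE)
    }
  }

  fit <- fit_model(blocks)
  trace <- list()
  step <- 0L
  repeat {
    if (length(blocks) == 0L) break
    p <- block_pvalues(fit, blocks, df, test)
    if (max(p) < alpha) break
    # ties broken by the documented covariate order: first block at max p
    worst <- blocks[which(p >= max(p))[1L]]
    step <- step + 1L
    trace[[step]] <- tibble::tibble(step = step, removed = worst,
                                    p_at_removal = unname(max(p)))
    blocks <- setdiff(blocks, worst)
    fit <- fit_model(blocks)
  }
  check_separation(fit)
  block_p <- if (length(blocks) > 0L) {
    block_pvalues(fit, blocks, df, test)
  } else {
    stats::setNames(numeric(0), character(0))
  }

  sm <- summary(fit)$coefficients
  rows <- list()
  for (cov in blocks) {
    lv <- levels(df[[cov]])
    for (l in lv) {
      cname <- paste0(cov, l)
      is_ref <- l == lv[1L]
      if (is_ref) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          variable = cov, level = l, estimate = 0, se = NA_real_,
          aor = 1, ci_low = NA_real_, ci_high = NA_real_,
          p_value = NA_real_, reference = TRUE)
      } else {
        b <- sm[cname, "Estimate"]
        se <- sm[cname, "Std. Error"]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          variable = cov, level = l, estimate = b, se = se,
          aor = exp(b), ci_low = exp(b - 1.96 * se),
          ci_high = exp(b + 1.96 * se),
          p_value = sm[cname, "Pr(>|z|)"], reference = FALSE)
      }
    }
  }
  table <- if (length(rows) > 0L) do.call(rbind, rows) else
    tibble::tibble(variable = character(0), level = character(0),
                   estimate = numeric(0), se = numeric(0), aor = numeric(0),
                   ci_low = numeric(0), ci_high = numeric(0),
                   p_value = numeric(0), reference = logical(0))
  trace <- if (length(trace) > 0L) do.call(rbind, trace) else
    tibble::tibble(step = integer(0), removed = character(0),
                   p_at_removal = numeric(0))
  structure(list(table = table, retained = blocks, dropped_degenerate =
                   degenerate, trace = trace, block_p = block_p,
                 alpha = alpha, test = test, n = nrow(df), fit = fit),
            class = "undiagnosed_fit")
}

#' @export
print.undiagnosed_fit <- function(x, ...) {
  cat(sprintf("Undiagnosed-T2D logistic model (n = %d cases, %s block %s)\n",
              x$n, x$test, "tests"))
  if (length(x$retained) == 0L) {
    cat("no covariate block retained at alpha =", x$alpha, "\n")
  } else {
    cat("retained blocks:", paste(x$retained, collapse = ", "), "\n")
    tb <- x$table
    tb$aor <- round(tb$aor, 2)
    tb$ci_low <- round(tb$ci_low, 2)
    tb$ci_high <- round(tb$ci_high, 2)
    print(tb, n = nrow(tb))
  }
  if (nrow(x$trace) > 0L) {
    cat("eliminated:",
        paste(sprintf("%s (p=%.2f)", x$trace$removed, x$trace$p_at_removal),
              collapse = ", "), "\n")
  }
  invisible(x)
}
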