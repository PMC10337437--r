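#' Pipeline configuration
#'
#' Exactly one data source must be given: a microdata CSV (`input`), a
#' fixture-spec YAML (`fixture`), or generator parameters (`generator`,
#' either a [generator_params()] object or a YAML path of its fields).
#'
#' @param input Path to a microdata CSV.
#' @param fixture Path to a fixture-spec YAML.
#' @param generator [generator_params()] object or YAML path.
#' @param cascade [cascade_config()].
#' @param covariates Covariate blocks for the bivariate tables and the model.
#' @param alpha Retention threshold for backward elimination.
#' @param out_dir Output directory (created if needed); `NULL` for no files.
#' @param seed Optional integer; overrides the generator seed.
#' @param fisher Use Fisher's exact test for the bivariate tables.
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, fixture = NULL, generator = NULL,
                            cascade = cascade_config(),
                            covariates = c("age_group", "sex", "marital",
                                           "education", "wealth_quintile",
                                           "setting"),
                            alpha = 0.05, out_dir = NULL, seed = NULL,
                            fisher = FALSE, quiet = TRUE) {
  sources <- !vapply(list(input, fixture, generator), is.null, logical(1L))
  if (sum(sources) != 1L) {
    stop("exactly one data source (input, fixture or generator) must be ",
         "specified", call. = FALSE)
  }
  structure(list(input = input, fixture = fixture, generator = generator,
                 cascade = cascade, covariates = covariates, alpha = alpha,
                 out_dir = out_dir, seed = seed, fisher = fisher,
                 quiet = quiet),
            class = "pipeline_config")
}

pipe_log <- function(config, fmt, ...) {
  if (!isTRUE(config$quiet)) message(sprintf(fmt, ...))
}

run_stage <- function(config, stage, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  pipe_log(config, "stage %s done (%.2fs)", stage,
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}

#' Run the full cascade-of-care analysis pipeline
#'
#' Loads or generates microdata, attaches wealth quintiles, builds the
#' overall and per-setting fixed-denominator cascades, computes bivariate
#' diagnosed/undiagnosed tables with independence tests, and fits the
#' undiagnosed-status logistic model with backward elimination. When
#' `out_dir` is set, writes `cascade.csv`, `cascade.json`,
#' `chart_data.csv`, `bivariate.csv`, `model.csv`, `elimination_trace.json`,
#' `wealth.csv` and `manifest.json`; on any stage error the partial outputs
#' are removed. Identical configuration and seed yield byte-identical
#' outputs (the manifest records file checksums, the seed and the input
#' checksum; no timestamps).
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `data`, `wealth`,
#'   `cascade` (a `cascade_set`), `bivariate`, `model` (or `NULL` with
#'   `model_skipped_reason`), `chart_data` and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("run_pipeline() needs a pipeline_config", call. = FALSE)
  }
  data <- run_stage(config, "load", {
    if (!is.null(config$input)) {
      read_microdata(config$input)
    } else if (!is.null(config$fixture)) {
      reconstruct_fixture(read_fixture_spec(config$fixture))
    } else {
      params <- config$generator
      if (is.character(params)) {
        params <- do.call(generator_params, yaml::read_yaml(params))
      }
      if (!is.null(config$seed)) params$seed <- as.integer(config$seed)
      generate_population(params)
    }
  })

  wealth <- run_stage(config, "wealth", {
    hh <- data[!duplicated(data$household_id),
               c("household_id", asset_columns())]
    compute_wealth_index(hh)
  })
  data$wealth_quintile <- factor(
    wealth$quintile[match(data$household_id, wealth$household_id)],
    levels = 1:5)

  cascades <- run_stage(config, "cascade", {
    build_cascade(data, config$cascade, stratify_by = "setting")
  })

  cases <- data[classify_case(data, config$cascade), , drop = FALSE]
  method <- if (isTRUE(config$fisher)) "fisher" else "chisq"
  bivariate <- run_stage(config, "bivariate", {
    if (nrow(cases) == 0L) NULL else {
      res <- lapply(config$covariates, function(cov) {
        tab <- case_crosstab(cases, cov)
        test <- tryCatch(suppressWarnings(crosstab_test(tab, method)),
                         error = function(e) NULL)
        tibble::tibble(
          covariate = cov, level = rownames(tab),
          diagnosed = tab[, "diagnosed"], undiagnosed = tab[, "undiagnosed"],
          diagnosed_pct = if (sum(tab[, 1L]) > 0)
            100 * tab[, 1L] / sum(tab[, 1L]) else 0,
          undiagnosed_pct = if (sum(tab[, 2L]) > 0)
            100 * tab[, 2L] / sum(tab[, 2L]) else 0,
          p_value = if (is.null(test)) NA_real_ else test$p_value)
      })
      do.call(rbind, res)
    }
  })

  model <- NULL
  model_skipped_reason <- NULL
  if (nrow(cases) == 0L) {
    model_skipped_reason <- "no prevalent cases; regression skipped"
  } else if (length(unique(cases$ever_told_t2d)) < 2L) {
    model_skipped_reason <-
      "undiagnosed status is constant among cases; regression skipped"
  } else {
    model <- run_stage(config, "model", {
      fit_undiagnosed_model(cases, covariates = config$covariates,
                            alpha = config$alpha)
    })
  }
  if (!is.null(model_skipped_reason)) {
    pipe_log(config, "stage model skipped: %s", model_skipped_reason)
  }

  chart <- cascade_chart_data(cascades)

  result <- list(data = data, wealth = wealth, cascade = cascades,
                 bivariate = bivariate, model = model,
                 model_skipped_reason = model_skipped_reason,
                 chart_data = chart, manifest = NULL)

  if (!is.null(config$out_dir)) {
    result$manifest <- write_pipeline_outputs(result, config)
  }
  structure(result, class = "pipeline_result")
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$out_dir,
                     c("cascade.csv", "cascade.json", "chart_data.csv",
                       "bivariate.csv", "model.csv",
                       "elimination_trace.json", "wealth.csv",
                       "manifest.json"))
  names(paths) <- basename(paths)
  on_error <- function(e) {
    unlink(paths[file.exists(paths)])
    stop(sprintf("pipeline stage 'write' failed: %s", conditionMessage(e)),
         call. = FALSE)
  }
  tryCatch({
    ct <- cascade_table(result$cascade)
    readr::write_csv(ct, paths[["cascade.csv"]])
    jsonlite::write_json(ct, paths[["cascade.json"]], digits = NA)
    readr::write_csv(result$chart_data, paths[["chart_data.csv"]])
    if (!is.null(result$bivariate)) {
      readr::write_csv(result$bivariate, paths[["bivariate.csv"]])
    } else {
      readr::write_csv(tibble::tibble(), paths[["bivariate.csv"]])
    }
    if (!is.null(result$model)) {
      readr::write_csv(result$model$table, paths[["model.csv"]])
      jsonlite::write_json(result$model$trace,
                           paths[["elimination_trace.json"]], digits = NA)
    } else {
      readr::write_csv(tibble::tibble(
        skipped = result$model_skipped_reason %||% "not run"),
        paths[["model.csv"]])
      jsonlite::write_json(list(), paths[["elimination_trace.json"]])
    }
    readr::write_csv(result$wealth, paths[["wealth.csv"]])
    overall <- result$cascade$overall
    manifest <- list(
      package = "carecascade",
      version = as.character(utils::packageVersion("carecascade")),
      seed = config$seed,
      input = config$input %||% config$fixture %||% "generator",
      input_checksum = if (!is.null(config$input)) {
        unname(tools::md5sum(config$input))
      } else if (!is.null(config$fixture)) {
        unname(tools::md5sum(config$fixture))
      } else {
        NULL
      },
      denominator = overall$denominator,
      total_n = overall$total_n,
      bars = stats::setNames(as.list(overall$bars$count),
                             overall$bars$stage),
      all_zero = overall$all_zero,
      model_skipped = result$model_skipped_reason,
      output_checksums = as.list(tools::md5sum(
        paths[setdiff(names(paths), "manifest.json")]))
    )
    names(manifest$output_checksums) <-
      basename(names(manifest$output_checksums))
    jsonlite::write_json(manifest, paths[["manifest.json"]],
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest
  }, error = on_error)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chart-ready long-format cascade table
#'
#' One row per stratum and bar, six bars per stratum in cascade order with
#' the overall stratum first — the layout used for grouped bar charts of
#' cascades by setting.
#'
#' @param results A `cascade_result` or `cascade_set`.
#' @return Tibble with columns `stratum`, `stage`, `percent`.
#' @export
cascade_chart_data <- function(results) {
  ct <- cascade_table(results)
  ct[, c("stratum", "stage", "percent")]
}
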