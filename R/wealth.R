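#' Asset-based household wealth index and quintiles
#'
#' Computes the standard DHS-style wealth index: the first principal component
#' of the standardized household asset-indicator matrix, oriented so that
#' households owning more assets score positive, with sample-relative
#' quintiles (1 = poorest, 5 = richest) assigned by score rank. Ties are
#' broken by the input (household) order. Constant indicator columns carry no
#' information and are dropped with a warning.
#'
#' @param data Either a microdata tibble (the `household_id` and `asset_*`
#'   columns are used, one row per household) or a data frame/matrix of asset
#'   indicators with a `household_id` column or row names.
#' @return A tibble with `household_id`, `score` (dimensionless, mean 0) and
#'   `quintile` (integer 1-5).
#' @export
compute_wealth_index <- function(data) {
  if (is.matrix(data)) data <- as.data.frame(data)
  asset_cols <- intersect(asset_columns(), names(data))
  if (length(asset_cols) == 0L) {
    asset_cols <- setdiff(names(data), "household_id")
  }
  household_id <- if ("household_id" %in% names(data)) {
    as.character(data$household_id)
  } else {
    sprintf("H%06d", seq_len(nrow(data)))
  }
  x <- as.matrix(data[asset_cols])
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 5L) {
    stop("wealth index needs at least 5 households (one per quintile)",
         call. = FALSE)
  }
  v <- apply(x, 2L, stats::var)
  if (all(v == 0)) {
    stop("all asset indicators are constant; wealth index is undefined",
         call. = FALSE)
  }
  if (any(v == 0)) {
    warning("dropping constant asset indicator(s): ",
            paste(colnames(x)[v == 0], collapse = ", "), call. = FALSE)
    x <- x[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1L]
  # orient: more assets => positive score
  own_total <- rowSums(scale(x))
  s <- sum(score * own_total)
  if (s < 0) score <- -score
  rk <- order(order(score, household_id))   # ties broken by household id
  quintile <- floor((rk - 1L) * 5L / n) + 1L
  tibble::tibble(household_id = household_id,
                 score = unname(score),
                 quintile = as.integer(quintile))
}

#' Attach household wealth quintiles to participant records
#'
#' Computes [compute_wealth_index()] over the households in `data` and joins
#' the quintile back to each participant as a `wealth_quintile` factor with
#' levels `"1"` (poorest) to `"5"` (richest).
#'
#' @param data Microdata tibble.
#' @return `data` with an added `wealth_quintile` column.
#' @export
add_wealth_quintile <- function(data) {
  hh <- data[!duplicated(data$household_id),
             c("household_id", asset_columns())]
  w <- compute_wealth_index(hh)
  idx <- match(as.character(data$household_id), w$household_id)
  data$wealth_quintile <- factor(w$quintile[idx], levels = 1:5)
  data
}
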