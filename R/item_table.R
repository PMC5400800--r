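#' Construct an item-response table
#'
#' The universal input of the package: `N` respondents scoring `K` ordinal
#' items (categories `0..m_k` per item), together with one external binary
#' criterion (1 = positive diagnosis, 0 = negative) against which scale
#' scores are judged.
#'
#' @param responses integer matrix or data frame, `N` rows (respondents) by
#'   `K` columns (items); every entry a non-negative integer.
#' @param criterion integer vector of length `N` containing only 0 and 1.
#' @param item_ids character vector of `K` unique item labels; defaults to
#'   the column names of `responses`, or `"V1".."VK"`.
#' @param n_categories optional integer vector giving the number of response
#'   categories per item (item `k` scored `0..n_categories[k]-1`). Inferred
#'   from the data (`max + 1`) when omitted, so the scale need not be 0-3.
#' @return An object of class `item_response_table` with components
#'   `responses` (integer matrix), `criterion`, `item_ids`, `n_categories`.
#' @examples
#' tab <- item_response_table(cbind(a = c(0, 1, 2, 3), b = c(0, 0, 1, 1)),
#'                            criterion = c(0, 0, 1, 1))
#' tab
#' @export
item_response_table <- function(responses, criterion, item_ids = NULL,
                                n_categories = NULL) {
  responses <- as.matrix(responses)
  if (is.null(item_ids)) {
    item_ids <- colnames(responses)
    if (is.null(item_ids)) item_ids <- paste0("V", seq_len(ncol(responses)))
  }
  item_ids <- as.character(item_ids)
  if (length(item_ids) != ncol(responses))
    stop("item_ids must have one label per item column")
  if (anyDuplicated(item_ids))
    stop("item_ids must be unique")
  storage <- suppressWarnings(as.numeric(responses))
  if (anyNA(storage))
    stop("responses must not contain missing values (apply listwise deletion first)")
  if (any(storage != round(storage)))
    stop("responses must be integers (ordinal category codes)")
  if (any(storage < 0))
    stop("responses must be non-negative category codes starting at 0")
  responses <- matrix(as.integer(storage), nrow = nrow(responses),
                      dimnames = list(NULL, item_ids))
  criterion <- as.vector(criterion)
  if (length(criterion) != nrow(responses))
    stop("criterion must have one value per respondent row")
  if (anyNA(criterion) || !all(criterion %in% c(0, 1)))
    stop("criterion must contain only 0 and 1")
  criterion <- as.integer(criterion)
  observed_max <- if (nrow(responses)) apply(responses, 2, max) else
    integer(ncol(responses))
  if (is.null(n_categories)) {
    n_categories <- observed_max + 1L
  } else {
    n_categories <- as.integer(n_categories)
    if (length(n_categories) == 1L)
      n_categories <- rep(n_categories, ncol(responses))
    if (length(n_categories) != ncol(responses))
      stop("n_categories must be a single count or one per item")
    if (any(observed_max > n_categories - 1L))
      stop("responses exceed the declared number of categories")
  }
  structure(list(responses = responses, criterion = criterion,
                 item_ids = item_ids,
                 n_categories = as.integer(n_categories)),
            class = "item_response_table")
}

#' @export
print.item_response_table <- function(x, ...) {
  cat(sprintf("item_response_table: %d respondents x %d items\n",
              nrow(x$responses), length(x$item_ids)))
  cat(sprintf("  categories per item: %s\n",
              paste(unique(x$n_categories), collapse = "/")))
  cat(sprintf("  criterion prevalence: %d/%d positive (%.1f%%)\n",
              sum(x$criterion), length(x$criterion),
              100 * mean(x$criterion)))
  invisible(x)
}

#' @export
dim.item_response_table <- function(x) dim(x$responses)

#' Read an item-response table from CSV
#'
#' Expects one row per respondent, one integer column per item, and one
#' binary criterion column. Rows containing any missing cell are removed
#' (listwise deletion) with a warning reporting the count; surviving rows
#' are never altered.
#'
#' @param path path to a CSV file with a header row.
#' @param criterion_column name of the binary criterion column
#'   (default `"criterion"`).
#' @param n_categories optional declared category count, see
#'   [item_response_table()].
#' @return An [item_response_table()].
#' @export
read_item_table <- function(path, criterion_column = "criterion",
                            n_categories = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!criterion_column %in% names(df))
    stop(sprintf("criterion column '%s' not found in %s",
                 criterion_column, path))
  for (nm in names(df)) {
    v <- df[[nm]]
    if (!is.numeric(v) && !is.logical(v)) {
      conv <- suppressWarnings(as.numeric(as.character(v)))
      if (any(!is.na(as.character(v)) & as.character(v) != "" & is.na(conv)))
        stop(sprintf("column '%s' contains a non-numeric cell", nm))
      conv[as.character(v) == ""] <- NA_real_
      df[[nm]] <- conv
    }
  }
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    warning(sprintf("listwise deletion: dropped %d of %d rows with missing cells",
                    n_dropped, nrow(df)))
    df <- df[complete, , drop = FALSE]
  }
  if (nrow(df) < 2)
    stop("fewer than 2 complete rows after listwise deletion")
  crit <- df[[criterion_column]]
  if (!all(crit %in% c(0, 1)))
    stop(sprintf("criterion column '%s' must contain only 0 and 1",
                 criterion_column))
  items <- df[setdiff(names(df), criterion_column)]
  item_response_table(as.matrix(items), crit,
                      item_ids = names(items), n_categories = n_categories)
}

#' Write an item-response table to CSV
#'
#' Inverse of [read_item_table()]: `read_item_table(write_item_table(x, p))`
#' reproduces `x` exactly.
#'
#' @param x an [item_response_table()].
#' @param path output CSV path.
#' @param criterion_column column name used for the criterion.
#' @return `path`, invisibly.
#' @export
write_item_table <- function(x, path, criterion_column = "criterion") {
  stopifnot(inherits(x, "item_response_table"))
  if (criterion_column %in% x$item_ids)
    stop("criterion column name collides with an item id")
  df <- as.data.frame(x$responses)
  df[[criterion_column]] <- x$criterion
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a set of standardized factor loadings
#'
#' Holds standardized loadings `lambda` and error variances `delta` for a
#' fitted one-factor measurement model, the inputs to composite reliability
#' ([construct_reliability()]) and variance extracted
#' ([variance_extracted()]). Loadings come from any CFA tool; this package
#' never fits a factor model.
#'
#' @param item_ids item labels.
#' @param lambda standardized loadings, each in `[-1, 1]`.
#' @param delta error variances in `[0, 1]`; when omitted the standardized
#'   convention `delta = 1 - lambda^2` (variance unexplained by the factor)
#'   is applied.
#' @return An object of class `factor_loading_set`.
#' @examples
#' factor_loading_set(paste0("V", 1:3), c(0.7, 0.6, 0.8))
#' @export
factor_loading_set <- function(item_ids, lambda, delta = NULL) {
  item_ids <- as.character(item_ids)
  lambda <- as.numeric(lambda)
  if (length(item_ids) != length(lambda))
    stop("item_ids and lambda must have equal length")
  if (anyDuplicated(item_ids)) stop("item_ids must be unique")
  if (anyNA(lambda) || any(abs(lambda) > 1))
    stop("lambda must lie in [-1, 1]")
  if (is.null(delta)) {
    delta <- 1 - lambda^2
  } else {
    delta <- as.numeric(delta)
    if (length(delta) != length(lambda))
      stop("delta must have one value per loading")
    if (anyNA(delta) || any(delta < 0))
      stop("delta must be non-negative error variances")
  }
  structure(list(item_ids = item_ids, lambda = lambda, delta = delta),
            class = "factor_loading_set")
}

#' Read factor loadings from CSV
#'
#' Columns: `item_id`, `lambda`, optional `delta`.
#'
#' @param path CSV path.
#' @return A [factor_loading_set()].
#' @export
read_loadings <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("item_id", "lambda") %in% names(df)))
    stop("loadings CSV needs columns item_id and lambda")
  factor_loading_set(df$item_id, df$lambda,
                     delta = if ("delta" %in% names(df)) df$delta)
}

#' @export
print.factor_loading_set <- function(x, ...) {
  cat(sprintf("factor_loading_set: %d items, lambda in [%.3f, %.3f]\n",
              length(x$lambda), min(x$lambda), max(x$lambda)))
  invisible(x)
}
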