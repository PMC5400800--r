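#' Rank items by their individual AUC against the criterion
#'
#' Computes, for every item, the AUC of the raw item score against the
#' binary criterion, and sorts items in descending AUC order. Ties are
#' broken by input column order. A constant item is chance level (AUC 0.5
#' under the tie rule) and triggers a warning, not an error.
#'
#' @param table an [item_response_table()].
#' @param flip_negative_items if `TRUE`, items with AUC below 0.5 are
#'   reverse-scored (category `m - x`) before ranking, so negatively keyed
#'   items contribute positively to the total. Off by default: the method
#'   assumes higher item scores are more disease-like.
#' @return An object of class `item_auc_ranking`: data frame with columns
#'   `item` and `auc`, ordered by descending `auc`, plus attribute
#'   `flipped` naming any reverse-scored items.
#' @examples
#' tab <- item_response_table(cbind(a = c(0, 0, 0, 0), b = c(0, 0, 1, 1)),
#'                            criterion = c(0, 0, 1, 1))
#' suppressWarnings(item_aucs(tab))
#' @export
item_aucs <- function(table, flip_negative_items = FALSE) {
  stopifnot(inherits(table, "item_response_table"))
  resp <- table$responses
  crit <- table$criterion
  aucs <- vapply(seq_len(ncol(resp)), function(j)
    auc_mann_whitney(resp[, j], crit), 0)
  flipped <- character(0)
  if (flip_negative_items && any(aucs < 0.5)) {
    flip <- which(aucs < 0.5)
    flipped <- table$item_ids[flip]
    aucs[flip] <- 1 - aucs[flip]
  }
  const <- apply(resp, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    warning(sprintf("constant item(s) at chance level: %s",
                    paste(table$item_ids[const], collapse = ", ")))
  ord <- order(-aucs, seq_along(aucs))   # stable: ties keep input order
  out <- data.frame(item = table$item_ids[ord], auc = aucs[ord],
                    stringsAsFactors = FALSE)
  attr(out, "flipped") <- flipped
  class(out) <- c("item_auc_ranking", "data.frame")
  out
}

#' AUC of running item totals along a given item order
#'
#' Entry `j` is the AUC of the unweighted sum of the first `j` items'
#' responses against the criterion, so the first entry equals the leading
#' item's individual AUC and the last equals the full-scale total-score
#' AUC.
#'
#' @param table an [item_response_table()].
#' @param order character vector: a permutation of the table's item ids,
#'   typically `item_aucs(table)$item`.
#' @return An object of class `running_auc_curve`: data frame with columns
#'   `position`, `item`, `cumulative_auc`.
#' @export
running_total_auc <- function(table, order) {
  stopifnot(inherits(table, "item_response_table"))
  order <- as.character(order)
  if (!setequal(order, table$item_ids) ||
      length(order) != length(table$item_ids))
    stop("order must be a permutation of the table's item ids")
  idx <- match(order, table$item_ids)
  total <- rep(0, nrow(table$responses))
  cum_auc <- numeric(length(idx))
  for (j in seq_along(idx)) {
    total <- total + table$responses[, idx[j]]
    cum_auc[j] <- auc_mann_whitney(total, table$criterion)
  }
  out <- data.frame(position = seq_along(order), item = order,
                    cumulative_auc = cum_auc, stringsAsFactors = FALSE)
  class(out) <- c("running_auc_curve", "data.frame")
  out
}

#' Select the item subset at the running-AUC peak
#'
#' Returns the prefix of the item order ending at the global maximum of the
#' running-total AUC. Ties at the maximum resolve toward the shortest
#' prefix: among equally predictive subsets the smaller scale wins.
#'
#' @param curve a [running_total_auc()] result.
#' @return Character vector of selected item ids (a prefix of the order).
#' @export
select_peak <- function(curve) {
  stopifnot(inherits(curve, "running_auc_curve"), nrow(curve) > 0)
  peak <- which.max(curve$cumulative_auc)   # first index at ties
  curve$item[seq_len(peak)]
}

#' Reduce a rating scale by the running-AUC peak rule
#'
#' The full pipeline: rank items by individual AUC ([item_aucs()]), trace
#' the AUC of the running total as items are added in rank order
#' ([running_total_auc()]), and keep the prefix at the curve's peak
#' ([select_peak()]). The peak subset's total score predicts the criterion
#' at least as well as the full scale's total score, with (often far)
#' fewer items.
#'
#' @inheritParams item_aucs
#' @return An object of class `reduction_result` with components:
#'   \describe{
#'     \item{ranking}{the [item_aucs()] table}
#'     \item{curve}{the [running_total_auc()] curve}
#'     \item{selected_items}{items retained at the peak}
#'     \item{peak_auc}{running-total AUC at the peak}
#'     \item{full_scale_auc}{AUC of the all-items total score}
#'     \item{retained_fraction}{`length(selected_items) / K`}
#'     \item{predictability_delta}{`peak_auc - full_scale_auc` (never
#'       negative)}
#'   }
#' @examples
#' tab <- simulate_study(study_scenario(n_respondents = 300, seed = 1))
#' reduce_scale(tab)
#' @export
reduce_scale <- function(table, flip_negative_items = FALSE) {
  ranking <- item_aucs(table, flip_negative_items = flip_negative_items)
  work <- table
  flipped <- attr(ranking, "flipped")
  if (length(flipped)) {
    j <- match(flipped, work$item_ids)
    work$responses[, j] <- rep(work$n_categories[j] - 1L,
                               each = nrow(work$responses)) -
      work$responses[, j]
  }
  curve <- running_total_auc(work, ranking$item)
  selected <- select_peak(curve)
  structure(list(ranking = ranking, curve = curve,
                 selected_items = selected,
                 peak_auc = max(curve$cumulative_auc),
                 full_scale_auc = curve$cumulative_auc[nrow(curve)],
                 retained_fraction = length(selected) / nrow(curve),
                 predictability_delta = max(curve$cumulative_auc) -
                   curve$cumulative_auc[nrow(curve)]),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  k <- nrow(x$curve)
  cat(sprintf("reduction_result: %d of %d items retained (%.2f%%)\n",
              length(x$selected_items), k, 100 * x$retained_fraction))
  cat(sprintf("  selected: %s\n", paste(x$selected_items, collapse = ", ")))
  cat(sprintf("  peak AUC %.6f vs full-scale AUC %.6f (delta %+.6f)\n",
              x$peak_auc, x$full_scale_auc, x$predictability_delta))
  invisible(x)
}

#' Write a reduction result as a JSON report
#'
#' Serializes the item ranking, running-AUC curve, selected subset and
#' summary statistics at full double precision; [read_report()] restores
#' an identical object.
#'
#' @param result a [reduce_scale()] result.
#' @param path output JSON path.
#' @param meta optional named list (e.g. seed, input path) embedded under
#'   `"meta"` for provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, meta = NULL) {
  stopifnot(inherits(result, "reduction_result"))
  doc <- list(
    item_order = result$ranking$item,
    item_aucs = result$ranking$auc,
    running_auc = result$curve$cumulative_auc,
    selected_items = result$selected_items,
    peak_auc = result$peak_auc,
    full_scale_auc = result$full_scale_auc,
    retained_fraction = result$retained_fraction,
    predictability_delta = result$predictability_delta
  )
  if (!is.null(meta)) doc$meta <- meta
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON reduction report back into a `reduction_result`
#'
#' @param path a report written by [write_report()].
#' @return A `reduction_result`; `read_report(write_report(x, p))` equals
#'   `x` (metadata aside).
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranking <- data.frame(item = as.character(doc$item_order),
                        auc = as.numeric(doc$item_aucs),
                        stringsAsFactors = FALSE)
  attr(ranking, "flipped") <- character(0)
  class(ranking) <- c("item_auc_ranking", "data.frame")
  curve <- data.frame(position = seq_along(doc$item_order),
                      item = as.character(doc$item_order),
                      cumulative_auc = as.numeric(doc$running_auc),
                      stringsAsFactors = FALSE)
  class(curve) <- c("running_auc_curve", "data.frame")
  structure(list(ranking = ranking, curve = curve,
                 selected_items = as.character(unlist(doc$selected_items)),
                 peak_auc = doc$peak_auc,
                 full_scale_auc = doc$full_scale_auc,
                 retained_fraction = doc$retained_fraction,
                 predictability_delta = doc$predictability_delta),
            class = "reduction_result")
}
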