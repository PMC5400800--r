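test_that("items are ranked by descending individual AUC with input-order tie-breaks", {
  tab <- item_response_table(
    cbind(flat = c(1L, 1L, 1L, 1L),          # constant: chance level
          sep = c(0L, 0L, 1L, 1L)),          # perfect separator
    criterion = c(0, 0, 1, 1))
  expect_warning(rk <- item_aucs(tab), "constant")
  expect_equal(rk$item, c("sep", "flat"))
  expect_equal(rk$auc, c(1.0, 0.5))

  # duplicated columns tie exactly and keep input order
  dup <- item_response_table(
    cbind(x1 = c(0L, 1L, 2L, 1L), x2 = c(0L, 1L, 2L, 1L),
          y = c(0L, 0L, 1L, 1L)),
    criterion = c(0, 0, 1, 1))
  rk2 <- item_aucs(dup)
  expect_equal(rk2$auc[rk2$item == "x1"], rk2$auc[rk2$item == "x2"])
  expect_lt(match("x1", rk2$item), match("x2", rk2$item))
})

test_that("running totals start at the leading item's AUC and end at the full-scale AUC", {
  tab <- tiny_table()
  rk <- item_aucs(tab)
  curve <- running_total_auc(tab, rk$item)
  expect_equal(curve$cumulative_auc[1], rk$auc[1])
  expect_equal(curve$cumulative_auc[nrow(curve)],
               auc_mann_whitney(rowSums(tab$responses), tab$criterion))
  expect_error(running_total_auc(tab, c("a", "a")), "permutation")
  expect_error(running_total_auc(tab, c("a", "zz")), "permutation")
})

test_that("peak selection takes the global argmax, shortest prefix on ties", {
  mk_curve <- function(v) {
    out <- data.frame(position = seq_along(v),
                      item = paste0("V", seq_along(v)),
                      cumulative_auc = v)
    class(out) <- c("running_auc_curve", "data.frame")
    out
  }
  expect_equal(select_peak(mk_curve(c(0.7, 0.8, 0.8))), c("V1", "V2"))
  expect_equal(select_peak(mk_curve(c(0.6, 0.7, 0.9))),
               c("V1", "V2", "V3"))   # strictly increasing: keep all
  expect_equal(select_peak(mk_curve(0.55)), "V1")
})

test_that("reduce_scale composes ranking, curve and peak with coherent summaries", {
  tab <- bdi_style_fixture(2)
  res <- reduce_scale(tab)
  expect_equal(res$peak_auc, max(res$curve$cumulative_auc))
  expect_equal(res$selected_items,
               res$curve$item[seq_along(res$selected_items)])
  expect_gte(res$peak_auc, res$full_scale_auc)
  expect_equal(res$retained_fraction, length(res$selected_items) / 21)
  expect_equal(res$predictability_delta, res$peak_auc - res$full_scale_auc)

  # single-item scale: trivially fully retained
  one <- item_response_table(cbind(only = c(0L, 1L, 0L, 2L)),
                             criterion = c(0, 0, 1, 1))
  res1 <- reduce_scale(one)
  expect_equal(res1$selected_items, "only")
  expect_equal(res1$retained_fraction, 1)
})

test_that("shuffling respondent rows changes no AUC", {
  tab <- simulate_study(study_scenario(n_respondents = 400, seed = 5))
  res <- reduce_scale(tab)
  perm <- sample(nrow(tab$responses))
  shuffled <- item_response_table(tab$responses[perm, ], tab$criterion[perm],
                                  item_ids = tab$item_ids,
                                  n_categories = tab$n_categories)
  res2 <- reduce_scale(shuffled)
  expect_equal(res2$ranking, res$ranking)
  expect_equal(res2$curve$cumulative_auc, res$curve$cumulative_auc)
})

test_that("opt-in flipping reverse-scores items with AUC below 0.5", {
  withr::local_seed(9)
  base <- simulate_study(study_scenario(n_respondents = 500, n_items = 4,
                                        informative_items = 1:2, seed = 9))
  resp <- base$responses
  resp[, 3] <- 3L - resp[, 3]   # reverse-key one background item
  flipped_tab <- item_response_table(resp, base$criterion,
                                     item_ids = base$item_ids,
                                     n_categories = base$n_categories)
  plain <- item_aucs(flipped_tab)
  expect_lt(plain$auc[plain$item == "V3"], 0.5)
  rk <- item_aucs(flipped_tab, flip_negative_items = TRUE)
  expect_gte(rk$auc[rk$item == "V3"], 0.5)
  expect_equal(attr(rk, "flipped"), "V3")
  # flipped reduction uses the reversed scores in the running totals
  res <- reduce_scale(flipped_tab, flip_negative_items = TRUE)
  expect_equal(res$curve$cumulative_auc[4],
               auc_mann_whitney(rowSums(base$responses), base$criterion))
})

test_that("a planted informative subset drives the running-AUC peak (single fixture)", {
  tab <- bdi_style_fixture(1)
  res <- reduce_scale(tab)
  planted <- paste0("V", c(1, 7, 9, 10, 14, 15))
  expect_gte(length(intersect(res$selected_items, planted)), 5)
  # curve rises over the informative prefix, then stops improving
  expect_lt(match(TRUE, cumsum(res$curve$cumulative_auc ==
                                 res$peak_auc) > 0), 10)
})
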