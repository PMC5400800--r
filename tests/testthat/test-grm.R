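test_that("graded-model category probabilities match logistic arithmetic and normalize", {
  p <- grm_probabilities(grm_params(1, c(-1, 0, 1)), theta = 0)[[1]]
  expect_equal(as.vector(p),
               c(1 - plogis(1), plogis(1) - 0.5, 0.5 - plogis(-1),
                 plogis(-1)))
  expect_equal(as.vector(p), c(0.2689, 0.2311, 0.2311, 0.2689),
               tolerance = 1e-3)

  # theta at a threshold puts the matching cumulative curve at one half
  p2 <- grm_probabilities(grm_params(1.7, c(-0.4, 0.9, 2.1)),
                          theta = 0.9)[[1]]
  expect_equal(sum(p2[3:4, 1]), 0.5)   # P(X >= 2 | theta = b_2)

  # slope zero: flat in theta, mass only at the extreme categories
  p0 <- grm_probabilities(grm_params(0, c(-1, 0, 1)), theta = c(-3, 0, 3))[[1]]
  expect_equal(p0[, 1], p0[, 3])
  expect_equal(p0[1, ], rep(0.5, 3))
  expect_equal(p0[4, ], rep(0.5, 3))

  withr::local_seed(23)
  for (rep in 1:50) {
    prm <- grm_params(runif(1, 0, 3), sort(rnorm(sample(1:5, 1), 0, 1.5)))
    th <- rnorm(7, 0, 2)
    probs <- grm_probabilities(prm, th)[[1]]
    expect_true(all(probs >= 0))
    expect_equal(colSums(probs), rep(1, 7))
  }
  expect_error(grm_params(1, c(0, 0, 1)), "strictly increasing")
})

test_that("simulation is reproducible under a seed and respects the model", {
  prm <- grm_params(c(1.8, 1.8, 0), c(-0.5, 1.0, 2.4))
  t1 <- grm_simulate(prm, 500, seed = 99)
  t2 <- grm_simulate(prm, 500, seed = 99)
  expect_equal(t1, t2)
  expect_equal(dim(t1), c(500L, 3L))
  expect_equal(t1$n_categories, rep(4L, 3))

  # zero-discrimination items carry no signal about the criterion
  flat <- grm_simulate(grm_params(rep(0, 3), c(-1, 0, 1)), 5000, seed = 4)
  aucs <- suppressWarnings(item_aucs(flat))$auc
  expect_true(all(abs(aucs - 0.5) < 0.03))

  # strongly discriminating items separate the classes well
  sharp <- grm_simulate(grm_params(3, list(c(-0.5, 1.0, 2.4))), 5000,
                        seed = 5)
  expect_gt(item_aucs(sharp)$auc[1], 0.8)
})

test_that("the fitter recovers spread discriminations and thresholds, with monotone likelihood", {
  prm <- grm_params(c(0.6, 1.4, 2.2, 1.0), c(-1, 0.3, 1.6))
  tab <- grm_simulate(prm, 1200, seed = 31)
  fit <- grm_fit(tab)
  expect_true(fit$converged)
  expect_lt(mean(abs(fit$params$a - prm$a)), 0.3)
  expect_lt(mean(abs(unlist(fit$params$b) - unlist(prm$b))), 0.3)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * fit$n_parameters)
  expect_equal(fit$bic,
               -2 * fit$log_likelihood + fit$n_parameters * log(fit$n))
  expect_equal(fit$n_parameters, 4 * 4)
  for (b in fit$params$b) expect_true(all(diff(b) > 0))
})

test_that("the constrained fit shares one discrimination and nests in the unconstrained", {
  prm <- grm_params(rep(1.3, 4), c(-0.8, 0.5, 1.7))
  tab <- grm_simulate(prm, 800, seed = 37)
  fc <- grm_fit(tab, constrained = TRUE)
  fu <- grm_fit(tab, constrained = FALSE)
  expect_equal(length(unique(fc$params$a)), 1L)
  expect_equal(fc$n_parameters, 4 * 3 + 1)
  expect_gte(fu$log_likelihood, fc$log_likelihood - 1e-6)

  lrt <- likelihood_ratio_test(fc, fu)
  expect_equal(lrt$df, 3L)
  expect_equal(lrt$statistic,
               2 * (fu$log_likelihood - fc$log_likelihood))
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, 3, lower.tail = FALSE))
  expect_error(likelihood_ratio_test(fu, fc), "constrained fit first")

  # equal log-likelihoods: statistic 0, p = 1
  null_twin <- structure(
    modifyList(unclass(fu), list(constrained = TRUE,
                                 n_parameters = fu$n_parameters - 3L)),
    class = "grm_fit_result")
  same <- likelihood_ratio_test(null_twin, fu)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("a large likelihood-ratio statistic at 20 df is overwhelming evidence", {
  p <- pchisq(166.49, 20, lower.tail = FALSE)
  expect_lt(p, 0.001)
})

test_that("unobserved categories are collapsed with a warning before fitting", {
  resp <- cbind(a = c(0L, 1L, 3L, 3L, 0L, 1L, 0L, 3L),   # category 2 unseen
                b = c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L))
  tab <- item_response_table(resp, c(0, 0, 1, 1, 0, 1, 0, 1))
  expect_warning(fit <- grm_fit(tab, constrained = TRUE), "collapsing")
  expect_length(fit$params$b[[1]], 2)   # 3 observed categories -> 2 cuts
})

test_that("item information follows the dichotomous closed form and is additive", {
  a <- 1.4
  b <- 0.3
  info_at_b <- unname(item_information(grm_params(a, list(b)),
                                       theta = b)[1, 1])
  expect_equal(info_at_b, a^2 / 4)
  # doubling the slope of a dichotomous item quadruples peak information
  expect_equal(unname(item_information(grm_params(2 * a, list(b)),
                                       theta = b)[1, 1]), 4 * info_at_b)

  prm <- grm_params(c(1.8, 0.9, 1.2), c(-0.5, 1.0, 2.4))
  th <- seq(-4, 4, length.out = 9)
  per_item <- item_information(prm, th)
  expect_true(all(per_item >= 0))
  expect_equal(colSums(per_item),
               colSums(item_information(prm, th, items = 1:2)) +
                 item_information(prm, th, items = 3)[1, ])
})

test_that("test information integrates the curve and reports the focal share", {
  prm <- grm_params(c(1.8, 1.8, 0.4), c(-0.5, 1.0, 2.4))
  all_items <- test_information(prm)
  subset <- test_information(prm, items = 1:2)
  expect_lt(subset$total, all_items$total)
  expect_true(subset$share_pct > 0 && subset$share_pct <= 100)
  expect_lt(subset$in_range, subset$total)
  # the whole-scale summary equals the subset-of-everything summary
  expect_equal(test_information(prm, items = 1:3)$total, all_items$total)
  expect_error(test_information(prm, items = integer(0)), "non-empty")
})
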