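#' Graded response model item parameters
#'
#' Per-item discrimination (logistic slope `a_i >= 0`) and strictly
#' increasing category thresholds `b_{i,1} < ... < b_{i,m_i}` on the
#' latent-trait scale; item `i` has `m_i + 1` response categories. The
#' model is the cumulative-logistic graded model:
#' `P(X_i >= k | theta) = plogis(a_i * (theta - b_ik))`.
#'
#' @param a numeric vector of discriminations, one per item.
#' @param b list of numeric threshold vectors, one per item, each strictly
#'   increasing (a single vector is recycled to all items).
#' @param item_ids optional labels, default `"V1".."VK"`.
#' @return An object of class `grm_params`.
#' @examples
#' grm_params(a = c(1.8, 0.4), b = c(-0.5, 1.0, 2.4))
#' @export
grm_params <- function(a, b, item_ids = NULL) {
  a <- as.numeric(a)
  if (anyNA(a) || any(a < 0)) stop("discriminations must be >= 0")
  if (!is.list(b)) b <- rep(list(as.numeric(b)), length(a))
  if (length(b) != length(a)) stop("need one threshold vector per item")
  b <- lapply(b, as.numeric)
  ok <- vapply(b, function(v) length(v) >= 1 && !anyNA(v) &&
                 all(diff(v) > 0), TRUE)
  if (!all(ok))
    stop("thresholds must be strictly increasing within each item")
  if (is.null(item_ids)) item_ids <- paste0("V", seq_along(a))
  item_ids <- as.character(item_ids)
  if (length(item_ids) != length(a) || anyDuplicated(item_ids))
    stop("item_ids must be unique, one per item")
  structure(list(a = a, b = b, item_ids = item_ids), class = "grm_params")
}

#' @export
print.grm_params <- function(x, ...) {
  cat(sprintf("grm_params: %d items\n", length(x$a)))
  for (i in seq_along(x$a))
    cat(sprintf("  %s: a = %.3f, b = (%s)\n", x$item_ids[i], x$a[i],
                paste(sprintf("%.3f", x$b[[i]]), collapse = ", ")))
  invisible(x)
}

# category probabilities for one item across a theta grid: (m+1) x Q
grm_item_probs <- function(a, b, theta) {
  m <- length(b)
  f <- matrix(stats::plogis(a * outer(b, theta, function(bb, tt) tt - bb)),
              m, length(theta))
  p <- rbind(1 - f[1, , drop = FALSE],
             if (m > 1) f[-m, , drop = FALSE] - f[-1, , drop = FALSE],
             f[m, , drop = FALSE])
  pmax(p, 0)
}

#' Category probabilities of the graded response model
#'
#' Cumulative-logistic graded model: `P(X_i >= k | theta) =
#' plogis(a_i (theta - b_ik))`; category probabilities are adjacent
#' differences of the cumulative curves and sum to 1 at every `theta`.
#'
#' @param params a [grm_params()] object.
#' @param theta latent-trait value(s).
#' @return A list, one element per item, each an `(m_i + 1) x
#'   length(theta)` matrix of category probabilities (rows are categories
#'   `0..m_i`).
#' @examples
#' p <- grm_probabilities(grm_params(1, c(-1, 0, 1)), theta = 0)
#' colSums(p[[1]])  # 1
#' @export
grm_probabilities <- function(params, theta) {
  stopifnot(inherits(params, "grm_params"))
  theta <- as.numeric(theta)
  out <- lapply(seq_along(params$a), function(i)
    grm_item_probs(params$a[i], params$b[[i]], theta))
  names(out) <- params$item_ids
  out
}

#' Simulate an item-response study from a graded response model
#'
#' Draws latent traits `theta ~ N(0, 1)`, samples ordinal responses from
#' [grm_probabilities()], and sets the external criterion to 1 for
#' respondents with `theta >= criterion_threshold` — the diagnosis and the
#' items reflect the same underlying construct, as in a clinical
#' validation study where an external assessment defines caseness.
#'
#' @param params a [grm_params()] object.
#' @param n number of respondents.
#' @param criterion_threshold latent cutoff defining a positive diagnosis;
#'   the default `qnorm(0.8)` gives 20 percent expected prevalence.
#' @param seed optional integer seed for reproducibility.
#' @return An [item_response_table()] with `n` rows.
#' @examples
#' tab <- grm_simulate(grm_params(c(2, 2), c(-1, 0, 1)), n = 100, seed = 1)
#' @export
grm_simulate <- function(params, n, criterion_threshold = stats::qnorm(0.8),
                         seed = NULL) {
  stopifnot(inherits(params, "grm_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  theta <- stats::rnorm(n)
  K <- length(params$a)
  resp <- matrix(0L, n, K)
  for (i in seq_len(K)) {
    # X >= k iff u < P(X >= k) = plogis(a (theta - b_k)); nested in k
    f <- stats::plogis(params$a[i] *
                         outer(theta, params$b[[i]], `-`))  # n x m
    u <- stats::runif(n)
    resp[, i] <- as.integer(rowSums(u < f))
  }
  item_response_table(resp, as.integer(theta >= criterion_threshold),
                      item_ids = params$item_ids,
                      n_categories = vapply(params$b, length, 0L) + 1L)
}

# Gauss-Hermite nodes/weights rescaled to a standard-normal prior
gh_standard_normal <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(theta = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# pack/unpack: per item psi = (log a, b1, log diff(b)); constrained shares
# one leading log a across items
grm_pack <- function(a, b, constrained) {
  per_item <- lapply(seq_along(a), function(i) {
    v <- b[[i]]
    c(v[1], if (length(v) > 1) log(diff(v)))
  })
  if (constrained) c(log(a[1]), unlist(per_item))
  else unlist(lapply(seq_along(a), function(i) c(log(a[i]), per_item[[i]])))
}

grm_unpack <- function(par, mvec, constrained) {
  K <- length(mvec)
  a <- numeric(K)
  b <- vector("list", K)
  pos <- 1L
  if (constrained) {
    a[] <- exp(par[1])
    pos <- 2L
  }
  for (i in seq_len(K)) {
    if (!constrained) {
      a[i] <- exp(par[pos])
      pos <- pos + 1L
    }
    m <- mvec[i]
    b1 <- par[pos]
    d <- if (m > 1) exp(par[pos + seq_len(m - 1)]) else numeric(0)
    b[[i]] <- b1 + c(0, cumsum(d))
    pos <- pos + m
  }
  list(a = a, b = b)
}

#' Fit a graded response model by marginal maximum likelihood
#'
#' Integrates the latent trait out against a standard-normal prior with
#' fixed-node Gauss-Hermite quadrature and maximizes the marginal
#' likelihood by quasi-Newton (BFGS) updates with analytic gradients, run
#' in restarts whose log-likelihood sequence is monotone non-decreasing
#' until the improvement falls below `tol`. The `constrained` variant
#' shares a single discrimination across items (`K*m + 1` parameters for
#' equal category counts); the unconstrained variant frees them
#' (`K*(m+1)`). Response categories never observed in the data are
#' collapsed out with a warning, since their probabilities are not
#' estimable.
#'
#' @param table an [item_response_table()] with at least 2 items.
#' @param constrained logical: equal discriminations across items?
#' @param n_quad number of Gauss-Hermite nodes (default 61).
#' @param tol absolute log-likelihood improvement below which the restart
#'   loop stops.
#' @param max_restarts cap on BFGS restarts (50 iterations each);
#'   exceeding it sets `converged = FALSE` with a warning.
#' @return An object of class `grm_fit_result`: `params` ([grm_params()]),
#'   `log_likelihood`, `aic` (`-2 logL + 2p`), `bic`
#'   (`-2 logL + p log N`), `n_parameters`, `converged`, `loglik_trace`,
#'   `constrained`, `n`.
#' @examples
#' tab <- grm_simulate(grm_params(c(1.5, 1.5, 1.5), c(-1, 1)), 200, seed = 1)
#' grm_fit(tab, constrained = TRUE)
#' @export
grm_fit <- function(table, constrained = FALSE, n_quad = 61, tol = 1e-5,
                    max_restarts = 40) {
  stopifnot(inherits(table, "item_response_table"))
  X <- table$responses
  K <- ncol(X)
  if (K < 2) stop("need at least 2 items to fit a graded response model")

  # collapse unobserved categories: estimation needs every category seen
  for (i in seq_len(K)) {
    obs <- sort(unique(X[, i]))
    if (length(obs) < 2)
      stop(sprintf("item %s is constant; no model can be fitted",
                   table$item_ids[i]))
    if (length(obs) != max(obs) + 1L || length(obs) != table$n_categories[i]) {
      warning(sprintf("item %s: collapsing to %d observed categories",
                      table$item_ids[i], length(obs)))
      X[, i] <- match(X[, i], obs) - 1L
    }
  }
  mvec <- apply(X, 2, max)  # thresholds per item

  # compress duplicate response patterns
  key <- apply(X, 1, paste, collapse = ",")
  first <- !duplicated(key)
  Xp <- X[first, , drop = FALSE]
  cnt <- as.vector(table(factor(key, levels = key[first])))
  npat <- nrow(Xp)

  gh <- gh_standard_normal(n_quad)
  th <- gh$theta
  lw <- log(gh$w)
  Q <- n_quad
  lw_mat <- matrix(lw, npat, Q, byrow = TRUE)
  tiny <- 1e-300

  marginal <- function(a, b) {
    A <- lw_mat
    for (i in seq_len(K)) {
      lp <- log(pmax(grm_item_probs(a[i], b[[i]], th), tiny))
      A <- A + lp[Xp[, i] + 1L, , drop = FALSE]
    }
    rmax <- apply(A, 1, max)
    logf <- rmax + log(rowSums(exp(A - rmax)))
    list(logf = logf, A = A)
  }

  nll <- function(par) {
    p <- grm_unpack(par, mvec, constrained)
    -sum(cnt * marginal(p$a, p$b)$logf)
  }

  ngr <- function(par) {
    p <- grm_unpack(par, mvec, constrained)
    marg <- marginal(p$a, p$b)
    post <- exp(marg$A - marg$logf) * cnt      # npat x Q, count-weighted
    g <- numeric(length(par))
    pos <- 1L
    if (constrained) pos <- 2L
    g_loga_shared <- 0
    for (i in seq_len(K)) {
      m <- mvec[i]
      a <- p$a[i]
      b <- p$b[[i]]
      f <- stats::plogis(a * outer(b, th, function(bb, tt) tt - bb)) # m x Q
      u <- f * (1 - f)
      P <- pmax(grm_item_probs(a, b, th), tiny)                  # (m+1) x Q
      N <- rowsum(post, group = factor(Xp[, i], levels = 0:m))   # (m+1) x Q
      R <- N / P
      g_a <- 0
      g_b <- numeric(m)
      for (k in seq_len(m)) {
        dR <- R[k + 1, ] - R[k, ]
        g_a <- g_a + sum((th - b[k]) * u[k, ] * dR)
        g_b[k] <- -a * sum(u[k, ] * dR)
      }
      if (constrained) {
        g_loga_shared <- g_loga_shared + a * g_a
      } else {
        g[pos] <- a * g_a
        pos <- pos + 1L
      }
      g[pos] <- sum(g_b)                       # d/d b1
      if (m > 1) {
        d <- diff(b)
        g[pos + seq_len(m - 1)] <- d * rev(cumsum(rev(g_b)))[-1]
      }
      pos <- pos + m
    }
    if (constrained) g[1] <- g_loga_shared
    -g
  }

  # start values: a = 1, thresholds from marginal category proportions
  b0 <- lapply(seq_len(K), function(i) {
    pge <- vapply(seq_len(mvec[i]), function(k) mean(X[, i] >= k), 0)
    pge <- pmin(pmax(pge, 1e-3), 1 - 1e-3)
    v <- stats::qlogis(1 - pge)
    v + cumsum(c(0, pmax(0, 1e-3 - diff(v))))  # enforce strict increase
  })
  par <- grm_pack(rep(1, K), b0, constrained)

  trace <- -nll(par)
  converged <- FALSE
  for (r in seq_len(max_restarts)) {
    res <- stats::optim(par, nll, ngr, method = "BFGS",
                        control = list(maxit = 50, reltol = 1e-12))
    par <- res$par
    trace <- c(trace, -res$value)
    improvement <- trace[length(trace)] - trace[length(trace) - 1]
    if (res$convergence == 0 || improvement < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("GRM fit did not converge within the restart cap")

  p <- grm_unpack(par, mvec, constrained)
  logL <- trace[length(trace)]
  n_par <- length(par)
  N <- nrow(X)
  structure(list(params = grm_params(p$a, p$b, table$item_ids),
                 log_likelihood = logL,
                 aic = -2 * logL + 2 * n_par,
                 bic = -2 * logL + n_par * log(N),
                 n_parameters = n_par, converged = converged,
                 loglik_trace = trace, constrained = constrained, n = N),
            class = "grm_fit_result")
}

#' @export
print.grm_fit_result <- function(x, ...) {
  cat(sprintf("grm_fit_result (%s): logLik = %.3f, AIC = %.2f, BIC = %.2f\n",
              if (x$constrained) "constrained" else "unconstrained",
              x$log_likelihood, x$aic, x$bic))
  cat(sprintf("  %d parameters, n = %d, converged: %s\n",
              x$n_parameters, x$n, x$converged))
  invisible(x)
}

#' Likelihood-ratio test of constrained vs unconstrained GRM
#'
#' Tests whether freeing the discriminations improves fit: statistic
#' `2 (logL_u - logL_c)` referred to a chi-square with `df` equal to the
#' difference in parameter counts (`K - 1` for a shared vs per-item
#' discrimination).
#'
#' @param constrained fit with equal discriminations (the null).
#' @param unconstrained fit with free discriminations.
#' @return An object of class `lrt_result`: `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(constrained, unconstrained) {
  stopifnot(inherits(constrained, "grm_fit_result"),
            inherits(unconstrained, "grm_fit_result"))
  if (!constrained$constrained || unconstrained$constrained)
    stop("pass the constrained fit first, the unconstrained second")
  if (constrained$n != unconstrained$n)
    stop("fits must come from the same data")
  stat <- 2 * (unconstrained$log_likelihood - constrained$log_likelihood)
  if (stat < -1e-6 * max(1, abs(constrained$log_likelihood)))
    stop("unconstrained log-likelihood below constrained: fitting failure")
  stat <- max(stat, 0)
  df <- unconstrained$n_parameters - constrained$n_parameters
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi-square = %.3f, df = %d, p %s\n", x$statistic, x$df,
              if (x$p_value < 0.001) "< 0.001" else
                sprintf("= %.4f", x$p_value)))
  invisible(x)
}

#' Item Fisher information of the graded response model
#'
#' `I_i(theta) = a_i^2 * sum_k (u_k - u_{k+1})^2 / P_k` with
#' `u_k = F_k (1 - F_k)` the derivative factor of the k-th cumulative
#' logistic curve (`u_0 = u_{m+1} = 0`). For a dichotomous item this
#' reduces to `a^2 F (1 - F)`, peaking at `a^2 / 4` when `theta = b`.
#'
#' @param params a [grm_params()] object.
#' @param theta latent-trait grid.
#' @param items indices or ids of the items to evaluate (default all).
#' @return Matrix, items x theta values.
#' @export
item_information <- function(params, theta, items = NULL) {
  stopifnot(inherits(params, "grm_params"))
  idx <- resolve_items(params, items)
  theta <- as.numeric(theta)
  out <- matrix(0, length(idx), length(theta),
                dimnames = list(params$item_ids[idx], NULL))
  for (r in seq_along(idx)) {
    i <- idx[r]
    a <- params$a[i]
    b <- params$b[[i]]
    m <- length(b)
    f <- stats::plogis(a * outer(b, theta, function(bb, tt) tt - bb))
    u <- rbind(0, f * (1 - f), 0)                       # (m+2) x Q
    P <- pmax(grm_item_probs(a, b, theta), 1e-300)      # (m+1) x Q
    num <- (u[seq_len(m + 1), , drop = FALSE] -
              u[1 + seq_len(m + 1), , drop = FALSE])^2
    out[r, ] <- a^2 * colSums(num / P)
  }
  out
}

resolve_items <- function(params, items) {
  if (is.null(items)) return(seq_along(params$a))
  if (is.character(items)) {
    idx <- match(items, params$item_ids)
    if (anyNA(idx)) stop("unknown item id(s)")
  } else {
    idx <- as.integer(items)
    if (any(idx < 1 | idx > length(params$a))) stop("item index out of range")
  }
  if (length(idx) == 0) stop("item subset must be non-empty")
  idx
}

#' Test information of an item subset
#'
#' Sums the per-item Fisher information over the chosen subset and
#' integrates it by the trapezoid rule over a wide latent-trait grid
#' (default 1000 points on (-10, 10)), reporting the grid total, the
#' information inside a focal range (default (-4, 4), where virtually all
#' respondents lie), and the focal share as a percent.
#'
#' @param params a [grm_params()] object.
#' @param items item indices or ids (default all items).
#' @param grid_range integration limits, default `c(-10, 10)`.
#' @param n_grid number of trapezoid points, default 1000.
#' @param focus focal range, default `c(-4, 4)`.
#' @return An object of class `information_summary`: `total`, `in_range`,
#'   `share_pct`, `focus`, `items`.
#' @examples
#' p <- grm_params(c(1.8, 0.4), c(-0.5, 1.0, 2.4))
#' test_information(p)
#' @export
test_information <- function(params, items = NULL,
                             grid_range = c(-10, 10), n_grid = 1000,
                             focus = c(-4, 4)) {
  idx <- resolve_items(params, items)
  grid <- seq(grid_range[1], grid_range[2], length.out = n_grid)
  info <- colSums(item_information(params, grid, items = idx))
  total <- pracma::trapz(grid, info)
  inside <- grid > focus[1] & grid < focus[2]
  fg <- c(focus[1], grid[inside], focus[2])
  fi <- colSums(item_information(params, fg, items = idx))
  in_range <- pracma::trapz(fg, fi)
  structure(list(total = total, in_range = in_range,
                 share_pct = 100 * in_range / total, focus = focus,
                 items = params$item_ids[idx]),
            class = "information_summary")
}

#' @export
print.information_summary <- function(x, ...) {
  cat(sprintf("Total information = %.2f\n", x$total))
  cat(sprintf("Information in (%g, %g) = %.2f (%.2f%%)\n",
              x$focus[1], x$focus[2], x$in_range, x$share_pct))
  cat(sprintf("Based on items %s\n", paste(x$items, collapse = ", ")))
  invisible(x)
}
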