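# Independent AUC oracle: explicit enumeration of positive-negative pairs,
# ties credited one half. Deliberately O(P*N) and rank-free so it shares no
# code path with auc_mann_whitney() or the ROC staircase.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# random small scored instance with heavy ties (integer scores)
random_tied_instance <- function(n_max = 30, score_levels = 6) {
  repeat {
    n <- sample(4:n_max, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) == 2) break
  }
  list(scores = sample(0:(score_levels - 1), n, replace = TRUE),
       labels = labels)
}

# small deterministic item table: item b separates classes, a is noisy
tiny_table <- function() {
  item_response_table(
    cbind(a = c(1L, 0L, 1L, 0L, 2L, 1L),
          b = c(0L, 0L, 0L, 1L, 1L, 1L)),
    criterion = c(0, 0, 0, 1, 1, 1))
}

extdata <- function(name) system.file("extdata", name, package = "rocreduce")
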