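# Shared fixtures: everything is generated in code at test time.

tiny_corpus <- function(n = 60, seed = 7, ...) {
  generate_corpus(generator_config(n_reports = n, seed = seed, ...))
}

tiny_vocab <- function(corpus = tiny_corpus()) {
  build_vocabulary(corpus$reports$text)
}

# A small classifier configuration that trains in seconds.
tiny_model <- function(vocab, seed = 1, ...) {
  report_classifier(vocab, d = 16, n_layers = 1, n_heads = 2, d_ff = 32,
                    max_len = 48, attn_dim = 16, head_hidden = 16,
                    seed = seed, ...)
}

# Exhaustive pairwise AUC oracle: P(s+ > s-) + 0.5 P(tie) by enumeration.
auc_by_enumeration <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Direct-formula Fleiss kappa, written independently of the package version.
fleiss_by_formula <- function(counts, r) {
  N <- nrow(counts)
  pj <- colSums(counts) / (N * r)
  pe <- sum(pj^2)
  pbar <- mean((rowSums(counts^2) - r) / (r * (r - 1)))
  (pbar - pe) / (1 - pe)
}

# Confusion-matrix metrics oracle.
metrics_by_confusion <- function(scores, labels, th = 0.5) {
  pred <- as.integer(scores >= th)
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  list(sens = tp / (tp + fn), spec = tn / (tn + fp),
       bal = (tp / (tp + fn) + tn / (tn + fp)) / 2,
       f1 = 2 * tp / (2 * tp + fp + fn))
}

# Paired permutation test for delta AUC: rank-standardise each score vector
# (AUC-invariant; makes the two marginals identical so within-case swaps are
# exchangeable under the null), then swap the two scores of random case
# subsets to build the null distribution of |AUC_A - AUC_B|.
delong_permutation_p <- function(sa, sb, y, n_perm = 2000, seed = 1) {
  n <- length(y)
  sa <- rank(sa) / n
  sb <- rank(sb) / n
  obs <- abs(roc_auc(sa, y) - roc_auc(sb, y))
  hits <- 0
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      swap <- runif(n) < 0.5
      a2 <- ifelse(swap, sb, sa)
      b2 <- ifelse(swap, sa, sb)
      if (abs(roc_auc(a2, y) - roc_auc(b2, y)) >= obs - 1e-12) hits <- hits + 1
    }
  })
  hits / n_perm
}
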