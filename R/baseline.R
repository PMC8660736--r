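# The comparator pipeline: context-independent static word embeddings
# (mean-pooled) plus N-gram counts (N = 1, 2, 3) feeding a logistic
# regression. Its defining weakness — the reason the contextual classifier
# beats it on corpora rich in distant negation — is that the mean-embedding
# block of a report depends only on its bag of words.

#' Train static (context-independent) word embeddings
#'
#' Skip-gram with negative sampling over the corpus, minibatched so the
#' inner loop is vectorised matrix arithmetic. Alternatively
#' (`method = "random"`) returns fixed random vectors per type — both modes
#' are context-independent, which is the property the comparison exercises.
#'
#' @param corpus Texts (`report_corpus`, data frame with `text`, or
#'   character vector).
#' @param d Embedding dimension (default 100).
#' @param method `"sgns"` (skip-gram negative sampling) or `"random"`.
#' @param window Context window half-width.
#' @param epochs Skip-gram passes over the pair list.
#' @param negative Negative samples per positive pair.
#' @param min_count Minimum word frequency.
#' @param learning_rate SGD rate.
#' @param seed Seed (initialisation, pair shuffling, negative draws).
#' @return An `embedding_table`: numeric matrix, one row per word type,
#'   rownames = words.
#' @export
train_embeddings <- function(corpus, d = 100L, method = c("sgns", "random"),
                             window = 2L, epochs = 3L, negative = 5L,
                             min_count = 2L, learning_rate = 0.05, seed = 1L) {
  method <- match.arg(method)
  texts <- corpus_texts(corpus)
  words_per_doc <- lapply(texts, normalise_words)
  freq <- table(unlist(words_per_doc, use.names = FALSE))
  vocab <- names(freq)[freq >= min_count]
  if (length(vocab) == 0L) stop("no words pass `min_count`", call. = FALSE)

  if (method == "random") {
    E <- with_seed(seed, matrix(stats::rnorm(length(vocab) * d, sd = 0.3),
                                length(vocab), d))
    rownames(E) <- vocab
    class(E) <- c("embedding_table", class(E))
    return(E)
  }

  with_seed(seed, {
    V <- length(vocab)
    idx_docs <- lapply(words_per_doc, function(w) {
      i <- match(w, vocab)
      i[!is.na(i)]
    })
    centers <- integer(0); contexts <- integer(0)
    for (ids in idx_docs) {
      n <- length(ids)
      if (n < 2L) next
      for (off in seq_len(window)) {
        if (n <= off) break
        a <- ids[seq_len(n - off)]
        b <- ids[seq(off + 1L, n)]
        centers <- c(centers, a, b)
        contexts <- c(contexts, b, a)
      }
    }
    if (length(centers) == 0L) stop("corpus too small for skip-gram", call. = FALSE)
    uni <- as.numeric(freq[vocab])^0.75
    uni <- uni / sum(uni)
    Ein <- matrix(stats::rnorm(V * d, sd = 0.1), V, d)
    Eout <- matrix(0, V, d)
    n_pairs <- length(centers)
    batch <- 512L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_pairs)
      b0 <- 1L
      while (b0 <= n_pairs) {
        sel <- ord[b0:min(b0 + batch - 1L, n_pairs)]
        ci <- centers[sel]; oi <- contexts[sel]
        nb <- length(sel)
        # positive pairs
        u <- Ein[ci, , drop = FALSE]
        w <- Eout[oi, , drop = FALSE]
        g_pos <- sigmoid(rowSums(u * w)) - 1      # d/ds of -log sigmoid(s)
        du <- g_pos * w
        dw <- g_pos * u
        # negative pairs (resampled per batch from the 3/4-power unigram)
        for (k in seq_len(negative)) {
          ni <- sample.int(V, nb, replace = TRUE, prob = uni)
          wn <- Eout[ni, , drop = FALSE]
          g_neg <- sigmoid(rowSums(u * wn))
          du <- du + g_neg * wn
          dwn <- g_neg * u
          acc_n <- rowsum(dwn, group = ni)
          rid <- as.integer(rownames(acc_n))
          Eout[rid, ] <- Eout[rid, ] - learning_rate * acc_n
        }
        acc_u <- rowsum(du, group = ci)
        rid <- as.integer(rownames(acc_u))
        Ein[rid, ] <- Ein[rid, ] - learning_rate * acc_u
        acc_w <- rowsum(dw, group = oi)
        rid <- as.integer(rownames(acc_w))
        Eout[rid, ] <- Eout[rid, ] - learning_rate * acc_w
        b0 <- b0 + batch
      }
    }
    rownames(Ein) <- vocab
    class(Ein) <- c("embedding_table", class(Ein))
    Ein
  })
}

#' Read / write an embedding table in word2vec text format
#'
#' One line per word: the token followed by its `d` floats, space-separated.
#'
#' @param E An `embedding_table`.
#' @param path File path.
#' @return `write_embeddings` returns `path` invisibly; `read_embeddings`
#'   the table.
#' @export
write_embeddings <- function(E, path) {
  lines <- vapply(seq_len(nrow(E)), function(i) {
    paste(rownames(E)[i], paste(format(E[i, ], digits = 17, trim = TRUE,
                                       scientific = TRUE), collapse = " "))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  rows <- strsplit(readLines(path, encoding = "UTF-8"), " ", fixed = TRUE)
  words <- vapply(rows, `[[`, "", 1L)
  E <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(E) <- words
  class(E) <- c("embedding_table", class(E))
  E
}

#' Build an N-gram vocabulary (N = 1, 2, 3)
#'
#' @param corpus Texts.
#' @param n_max Largest N.
#' @param min_count Minimum corpus frequency for an N-gram to be a feature.
#' @param max_features Keep at most this many N-grams (most frequent first).
#' @return Character vector of N-grams (tokens joined by spaces).
#' @export
build_ngram_vocabulary <- function(corpus, n_max = 3L, min_count = 2L,
                                   max_features = 2000L) {
  texts <- corpus_texts(corpus)
  grams <- unlist(lapply(texts, function(tx) {
    text_ngrams(normalise_words(tx), n_max)
  }), use.names = FALSE)
  freq <- sort(table(grams), decreasing = TRUE)
  keep <- names(freq)[freq >= min_count]
  utils::head(keep, max_features)
}

text_ngrams <- function(words, n_max = 3L) {
  n <- length(words)
  out <- words
  if (n >= 2L && n_max >= 2L) {
    for (k in 2:min(n_max, n)) {
      m <- n - k + 1L
      g <- words[seq_len(m)]
      for (j in 2:k) g <- paste(g, words[seq(j, m + j - 1L)])
      out <- c(out, g)
    }
  }
  out
}

#' Baseline features: mean static embedding + N-gram counts
#'
#' The mean block is the arithmetic mean of the embeddings of in-vocabulary
#' tokens (zero vector when every token is out of vocabulary); the N-gram
#' block holds raw counts over the supplied N-gram vocabulary. The mean
#' block is bag-of-words invariant: any permutation of the same tokens
#' yields the identical vector, which is why distant negation defeats it.
#'
#' @param text One report text.
#' @param embeddings An `embedding_table`.
#' @param ngram_vocab From [build_ngram_vocabulary()]; `NULL` for
#'   embeddings only.
#' @return Named numeric vector: `emb_1..emb_d`, then `ng_1..ng_K`.
#' @export
featurize_baseline <- function(text, embeddings, ngram_vocab = NULL) {
  if (nrow(embeddings) == 0L) stop("empty embedding table", call. = FALSE)
  words <- normalise_words(text)
  hit <- words[words %in% rownames(embeddings)]
  d <- ncol(embeddings)
  mean_block <- if (length(hit) == 0L) rep(0, d) else
    colMeans(embeddings[hit, , drop = FALSE])
  names(mean_block) <- paste0("emb_", seq_len(d))
  if (is.null(ngram_vocab)) return(mean_block)
  counts <- table(factor(text_ngrams(words), levels = ngram_vocab))
  ng <- as.numeric(counts)
  names(ng) <- paste0("ng_", seq_along(ngram_vocab))
  c(mean_block, ng)
}

featurize_corpus <- function(texts, embeddings, ngram_vocab = NULL) {
  X <- t(vapply(texts, featurize_baseline, embeddings = embeddings,
                ngram_vocab = ngram_vocab,
                FUN.VALUE = numeric(ncol(embeddings) + length(ngram_vocab)),
                USE.NAMES = FALSE))
  colnames(X) <- c(paste0("emb_", seq_len(ncol(embeddings))),
                   if (length(ngram_vocab)) paste0("ng_", seq_along(ngram_vocab)))
  X
}

#' Fit the baseline logistic regression and predict test probabilities
#'
#' Unregularised maximum-likelihood logistic regression by default; `l2 > 0`
#' requests ridge-penalised estimation. Narrow designs are fitted exactly
#' with `stats::glm.fit`; wide N-gram designs (over 300 columns) go through
#' `glmnet`'s coordinate descent at the requested penalty (a vanishing
#' ridge, `1e-6`, when `l2 = 0`), whose cost scales to text-sized feature
#' spaces. Constant feature columns are dropped before fitting.
#'
#' @param train_x,train_y Training feature matrix and 0/1 labels.
#' @param test_x Test feature matrix (same columns).
#' @param l2 Ridge penalty (0 = unregularised).
#' @return Numeric vector of test probabilities in (0, 1).
#' @export
fit_predict_baseline <- function(train_x, train_y, test_x, l2 = 0) {
  train_y <- as.integer(train_y)
  if (length(unique(train_y)) < 2L) {
    stop("baseline undefined: training labels contain a single class",
         call. = FALSE)
  }
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  keep <- apply(train_x, 2L, function(col) stats::sd(col) > 0)
  if (!any(keep)) stop("no informative features", call. = FALSE)
  train_x <- train_x[, keep, drop = FALSE]
  test_x <- test_x[, keep, drop = FALSE]
  use_glmnet <- l2 > 0 || ncol(train_x) > 300L
  if (use_glmnet) {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      stop("wide or ridge fits require the glmnet package", call. = FALSE)
    }
    lam <- if (l2 > 0) l2 else 1e-6
    # a decreasing path down to the target penalty gives the coordinate
    # descent warm starts; a cold solve at a near-zero lambda on separable
    # text features can fail to converge
    path <- sort(unique(c(10^seq(0, log10(lam), length.out = 8), lam)),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(train_x, train_y, family = "binomial",
                          alpha = 0, lambda = path, standardize = FALSE,
                          maxit = 2e5)
    p <- as.numeric(stats::predict(fit, test_x, type = "response",
                                   s = lam, exact = FALSE))
  } else {
    # glm.fit avoids the formula machinery, which does not scale to
    # thousands of feature columns
    Xd <- cbind(`(Intercept)` = 1, train_x)
    fit <- suppressWarnings(
      stats::glm.fit(Xd, train_y, family = stats::binomial(),
                     control = stats::glm.control(maxit = 50))
    )
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    p <- sigmoid(drop(cbind(1, test_x) %*% beta))
  }
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' End-to-end baseline classifier on a split corpus
#'
#' Convenience wrapper: trains embeddings and the N-gram vocabulary on the
#' training texts, fits the logistic regression and scores the test texts.
#'
#' @param train,test Corpora (`report_corpus` or `list(reports, labels)`).
#' @param category Label column.
#' @param embeddings Optional pre-trained `embedding_table`.
#' @param embedding_method Passed to [train_embeddings()] when training here.
#' @param d Embedding dimension.
#' @param ngram_min_count,max_features N-gram vocabulary controls.
#' @param l2 Ridge penalty for the fit.
#' @param seed Seed for embedding training.
#' @return List: `scores` (test probabilities), `auc` (against the test
#'   labels), `ngram_vocab`, `embeddings`.
#' @export
baseline_classifier <- function(train, test, category = "abnormal",
                                embeddings = NULL,
                                embedding_method = "sgns", d = 100L,
                                ngram_min_count = 2L, max_features = 2000L,
                                l2 = 0, seed = 1L) {
  trn <- corpus_parts(train)
  tst <- corpus_parts(test)
  if (is.null(embeddings)) {
    embeddings <- train_embeddings(trn$reports$text, d = d,
                                   method = embedding_method, seed = seed)
  }
  ngv <- build_ngram_vocabulary(trn$reports$text, min_count = ngram_min_count,
                                max_features = max_features)
  tx <- featurize_corpus(trn$reports$text, embeddings, ngv)
  sx <- featurize_corpus(tst$reports$text, embeddings, ngv)
  y_tr <- trn$labels[[category]][match(trn$reports$report_id,
                                       trn$labels$report_id)]
  y_te <- tst$labels[[category]][match(tst$reports$report_id,
                                       tst$labels$report_id)]
  scores <- fit_predict_baseline(tx, y_tr, sx, l2 = l2)
  list(scores = scores, auc = roc_auc(scores, y_te),
       ngram_vocab = ngv, embeddings = embeddings)
}
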