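# Architecture contracts: encoder determinism and padding invariance,
# attention-pool normalization, head arithmetic, and gradient correctness of
# the end-to-end backward pass.

test_that("encoding is deterministic and rejects out-of-range ids", {
  v <- tiny_vocab(tiny_corpus(20))
  enc <- tiny_encoder(v, d = 16, n_layers = 2, n_heads = 2, d_ff = 24,
                      max_len = 32, seed = 5)
  tr <- normalise_and_tokenize("there is clear evidence of an extra axial mass",
                               v, max_len = 32)
  e1 <- encode(tr, enc)
  e2 <- encode(tr, enc)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(32, 16))
  expect_true(all(is.finite(e1)))
  expect_error(encode(c(1L, vocab_size(v) + 10L), enc), "vocabulary")
})

test_that("padding length never changes the embeddings of real positions", {
  v <- tiny_vocab(tiny_corpus(20))
  enc <- tiny_encoder(v, d = 16, n_layers = 2, n_heads = 2, d_ff = 24,
                      max_len = 40, seed = 5)
  txt <- "appearances are strongly suggestive of marked parenchymal atrophy"
  short <- normalise_and_tokenize(txt, v, max_len = 12)
  long <- normalise_and_tokenize(txt, v, max_len = 40)
  n <- short$length
  expect_equal(encode(short, enc)[1:n, ], encode(long, enc)[1:n, ],
               tolerance = 1e-12)
})

test_that("attention pooling: identity, symmetry and hand-computed softmax", {
  # single real token: weight 1, pooled = that vector
  emb <- matrix(rnorm(3 * 8), 3, 8)
  out <- attention_pool(emb[1, , drop = FALSE], mask = 1, seed = 2)
  expect_equal(out$weights, 1)
  expect_equal(out$pooled, emb[1, ])

  # equal pre-softmax scores: uniform weights, pooled = arithmetic mean.
  # Duplicate rows force equal scores whatever the parameters.
  same <- matrix(rep(rnorm(8), each = 4), 4, 8)
  out2 <- attention_pool(same, seed = 3)
  expect_equal(out2$weights, rep(0.25, 4))
  expect_equal(out2$pooled, colMeans(same))

  # pre-softmax scores (ln 3, 0) => weights (0.75, 0.25)
  params <- list(W = diag(2), b = c(0, 0), v = c(2, 0))
  x1 <- atanh(log(3) / 2); x2 <- 0  # score_1 = 2 tanh(x1) = ln 3, score_2 = 0
  emb3 <- rbind(c(x1, 0), c(x2, 0))
  out3 <- attention_pool(emb3, params = params)
  expect_equal(out3$weights, c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(out3$pooled, 0.75 * emb3[1, ] + 0.25 * emb3[2, ],
               tolerance = 1e-12)

  expect_error(attention_pool(emb, mask = c(0, 0, 0)), "all-padding")
})

test_that("attention weights are a distribution over non-padding positions (1,000 random shapes)", {
  withr::with_seed(95, {
    for (rep in 1:1000) {
      Tn <- sample(1:12, 1)
      d <- sample(c(2, 4, 8), 1)
      nreal <- sample(Tn, 1)
      emb <- matrix(rnorm(Tn * d, sd = 2), Tn, d)
      mask <- c(rep(1, nreal), rep(0, Tn - nreal))
      out <- attention_pool(emb, mask, seed = rep)
      a <- out$weights
      expect_true(all(a >= 0))
      expect_lt(abs(sum(a[mask == 1]) - 1), 1e-6)
      expect_true(all(a[mask == 0] == 0))
      expect_equal(out$pooled, drop(crossprod(emb, a)), tolerance = 1e-10)
    }
  })
})

test_that("permuting token embeddings permutes their attention weights", {
  withr::with_seed(97, {
    emb <- matrix(rnorm(6 * 8), 6, 8)
    out <- attention_pool(emb, seed = 4)
    perm <- c(3, 2, 1, 6, 5, 4)
    out_p <- attention_pool(emb[perm, ], seed = 4)
    expect_equal(out_p$weights, out$weights[perm], tolerance = 1e-12)
    expect_equal(out_p$pooled, out$pooled, tolerance = 1e-12)
  })
})

test_that("classification head matches direct matrix arithmetic", {
  zero_head <- list(W1 = matrix(0, 4, 3), b1 = rep(0, 3), w2 = rep(0, 3), b2 = 0)
  expect_equal(classify(c(1, 2, 3, 4), zero_head), 0.5)

  withr::with_seed(99, {
    for (rep in 1:20) {
      d <- 6; h <- 5
      head <- list(W1 = matrix(rnorm(d * h), d, h), b1 = rnorm(h),
                   w2 = rnorm(h), b2 = rnorm(1))
      x <- rnorm(d)
      p <- classify(x, head)
      expect_gt(p, 0); expect_lt(p, 1)
      manual <- 1 / (1 + exp(-(sum(pmax(drop(x %*% head$W1) + head$b1, 0) *
                                     head$w2) + head$b2)))
      expect_equal(p, manual, tolerance = 1e-12)
    }
  })
  expect_error(classify(c(1, 2), zero_head), "dimension")
  expect_error(classify(c(1, NA, 3, 4), zero_head), "finite")
})

test_that("analytic gradients match central differences end-to-end", {
  v <- build_vocabulary("a b c d e f g h i j")
  mod <- report_classifier(v, d = 8, n_layers = 2, n_heads = 2, d_ff = 12,
                           max_len = 12, attn_dim = 6, head_hidden = 5,
                           seed = 3)
  ids <- normalise_and_tokenize("a b c d e f", v, max_len = 12,
                                pad = FALSE)$token_ids
  y <- 1
  loss_fn <- function(params) {
    p <- radlabel:::model_forward(ids, params, mod$cfg)$prob
    -(y * log(p) + (1 - y) * log(1 - p))
  }
  fwd <- radlabel:::model_forward(ids, mod$params, mod$cfg, with_cache = TRUE)
  g <- radlabel:::model_backward(fwd$prob - y, fwd$cache, mod$params, mod$cfg)

  paths <- function(tree, prefix = character(0)) {
    if (is.list(tree)) {
      unlist(lapply(seq_along(tree), function(i) {
        nm <- if (is.null(names(tree))) as.character(i) else names(tree)[i]
        paths(tree[[i]], c(prefix, nm))
      }), recursive = FALSE)
    } else list(prefix)
  }
  get_leaf <- function(tr, p) { for (k in p) tr <- tr[[k]]; tr }
  set_leaf <- function(tr, p, val) {
    if (length(p) == 1) { tr[[p]] <- val; tr }
    else { tr[[p[1]]] <- set_leaf(tr[[p[1]]], p[-1], val); tr }
  }
  eps <- 1e-5
  withr::with_seed(101, {
    for (p in paths(mod$params)) {
      leaf <- get_leaf(mod$params, p)
      gleaf <- get_leaf(g, p)
      for (j in sample(length(leaf), min(2, length(leaf)))) {
        up <- leaf; up[j] <- up[j] + eps
        dn <- leaf; dn[j] <- dn[j] - eps
        num <- (loss_fn(set_leaf(mod$params, p, up)) -
                  loss_fn(set_leaf(mod$params, p, dn))) / (2 * eps)
        ana <- gleaf[j]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
      }
    }
  })
})

test_that("attention_report maps pooling weights to surface tokens", {
  corp <- tiny_corpus(30, seed = 103)
  v <- build_vocabulary(corp$reports$text)
  mod <- tiny_model(v, seed = 6)

  expect_error(attention_report("", mod), "empty")

  txt <- corp$reports$text[1]
  attn <- attention_report(txt, mod)
  expect_equal(sum(attn$weight), 1, tolerance = 1e-6)
  expect_true(all(attn$weight >= 0))

  # definitional consistency with encode + attention_pool on the same input
  tok <- normalise_and_tokenize(txt, v, max_len = mod$cfg$max_len, pad = FALSE)
  H <- encode(tok, model_encoder(mod))
  pool <- attention_pool(H, tok$mask, params = mod$params$pool)
  expect_equal(attn$weight, pool$weights, tolerance = 1e-12)
  expect_equal(attn$token, detokenize(tok$token_ids, v, drop_special = FALSE))

  # one-token report
  v1 <- build_vocabulary("lesion")
  m1 <- report_classifier(v1, d = 8, n_layers = 1, n_heads = 2, d_ff = 8,
                          max_len = 8, attn_dim = 8, head_hidden = 4)
  a1 <- attention_report("lesion", m1, drop_special = TRUE)
  expect_equal(nrow(a1), 1)
  expect_equal(a1$weight, 1)
})

test_that("a trained model attends to finding-lexicon tokens in positive reports", {
  # train a small model to convergence on separable synthetic reports, then
  # compare mean attention on finding tokens vs filler tokens
  corp <- generate_corpus(generator_config(n_reports = 160, seed = 105,
                                           distant_negation_rate = 0))
  v <- build_vocabulary(corp$reports$text)
  mod <- tiny_model(v, seed = 7)
  y <- corp$labels$abnormal[match(corp$reports$report_id,
                                  corp$labels$report_id)]
  fit <- fit_batch(mod, corp$reports$text, y, n_steps = 60,
                   learning_rate = 3e-3)
  mod <- fit$model

  tpl <- report_templates()
  finding_words <- unique(unlist(strsplit(
    unlist(tpl$categories, use.names = FALSE), " ")))
  filler_words <- unique(unlist(strsplit(tpl$normal_sentences, " ")))
  filler_words <- setdiff(filler_words, c(finding_words, "."))

  scores <- predict_proba(mod, corp$reports$text)
  tp <- which(y == 1 & scores >= 0.5)
  expect_gte(length(tp), 50)
  w_find <- c(); w_fill <- c()
  for (i in tp[seq_len(min(100, length(tp)))]) {
    attn <- attention_report(corp$reports$text[i], mod, drop_special = TRUE)
    w_find <- c(w_find, attn$weight[attn$token %in% finding_words])
    w_fill <- c(w_fill, attn$weight[attn$token %in% filler_words])
  }
  expect_gt(mean(w_find), mean(w_fill))
})

test_that("models persist through the self-describing archive", {
  corp <- tiny_corpus(20, seed = 107)
  v <- build_vocabulary(corp$reports$text)
  mod <- tiny_model(v, seed = 8)
  tmp <- tempfile(fileext = ".json")
  save_model(mod, tmp)
  back <- load_model(tmp)
  expect_equal(back$cfg, mod$cfg)
  txts <- corp$reports$text[1:5]
  expect_equal(predict_proba(back, txts), predict_proba(mod, txts),
               tolerance = 1e-12)
})

test_that("attention exports to CSV and HTML", {
  corp <- tiny_corpus(10, seed = 109)
  v <- build_vocabulary(corp$reports$text)
  mod <- tiny_model(v)
  attn <- attention_report(corp$reports$text[1], mod, drop_special = TRUE)
  csv <- tempfile(fileext = ".csv")
  write_attention(attn, csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(attn))
  html <- tempfile(fileext = ".html")
  write_attention(attn, html)
  expect_true(any(grepl("span", readLines(html))))
})
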