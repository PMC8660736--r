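#' Desk-scale transformer encoder
#'
#' A randomly initialised contextual encoder with the same architecture
#' contract as a large pretrained biomedical encoder — token + learned
#' positional embeddings followed by pre-LayerNorm multi-head self-attention
#' blocks — at a width where it can be trained from scratch on a synthetic
#' corpus. Attention over keys is restricted to non-padding positions, so a
#' token's embedding never depends on how much padding follows it.
#'
#' @param vocab A `report_vocabulary` (or an integer vocabulary size).
#' @param d Embedding width (default 64; 768 at full scale).
#' @param n_layers Number of transformer blocks.
#' @param n_heads Attention heads (`d` must be divisible by `n_heads`).
#' @param d_ff Feed-forward inner width.
#' @param max_len Maximum sequence length the positional table supports.
#' @param seed Seed for weight initialisation.
#' @return An object of class `report_encoder`.
#' @export
tiny_encoder <- function(vocab, d = 64L, n_layers = 2L, n_heads = 4L,
                         d_ff = 128L, max_len = 64L, seed = 1L) {
  vs <- if (inherits(vocab, "report_vocabulary")) vocab_size(vocab) else
    assert_count(vocab, "vocab", positive = TRUE)
  d <- assert_count(d, "d", positive = TRUE)
  n_layers <- assert_count(n_layers, "n_layers", positive = TRUE)
  n_heads <- assert_count(n_heads, "n_heads", positive = TRUE)
  if (d %% n_heads != 0L) stop("`d` must be divisible by `n_heads`", call. = FALSE)
  cfg <- list(vocab_size = vs, d = d, n_layers = n_layers, n_heads = n_heads,
              d_ff = assert_count(d_ff, "d_ff", positive = TRUE),
              max_len = assert_count(max_len, "max_len", positive = TRUE))
  params <- with_seed(seed, {
    list(tok_emb = init_matrix(vs, d),
         pos_emb = init_matrix(max_len, d),
         layers = lapply(seq_len(n_layers), function(i) block_params_init(d, cfg$d_ff)),
         lnf_g = rep(1, d), lnf_b = rep(0, d))
  })
  structure(list(cfg = cfg, params = params), class = "report_encoder")
}

#' @export
print.report_encoder <- function(x, ...) {
  cat(sprintf("<report_encoder> %d layers, d = %d, %d heads, vocab %d, max_len %d\n",
              x$cfg$n_layers, x$cfg$d, x$cfg$n_heads, x$cfg$vocab_size,
              x$cfg$max_len))
  invisible(x)
}

encoder_forward <- function(ids, nreal, params, cfg, with_cache = FALSE) {
  Tn <- length(ids)
  if (Tn > cfg$max_len) stop("sequence longer than encoder max_len", call. = FALSE)
  X <- params$tok_emb[ids, , drop = FALSE] + params$pos_emb[seq_len(Tn), , drop = FALSE]
  key_idx <- if (nreal < Tn) seq_len(nreal) else NULL
  caches <- if (with_cache) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    out <- block_forward(X, params$layers[[l]], cfg$n_heads, key_idx)
    X <- out$X2
    if (with_cache) caches[[l]] <- out$cache
  }
  lnf <- ln_forward(X, params$lnf_g, params$lnf_b)
  if (with_cache) list(H = lnf$Y, lnf = lnf, caches = caches, ids = ids, Tn = Tn)
  else lnf$Y
}

encoder_backward <- function(dH, fwd, params, cfg) {
  g <- list()
  bb <- ln_backward(dH, fwd$lnf, params$lnf_g)
  g$lnf_g <- bb$dg; g$lnf_b <- bb$db
  dX <- bb$dX
  g$layers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    out <- block_backward(dX, params$layers[[l]], fwd$caches[[l]], cfg$n_heads)
    g$layers[[l]] <- out$grads
    dX <- out$dX
  }
  g$tok_emb <- matrix(0, cfg$vocab_size, cfg$d)
  acc <- rowsum(dX, group = fwd$ids)
  g$tok_emb[as.integer(rownames(acc)), ] <- acc
  g$pos_emb <- matrix(0, cfg$max_len, cfg$d)
  g$pos_emb[seq_len(fwd$Tn), ] <- dX
  g
}

#' Encode a tokenized report into contextual token embeddings
#'
#' Returns one `d`-dimensional vector per token position, padding included.
#' Padding positions are excluded from every attention key set, so vectors
#' at real positions are identical whatever the padding length.
#'
#' @param tokens A [normalise_and_tokenize()] result, or an integer id
#'   vector (then all positions are treated as real).
#' @param encoder A [tiny_encoder()] (or the encoder inside a trained
#'   classifier).
#' @return Numeric matrix, `length(token_ids)` rows by `d` columns.
#' @export
encode <- function(tokens, encoder) {
  stopifnot(inherits(encoder, "report_encoder"))
  if (inherits(tokens, "tokenized_report")) {
    ids <- tokens$token_ids
    nreal <- tokens$length
  } else {
    ids <- as.integer(tokens)
    nreal <- length(ids)
  }
  if (length(ids) == 0L) stop("no tokens to encode", call. = FALSE)
  if (any(ids < 1L | ids > encoder$cfg$vocab_size)) {
    stop("token id outside the encoder vocabulary", call. = FALSE)
  }
  encoder_forward(ids, nreal, encoder$params, encoder$cfg)
}

pool_params_init <- function(d, attn_dim) {
  list(W = init_matrix(d, attn_dim), b = rep(0, attn_dim),
       v = stats::rnorm(attn_dim, sd = 0.02))
}

pool_forward <- function(H, nreal, p) {
  Hr <- H[seq_len(nreal), , drop = FALSE]
  U <- tanh(add_bias(Hr %*% p$W, p$b))
  s <- drop(U %*% p$v)
  e <- exp(s - max(s))
  alpha_real <- e / sum(e)
  pooled <- drop(crossprod(Hr, alpha_real))
  alpha <- c(alpha_real, rep(0, nrow(H) - nreal))
  list(alpha = alpha, pooled = pooled,
       cache = list(Hr = Hr, U = U, alpha_real = alpha_real, nreal = nreal))
}

pool_backward <- function(dpooled, dalpha_extra, cache, p) {
  Hr <- cache$Hr; U <- cache$U; a <- cache$alpha_real
  dalpha <- drop(Hr %*% dpooled)
  if (!is.null(dalpha_extra)) dalpha <- dalpha + dalpha_extra
  dH <- outer(a, dpooled)
  ds <- a * (dalpha - sum(dalpha * a))
  dv <- drop(crossprod(U, ds))
  dU <- outer(ds, p$v)
  dpre <- dU * (1 - U * U)
  dW <- crossprod(Hr, dpre)
  db <- colSums(dpre)
  dH <- dH + dpre %*% t(p$W)
  list(dH = dH, grads = list(W = dW, b = db, v = dv))
}

#' Attention pooling of token embeddings
#'
#' Additive attention: `score_i = v' tanh(W h_i + b)`, softmax-normalised
#' over non-padding positions; the pooled report vector is the weighted sum
#' of token vectors. Padding positions receive exactly zero weight.
#'
#' @param emb Token-embedding matrix (rows = positions).
#' @param mask 0/1 vector marking real tokens; `NULL` means all real.
#' @param params Pooling parameters (`W`, `b`, `v`); a fresh set is drawn
#'   when omitted (seeded), for architecture-contract checks.
#' @param seed Seed used only when `params` is omitted.
#' @return List with `weights` (length `nrow(emb)`, sums to 1 over real
#'   positions) and `pooled` (length-`d` vector).
#' @export
attention_pool <- function(emb, mask = NULL, params = NULL, seed = 1L) {
  emb <- as.matrix(emb)
  if (is.null(mask)) mask <- rep(1L, nrow(emb))
  if (length(mask) != nrow(emb)) {
    stop("`mask` must be parallel to the embedding rows", call. = FALSE)
  }
  if (any(mask[-seq_len(sum(mask))] != 0)) {
    stop("padding must be trailing (mask must be 1...1 0...0)", call. = FALSE)
  }
  nreal <- sum(mask == 1)
  if (nreal == 0L) stop("all-padding mask: nothing to pool", call. = FALSE)
  if (is.null(params)) {
    params <- with_seed(seed, pool_params_init(ncol(emb), ncol(emb)))
  }
  out <- pool_forward(emb, nreal, params)
  list(weights = out$alpha, pooled = out$pooled)
}

head_params_init <- function(d, hidden) {
  list(W1 = init_matrix(d, hidden, sd = sqrt(2 / d)), b1 = rep(0, hidden),
       w2 = stats::rnorm(hidden, sd = sqrt(1 / hidden)), b2 = 0)
}

head_forward <- function(pooled, p) {
  hpre <- drop(pooled %*% p$W1) + p$b1
  h <- pmax(hpre, 0)
  logit <- sum(h * p$w2) + p$b2
  list(logit = logit, prob = sigmoid(logit), cache = list(pooled = pooled, h = h))
}

head_backward <- function(dlogit, cache, p) {
  dw2 <- cache$h * dlogit
  db2 <- dlogit
  dh <- p$w2 * dlogit * (cache$h > 0)
  dW1 <- outer(cache$pooled, dh)
  db1 <- dh
  dpooled <- drop(p$W1 %*% dh)
  list(dpooled = dpooled, grads = list(W1 = dW1, b1 = db1, w2 = dw2, b2 = db2))
}

#' Single-hidden-layer classification head
#'
#' `p = sigmoid(w2' relu(W1 x + b1) + b2)`; output strictly in (0, 1).
#'
#' @param pooled A length-`d` pooled report vector.
#' @param head Head parameters (`W1`, `b1`, `w2`, `b2`), e.g. from a trained
#'   classifier, or from [new_classifier_head()].
#' @return Probability in (0, 1).
#' @export
classify <- function(pooled, head) {
  pooled <- as.numeric(pooled)
  if (any(!is.finite(pooled))) stop("`pooled` must be finite", call. = FALSE)
  if (length(pooled) != nrow(head$W1)) {
    stop("dimension mismatch between `pooled` and the head", call. = FALSE)
  }
  head_forward(pooled, head)$prob
}

#' @rdname classify
#' @param d Input width.
#' @param hidden Hidden width (default 256).
#' @param seed Initialisation seed.
#' @export
new_classifier_head <- function(d, hidden = 256L, seed = 1L) {
  with_seed(seed, head_params_init(d, hidden))
}

#' Create an untrained report classifier
#'
#' Bundles a desk-scale encoder, additive attention pooling and a
#' single-hidden-layer head into one end-to-end trainable model for one
#' label category. Eight such models — one for `abnormal` plus one per
#' granular category — make up the full labelling pipeline.
#'
#' @param vocab A `report_vocabulary`.
#' @param category Label column this model predicts.
#' @param d,n_layers,n_heads,d_ff,max_len Encoder architecture; see
#'   [tiny_encoder()].
#' @param attn_dim Width of the attention scorer (default `d`).
#' @param head_hidden Hidden width of the classification head.
#' @param seed Initialisation seed.
#' @return An object of class `report_classifier`.
#' @export
report_classifier <- function(vocab, category = "abnormal", d = 64L,
                              n_layers = 2L, n_heads = 4L, d_ff = 128L,
                              max_len = 64L, attn_dim = d, head_hidden = 256L,
                              seed = 1L) {
  stopifnot(inherits(vocab, "report_vocabulary"))
  enc <- tiny_encoder(vocab, d = d, n_layers = n_layers, n_heads = n_heads,
                      d_ff = d_ff, max_len = max_len, seed = seed)
  extra <- with_seed(derive_seed(seed, 1L), {
    list(pool = pool_params_init(d, attn_dim),
         head = head_params_init(d, head_hidden))
  })
  structure(list(cfg = c(enc$cfg, list(attn_dim = attn_dim,
                                       head_hidden = head_hidden)),
                 params = list(encoder = enc$params, pool = extra$pool,
                               head = extra$head),
                 vocab = vocab, category = category,
                 threshold = 0.5, history = NULL),
            class = "report_classifier")
}

#' @export
print.report_classifier <- function(x, ...) {
  cat(sprintf("<report_classifier> category '%s': %d-layer encoder (d = %d, %d heads) + attention pool + head(%d)\n",
              x$category, x$cfg$n_layers, x$cfg$d, x$cfg$n_heads,
              x$cfg$head_hidden))
  if (!is.null(x$history)) {
    best <- which.min(x$history$val_loss)
    cat(sprintf("  trained %d epochs; selected epoch %d (val loss %.4f)\n",
                nrow(x$history), best, x$history$val_loss[best]))
  }
  invisible(x)
}

# Full end-to-end forward for one (already trimmed) id sequence.
model_forward <- function(ids, params, cfg, with_cache = FALSE) {
  fwd <- encoder_forward(ids, length(ids), params$encoder, cfg,
                         with_cache = with_cache)
  H <- if (with_cache) fwd$H else fwd
  pool <- pool_forward(H, length(ids), params$pool)
  hd <- head_forward(pool$pooled, params$head)
  res <- list(prob = hd$prob, logit = hd$logit, alpha = pool$alpha,
              pooled = pool$pooled)
  if (with_cache) res$cache <- list(enc = fwd, pool = pool$cache, head = hd$cache)
  res
}

model_backward <- function(dlogit, cache, params, cfg) {
  hb <- head_backward(dlogit, cache$head, params$head)
  pb <- pool_backward(hb$dpooled, NULL, cache$pool, params$pool)
  eg <- encoder_backward(pb$dH, cache$enc, params$encoder, cfg)
  list(encoder = eg, pool = pb$grads, head = hb$grads)
}

model_tokenize <- function(model, text) {
  normalise_and_tokenize(text, model$vocab, max_len = model$cfg$max_len,
                         pad = FALSE)
}

#' Predict category probabilities for report texts
#'
#' @param model A trained or initialised `report_classifier`.
#' @param texts Character vector of report texts.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, texts) {
  stopifnot(inherits(model, "report_classifier"))
  vapply(texts, function(tx) {
    tok <- model_tokenize(model, tx)
    model_forward(tok$token_ids, model$params, model$cfg)$prob
  }, numeric(1), USE.NAMES = FALSE)
}

#' Word-level attention weights for a report
#'
#' Maps the attention-pooling weights back to surface tokens, for
#' interpretability: on a trained model, tokens of the finding lexicon in a
#' true-positive report receive systematically higher weight than filler
#' tokens.
#'
#' @param report A report text (or one-row data frame with a `text` column).
#' @param model A `report_classifier`.
#' @param drop_special Drop the `<cls>`/`<sep>` boundary rows (weights are
#'   then renormalised to sum to 1 over surface tokens).
#' @return Data frame with columns `token` and `weight`, in report order;
#'   weights sum to 1.
#' @export
attention_report <- function(report, model, drop_special = FALSE) {
  stopifnot(inherits(model, "report_classifier"))
  if (is.data.frame(report)) report <- report$text[1]
  if (is.null(report) || !nzchar(trimws(report))) {
    stop("empty report", call. = FALSE)
  }
  tok <- model_tokenize(model, report)
  out <- model_forward(tok$token_ids, model$params, model$cfg)
  df <- data.frame(token = detokenize(tok$token_ids, model$vocab,
                                      drop_special = FALSE),
                   weight = out$alpha, stringsAsFactors = FALSE)
  if (drop_special) {
    df <- df[!df$token %in% RESERVED_TOKENS, , drop = FALSE]
    df$weight <- df$weight / sum(df$weight)
    rownames(df) <- NULL
  }
  df
}

#' Export attention weights as CSV or an HTML heatmap
#'
#' @param attn A data frame from [attention_report()].
#' @param path Output path (`.csv` or `.html`).
#' @return `path`, invisibly.
#' @export
write_attention <- function(attn, path) {
  if (grepl("\\.html$", path, ignore.case = TRUE)) {
    shade <- pmin(attn$weight / max(attn$weight), 1)
    spans <- sprintf(
      '<span style="background: rgba(178, 34, 52, %.3f); padding: 1px;">%s</span>',
      shade, vapply(attn$token, function(t) gsub("<", "&lt;", t), ""))
    html <- c("<!DOCTYPE html><html><body><p>", paste(spans, collapse = " "),
              "</p></body></html>")
    writeLines(html, path)
  } else {
    utils::write.csv(attn, path, row.names = FALSE)
  }
  invisible(path)
}

#' Save / load a trained classifier
#'
#' The archive is a single self-describing JSON file: architecture config,
#' category, vocabulary and all parameter arrays.
#'
#' @param model A `report_classifier`.
#' @param path File path (`.json`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  ser <- list(class = "report_classifier", cfg = model$cfg,
              category = model$category, threshold = model$threshold,
              vocab = list(tokens = model$vocab$tokens, mode = model$vocab$mode,
                           min_count = model$vocab$min_count),
              params = model$params,
              history = if (is.null(model$history)) NULL
                        else as.list(model$history))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

relist_matrices <- function(p, ref) {
  if (is.list(ref) && !is.null(names(ref))) {
    out <- lapply(names(ref), function(nm) relist_matrices(p[[nm]], ref[[nm]]))
    names(out) <- names(ref)
    out
  } else if (is.list(ref)) {
    lapply(seq_along(ref), function(i) relist_matrices(p[[i]], ref[[i]]))
  } else if (is.matrix(ref)) {
    matrix(unlist(p), nrow(ref), ncol(ref), byrow = TRUE)
  } else {
    as.numeric(unlist(p))
  }
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cfg <- lapply(ser$cfg, function(x) if (is.numeric(x)) as.integer(x) else x)
  tokens <- unlist(ser$vocab$tokens)
  vocab <- structure(list(tokens = tokens,
                          id_of = stats::setNames(seq_along(tokens), tokens),
                          mode = ser$vocab$mode,
                          min_count = as.integer(ser$vocab$min_count)),
                     class = "report_vocabulary")
  ref <- report_classifier(vocab, category = ser$category, d = cfg$d,
                           n_layers = cfg$n_layers, n_heads = cfg$n_heads,
                           d_ff = cfg$d_ff, max_len = cfg$max_len,
                           attn_dim = cfg$attn_dim,
                           head_hidden = cfg$head_hidden)
  ref$params <- relist_matrices(ser$params, ref$params)
  ref$threshold <- as.numeric(ser$threshold)
  if (!is.null(ser$history)) {
    ref$history <- as.data.frame(lapply(ser$history, unlist))
  }
  ref
}

#' Extract the encoder from a classifier
#' @param model A `report_classifier`.
#' @return A `report_encoder` sharing the trained weights.
#' @export
model_encoder <- function(model) {
  structure(list(cfg = model$cfg[c("vocab_size", "d", "n_layers", "n_heads",
                                   "d_ff", "max_len")],
                 params = model$params$encoder), class = "report_encoder")
}
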