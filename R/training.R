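#' Training hyperparameters
#'
#' @param learning_rate Adam learning rate. The default 1e-5 is the
#'   fine-tuning rate appropriate for a large pretrained encoder (it avoids
#'   catastrophic forgetting); desk-scale encoders trained from random
#'   initialisation need a larger rate, typically 1e-3.
#' @param batch_size Minibatch size (default 16).
#' @param max_epochs Number of epochs; a checkpoint is taken after each.
#' @param seed Run seed: controls initialisation and the per-epoch shuffles.
#' @return An object of class `hyperparams`.
#' @export
hyperparams <- function(learning_rate = 1e-5, batch_size = 16L,
                        max_epochs = 10L, seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("`learning_rate` must be positive", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = assert_count(batch_size, "batch_size", positive = TRUE),
                 max_epochs = assert_count(max_epochs, "max_epochs"),
                 seed = as.integer(seed)),
            class = "hyperparams")
}

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Tokenize every report once up front; returns a list of trimmed id vectors.
tokenize_corpus <- function(texts, vocab, max_len) {
  lapply(texts, function(tx) {
    normalise_and_tokenize(tx, vocab, max_len = max_len, pad = FALSE)$token_ids
  })
}

corpus_parts <- function(x) {
  if (inherits(x, "report_corpus")) return(list(reports = x$reports, labels = x$labels))
  if (is.list(x) && !is.null(x$reports) && !is.null(x$labels)) {
    return(list(reports = x$reports, labels = x$labels))
  }
  stop("expected a report_corpus or a list(reports, labels)", call. = FALSE)
}

#' Subset a corpus by report ids
#' @param corpus A `report_corpus` (or `list(reports, labels)`).
#' @param report_ids Report ids to keep.
#' @return A `report_corpus` restricted to those reports.
#' @export
subset_corpus <- function(corpus, report_ids) {
  parts <- corpus_parts(corpus)
  keep_r <- parts$reports$report_id %in% report_ids
  keep_l <- parts$labels$report_id %in% report_ids
  structure(list(reports = parts$reports[keep_r, , drop = FALSE],
                 labels = parts$labels[keep_l, , drop = FALSE],
                 meta = NULL, config = NULL),
            class = "report_corpus")
}

mean_loss_over <- function(seqs, y, params, cfg) {
  probs <- vapply(seqs, function(ids) model_forward(ids, params, cfg)$prob,
                  numeric(1))
  bce_loss(probs, y)
}

#' Train a report classifier end-to-end
#'
#' Minimises binary cross-entropy with Adam over the encoder, attention
#' pooling and head jointly. A parameter checkpoint is taken after every
#' epoch and the checkpoint with the lowest validation loss is returned.
#' Shuffling is reseeded each epoch from the run seed, the final partial
#' batch is averaged per example, and two runs with the same seed produce
#' identical histories.
#'
#' @param train,val Corpora (`report_corpus` or `list(reports, labels)`).
#'   Their patient sets must be disjoint.
#' @param category Label column to train on.
#' @param hp A [hyperparams()].
#' @param model Optional pre-built `report_classifier` (otherwise a
#'   desk-scale one is created from `vocab`).
#' @param vocab Optional vocabulary; built from the training reports when
#'   missing.
#' @param max_len,d,n_layers,n_heads,d_ff,head_hidden Architecture used when
#'   `model` is not supplied.
#' @param verbose Print one line per epoch.
#' @return The trained `report_classifier`; its `history` field is a data
#'   frame with one row per epoch (`epoch`, `train_loss`, `val_loss`,
#'   `selected`).
#' @export
train_model <- function(train, val, category = "abnormal", hp = hyperparams(),
                        model = NULL, vocab = NULL, max_len = 64L, d = 64L,
                        n_layers = 2L, n_heads = 4L, d_ff = 128L,
                        head_hidden = 256L, verbose = FALSE) {
  trn <- corpus_parts(train)
  vl <- corpus_parts(val)
  if (nrow(trn$reports) == 0L || nrow(vl$reports) == 0L) {
    stop("train and validation corpora must be non-empty", call. = FALSE)
  }
  if (hp$max_epochs < 1L) stop("`max_epochs` must be at least 1", call. = FALSE)
  if (!category %in% names(trn$labels)) {
    stop(sprintf("category '%s' not present in labels", category), call. = FALSE)
  }
  overlap <- intersect(trn$reports$patient_id, vl$reports$patient_id)
  if (length(overlap) > 0L) {
    stop(sprintf("data leakage: %d patient(s) appear in both train and validation",
                 length(overlap)), call. = FALSE)
  }
  y_train <- trn$labels[[category]][match(trn$reports$report_id,
                                          trn$labels$report_id)]
  y_val <- vl$labels[[category]][match(vl$reports$report_id,
                                       vl$labels$report_id)]
  if (length(unique(y_train)) < 2L) {
    warning("degenerate training data: a single class is present", call. = FALSE)
  }

  if (is.null(model)) {
    if (is.null(vocab)) vocab <- build_vocabulary(trn$reports$text)
    model <- report_classifier(vocab, category = category, d = d,
                               n_layers = n_layers, n_heads = n_heads,
                               d_ff = d_ff, max_len = max_len,
                               head_hidden = head_hidden, seed = hp$seed)
  }
  model$category <- category
  cfg <- model$cfg
  params <- model$params
  seq_train <- tokenize_corpus(trn$reports$text, model$vocab, cfg$max_len)
  seq_val <- tokenize_corpus(vl$reports$text, model$vocab, cfg$max_len)

  n <- length(seq_train)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(val = Inf, params = params, epoch = 0L)

  for (epoch in seq_len(hp$max_epochs)) {
    order_idx <- with_seed(derive_seed(hp$seed, 100L + epoch), sample.int(n))
    losses <- numeric(0)
    b0 <- 1L
    while (b0 <= n) {
      idx <- order_idx[b0:min(b0 + hp$batch_size - 1L, n)]
      gsum <- NULL
      batch_loss <- 0
      for (i in idx) {
        fwd <- model_forward(seq_train[[i]], params, cfg, with_cache = TRUE)
        y <- y_train[i]
        p <- min(max(fwd$prob, 1e-12), 1 - 1e-12)
        batch_loss <- batch_loss - (y * log(p) + (1 - y) * log(1 - p))
        g <- model_backward(fwd$prob - y, fwd$cache, params, cfg)
        gsum <- if (is.null(gsum)) g else tree_add(gsum, g)
      }
      gmean <- tree_scale(gsum, 1 / length(idx))
      upd <- adam_step(params, gmean, state, hp$learning_rate)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, batch_loss / length(idx))
      b0 <- b0 + hp$batch_size
    }
    train_loss <- mean(losses)
    val_loss <- mean_loss_over(seq_val, y_val, params, cfg)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss))
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = params, epoch = epoch)
    }
    if (verbose) {
      message(sprintf("epoch %d: train loss %.4f, val loss %.4f%s", epoch,
                      train_loss, val_loss,
                      if (best$epoch == epoch) " *" else ""))
    }
  }

  history$selected <- history$epoch == best$epoch
  model$params <- best$params
  model$history <- history
  model
}

#' Low-level optimisation loop over a fixed batch
#'
#' Runs `n_steps` Adam updates on one batch of texts — the capacity check
#' that a desk-scale model can drive training binary cross-entropy to zero
#' on a small memorisable set.
#'
#' @param model A `report_classifier`.
#' @param texts,y Training texts and 0/1 labels.
#' @param n_steps Number of Adam steps.
#' @param learning_rate Adam learning rate.
#' @return List with the updated `model` and the per-step `loss` vector.
#' @export
fit_batch <- function(model, texts, y, n_steps = 200L, learning_rate = 1e-3) {
  stopifnot(inherits(model, "report_classifier"))
  seqs <- tokenize_corpus(texts, model$vocab, model$cfg$max_len)
  params <- model$params
  cfg <- model$cfg
  state <- adam_init(params)
  loss <- numeric(n_steps)
  for (step in seq_len(n_steps)) {
    gsum <- NULL
    tot <- 0
    for (i in seq_along(seqs)) {
      fwd <- model_forward(seqs[[i]], params, cfg, with_cache = TRUE)
      p <- min(max(fwd$prob, 1e-12), 1 - 1e-12)
      tot <- tot - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
      g <- model_backward(fwd$prob - y[i], fwd$cache, params, cfg)
      gsum <- if (is.null(gsum)) g else tree_add(gsum, g)
    }
    loss[step] <- tot / length(seqs)
    upd <- adam_step(params, tree_scale(gsum, 1 / length(seqs)), state,
                     learning_rate)
    params <- upd$params
    state <- upd$state
  }
  model$params <- params
  list(model = model, loss = loss)
}

#' Write a training history as CSV
#' @param model A trained `report_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_history <- function(model, path) {
  if (is.null(model$history)) stop("model has no training history", call. = FALSE)
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
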