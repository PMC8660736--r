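# Batch label assignment and workflow orchestration behind the command-line
# interface.

#' Assign all eight labels to a corpus with trained models
#'
#' Runs each category's trained classifier in inference mode over every
#' report, streaming in chunks so memory stays bounded in corpus size, and
#' returns per-report probabilities plus binary calls at the configured
#' threshold.
#'
#' @param corpus A `report_corpus`, reports data frame or character vector
#'   of texts.
#' @param models Named list of trained `report_classifier` objects; names
#'   must cover [label_columns()] (or the subset you pass as `categories`).
#' @param threshold Calling threshold applied to every category.
#' @param categories Categories to assign (default: all eight).
#' @param chunk_size Reports scored per streaming chunk.
#' @return Data frame: `report_id`, then `prob_<category>` and
#'   `call_<category>` per category, plus a `model_version` column echoing
#'   each model's category and epoch.
#' @export
assign_labels <- function(corpus, models, threshold = 0.5,
                          categories = label_columns(), chunk_size = 256L) {
  reports <- if (inherits(corpus, "report_corpus")) corpus$reports
             else if (is.data.frame(corpus)) corpus
             else data.frame(report_id = sprintf("r%06d", seq_along(corpus)),
                             text = as.character(corpus),
                             stringsAsFactors = FALSE)
  missing <- setdiff(categories, names(models))
  if (length(missing) > 0L) {
    stop(sprintf("missing trained model(s) for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  assert_probability(threshold, "threshold")
  n <- nrow(reports)
  out_chunks <- list()
  b0 <- 1L
  while (b0 <= n) {
    idx <- b0:min(b0 + chunk_size - 1L, n)
    chunk <- data.frame(report_id = reports$report_id[idx],
                        stringsAsFactors = FALSE)
    for (cat in categories) {
      p <- predict_proba(models[[cat]], reports$text[idx])
      chunk[[paste0("prob_", cat)]] <- p
      chunk[[paste0("call_", cat)]] <- as.integer(p >= threshold)
    }
    out_chunks[[length(out_chunks) + 1L]] <- chunk
    b0 <- b0 + chunk_size
  }
  out <- if (n == 0L) {
    chunk <- data.frame(report_id = character(0), stringsAsFactors = FALSE)
    for (cat in categories) {
      chunk[[paste0("prob_", cat)]] <- numeric(0)
      chunk[[paste0("call_", cat)]] <- integer(0)
    }
    chunk
  } else {
    do.call(rbind, out_chunks)
  }
  attr(out, "model_version") <- vapply(categories, function(cat) {
    m <- models[[cat]]
    ep <- if (is.null(m$history)) 0L else m$history$epoch[m$history$selected][1]
    sprintf("%s@epoch%d", cat, ep)
  }, "")
  attr(out, "threshold") <- threshold
  out
}

#' Train one classifier per label category
#'
#' @param corpus Labelled corpus.
#' @param hp [hyperparams()] shared across categories (each category gets a
#'   derived seed).
#' @param categories Categories to train (default all eight).
#' @param val_fraction Patient-level fraction held out for validation and
#'   checkpoint selection.
#' @param ... Architecture arguments for [train_model()].
#' @return Named list of trained `report_classifier` objects.
#' @export
train_all_categories <- function(corpus, hp = hyperparams(),
                                 categories = label_columns(),
                                 val_fraction = 0.2, ...) {
  parts <- corpus_parts(corpus)
  sp <- patient_level_split(parts$reports,
                            fractions = c(1 - val_fraction, val_fraction, 0),
                            seed = derive_seed(hp$seed, 7L))
  sets <- split_corpus(corpus, sp)
  vocab <- build_vocabulary(sets$train$reports$text)
  models <- list()
  for (i in seq_along(categories)) {
    hp_c <- hp
    hp_c$seed <- derive_seed(hp$seed, 500L + i)
    models[[categories[i]]] <- train_model(sets$train, sets$val,
                                           category = categories[i],
                                           hp = hp_c, vocab = vocab, ...)
  }
  models
}

#' Provenance header for pipeline outputs
#'
#' @param config Any list-like run configuration.
#' @param seed The run seed.
#' @return One-line string: config hash, seed, package version.
#' @export
provenance_header <- function(config, seed) {
  blob <- paste(deparse(config), collapse = "")
  hash <- sum(utf8ToInt(blob) * (seq_along(utf8ToInt(blob)) %% 97 + 1)) %% 1e9
  sprintf("# radlabel %s | seed %s | config %09.0f",
          as.character(utils::packageVersion("radlabel")), seed, hash)
}

#' Read a key-value run configuration file
#'
#' Plain `key = value` lines; `#` comments allowed. Values are parsed as
#' numbers where possible.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
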