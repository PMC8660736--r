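# Report pre-processing: lower-casing and conversion of each report into a
# sequence of integer token identifiers. Only the normalisation a
# transformer-style encoder needs is performed — no stop-word removal, no
# stemming.

RESERVED_TOKENS <- c("<pad>", "<unk>", "<cls>", "<sep>")

# Lower-case and split on whitespace, detaching punctuation as its own
# tokens. Deterministic and case-insensitive by construction.
normalise_words <- function(text) {
  x <- tolower(text)
  x <- gsub("([[:punct:]])", " \\1 ", x)
  x <- trimws(gsub("[[:space:]]+", " ", x))
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1]]
}

#' Build a token-id vocabulary from a corpus
#'
#' Whitespace mode assigns one id per lower-cased word seen at least
#' `min_count` times; subword mode builds a compact corpus-derived subword
#' inventory (frequent whole words plus single characters and `##`-prefixed
#' continuation pieces) tokenised by greedy longest match, mirroring the
#' vocabulary shape of pretrained contextual encoders. Both modes include
#' the reserved `<pad>`, `<unk>`, `<cls>` and `<sep>` identifiers and form a
#' bijective token-id map.
#'
#' @param corpus A `report_corpus`, a data frame with a `text` column, or a
#'   character vector of report texts.
#' @param mode `"whitespace"` or `"subword"`.
#' @param min_count Minimum occurrences for a word to receive its own id.
#' @return An object of class `report_vocabulary`.
#' @export
#' @examples
#' v <- build_vocabulary("a b a", min_count = 1)
#' vocab_size(v)
build_vocabulary <- function(corpus, mode = c("whitespace", "subword"),
                             min_count = 1L) {
  mode <- match.arg(mode)
  texts <- corpus_texts(corpus)
  if (length(texts) == 0L) stop("corpus is empty", call. = FALSE)
  words <- unlist(lapply(texts, normalise_words), use.names = FALSE)
  if (length(words) == 0L) stop("corpus contains no tokens", call. = FALSE)
  freq <- sort(table(words), decreasing = TRUE)
  kept <- names(freq)[freq >= min_count]

  if (mode == "subword") {
    chars <- sort(unique(unlist(strsplit(names(freq), ""), use.names = FALSE)))
    tokens <- unique(c(RESERVED_TOKENS, kept, chars, paste0("##", chars)))
  } else {
    tokens <- c(RESERVED_TOKENS, kept)
  }
  ids <- seq_along(tokens)  # 1-based; <pad> is always id 1
  structure(list(tokens = tokens,
                 id_of = stats::setNames(ids, tokens),
                 mode = mode,
                 min_count = as.integer(min_count)),
            class = "report_vocabulary")
}

corpus_texts <- function(corpus) {
  if (inherits(corpus, "report_corpus")) return(corpus$reports$text)
  if (is.data.frame(corpus)) return(corpus$text)
  as.character(corpus)
}

#' @export
print.report_vocabulary <- function(x, ...) {
  cat(sprintf("<report_vocabulary> %d tokens (%s mode, min_count = %d)\n",
              length(x$tokens), x$mode, x$min_count))
  invisible(x)
}

#' @rdname build_vocabulary
#' @param vocab A `report_vocabulary`.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

token_id <- function(vocab, token) {
  id <- unname(vocab$id_of[token])
  id[is.na(id)] <- unname(vocab$id_of["<unk>"])
  id
}

# Greedy longest-match subword split of a single word, BERT-style.
subword_split <- function(word, vocab) {
  pieces <- character(0)
  rest <- word
  first <- TRUE
  while (nzchar(rest)) {
    n <- nchar(rest)
    hit <- NA_character_
    for (len in seq(n, 1L)) {
      cand <- substr(rest, 1L, len)
      key <- if (first) cand else paste0("##", cand)
      if (!is.na(vocab$id_of[key])) { hit <- key; break }
    }
    if (is.na(hit)) return("<unk>")
    pieces <- c(pieces, hit)
    rest <- substr(rest, nchar(gsub("^##", "", hit)) + 1L, n)
    first <- FALSE
  }
  pieces
}

#' Normalise a report and convert it to integer token identifiers
#'
#' Lower-cases the text, tokenises it under the vocabulary's mode, brackets
#' it with `<cls>`/`<sep>`, truncates over-long sequences (keeping both
#' boundary tokens) and pads to `max_len` with the `<pad>` id.
#'
#' @param text A single report text.
#' @param vocab A [build_vocabulary()] result.
#' @param max_len Maximum sequence length including boundary tokens.
#' @param truncation `"tail"` drops tokens from the end of over-long reports
#'   (findings sentences dominate early positions); `"head"` keeps the end.
#' @param pad If `FALSE`, no padding is appended.
#' @return A `tokenized_report`: list with integer `token_ids`, 0/1 `mask`
#'   (1 = real token) and `length` (number of real tokens);
#'   `length == sum(mask)`.
#' @export
#' @examples
#' v <- build_vocabulary("normal intracranial appearances")
#' tr <- normalise_and_tokenize("Normal Intracranial appearances", v, max_len = 8)
#' tr$token_ids
normalise_and_tokenize <- function(text, vocab, max_len = 512L,
                                   truncation = c("tail", "head"),
                                   pad = TRUE) {
  truncation <- match.arg(truncation)
  stopifnot(inherits(vocab, "report_vocabulary"))
  max_len <- assert_count(max_len, "max_len", positive = TRUE)
  if (max_len < 3L) stop("`max_len` must be at least 3", call. = FALSE)
  words <- normalise_words(text)
  if (length(words) == 0L) {
    stop("empty report: no tokens remain after normalisation", call. = FALSE)
  }
  toks <- if (vocab$mode == "subword") {
    unlist(lapply(words, subword_split, vocab = vocab), use.names = FALSE)
  } else {
    words
  }
  content <- token_id(vocab, toks)
  keep <- max_len - 2L
  if (length(content) > keep) {
    content <- if (truncation == "tail") {
      content[seq_len(keep)]
    } else {
      content[seq(length(content) - keep + 1L, length(content))]
    }
  }
  ids <- c(token_id(vocab, "<cls>"), content, token_id(vocab, "<sep>"))
  len <- length(ids)
  mask <- rep(1L, len)
  if (pad && len < max_len) {
    ids <- c(ids, rep(unname(vocab$id_of["<pad>"]), max_len - len))
    mask <- c(mask, rep(0L, max_len - len))
  }
  structure(list(token_ids = as.integer(ids), mask = as.integer(mask),
                 length = len), class = "tokenized_report")
}

#' Map token ids back to surface tokens
#'
#' For whitespace-mode vocabularies, detokenising an in-vocabulary report
#' recovers the normalised input.
#'
#' @param ids Integer token ids.
#' @param vocab The vocabulary they were produced with.
#' @param drop_special Drop reserved boundary/padding tokens.
#' @return Character vector of tokens.
#' @export
detokenize <- function(ids, vocab, drop_special = TRUE) {
  toks <- vocab$tokens[ids]
  if (drop_special) toks <- toks[!toks %in% RESERVED_TOKENS]
  toks
}

#' Persist / load a vocabulary
#'
#' The on-disk form is a UTF-8 two-column tab-separated text file
#' (token, id) with a `# mode:` header line.
#'
#' @param vocab A `report_vocabulary`.
#' @param path File path.
#' @return `write_vocabulary` returns `path` invisibly; `read_vocabulary`
#'   the vocabulary.
#' @export
write_vocabulary <- function(vocab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# mode: %s min_count: %d", vocab$mode, vocab$min_count),
             con, useBytes = TRUE)
  writeLines(sprintf("%s\t%d", vocab$tokens, seq_along(vocab$tokens)),
             con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  tokens <- vapply(body, `[[`, "", 1L)
  structure(list(tokens = tokens,
                 id_of = stats::setNames(seq_along(tokens), tokens),
                 mode = hdr[2],
                 min_count = as.integer(hdr[4])),
            class = "report_vocabulary")
}
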