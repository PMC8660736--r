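# Corpus lexical-complexity statistics: word-frequency spectrum, type-token
# ratio, Yule's I and unique words per report. The word definition here is
# deliberately independent of the model tokenizer: lower-cased,
# punctuation-stripped whitespace tokens.

lexical_words <- function(text) {
  x <- tolower(text)
  x <- gsub("[[:punct:]]", " ", x)
  x <- trimws(gsub("[[:space:]]+", " ", x))
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1]]
}

#' Word-frequency spectrum of a corpus
#'
#' Counts, for each occurrence count `i`, the number of word types `V(i)`
#' appearing exactly `i` times, together with the derived totals
#' `M1 = sum_i V(i)` (types), `N_tokens = sum_i i V(i)` and
#' `M2 = sum_i i^2 V(i)`.
#'
#' @param corpus Texts (`report_corpus`, data frame with `text`, or a
#'   character vector of reports).
#' @return A `frequency_spectrum`: list with `V` (named integer vector:
#'   names are occurrence counts), `M1`, `N_tokens`, `M2`, `n_reports`.
#' @export
#' @examples
#' s <- frequency_spectrum("a b a")
#' s$V  # one type once, one type twice
frequency_spectrum <- function(corpus) {
  texts <- corpus_texts(corpus)
  if (length(texts) == 0L) stop("corpus is empty", call. = FALSE)
  words <- unlist(lapply(texts, lexical_words), use.names = FALSE)
  if (length(words) == 0L) stop("corpus contains no words", call. = FALSE)
  type_freq <- table(words)
  V <- table(as.integer(type_freq))
  V <- stats::setNames(as.integer(V), names(V))
  i <- as.integer(names(V))
  structure(list(V = V,
                 M1 = sum(V),
                 N_tokens = sum(i * V),
                 M2 = sum(i^2 * V),
                 n_reports = length(texts)),
            class = "frequency_spectrum")
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat(sprintf("<frequency_spectrum> %d reports: %d tokens, %d types (M2 = %d)\n",
              x$n_reports, x$N_tokens, x$M1, x$M2))
  invisible(x)
}

#' Lexical-richness metrics from a frequency spectrum
#'
#' Type-token ratio `TTR = M1 / N_tokens`, Yule's
#' `I = M1^2 / (M2 - M1)` (the inverse form of Yule's characteristic, up to
#' the 10^4 factor) and unique words per report `M1 / n_reports`. When every
#' type occurs exactly once (`M2 = M1`) Yule's I is reported as `Inf`, the
#' undefined-richness marker.
#'
#' @param s A [frequency_spectrum()].
#' @return Named list: `ttr`, `yule_i`, `unique_per_report`.
#' @export
#' @examples
#' lexical_metrics(frequency_spectrum("a b a"))  # ttr 2/3, yule_i 4/3
lexical_metrics <- function(s) {
  stopifnot(inherits(s, "frequency_spectrum"))
  list(ttr = s$M1 / s$N_tokens,
       yule_i = if (s$M2 == s$M1) Inf else s$M1^2 / (s$M2 - s$M1),
       unique_per_report = s$M1 / s$n_reports)
}

#' Corpus complexity summary table
#'
#' One row per corpus in the style of a published comparative lexical
#' analysis: corpus name, report count, total and unique words, Yule's I,
#' type-token ratio and unique words per report.
#'
#' @param corpora Named list of corpora.
#' @param path Optional CSV output path.
#' @return The summary data frame (written to `path` when given).
#' @export
lexical_summary <- function(corpora, path = NULL) {
  rows <- lapply(names(corpora), function(nm) {
    s <- frequency_spectrum(corpora[[nm]])
    m <- lexical_metrics(s)
    data.frame(corpus = nm, n_reports = s$n_reports, total_words = s$N_tokens,
               unique_words = s$M1, yule_i = m$yule_i, ttr = m$ttr,
               unique_per_report = m$unique_per_report)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Published reference corpus sizes
#'
#' Printed headline counts for three large radiology report corpora (head
#' MRI, head CT, chest radiograph): number of reports, total words and
#' unique words, with the derived unique-words-per-report ratio. These are
#' inputs for arithmetic checks — the underlying corpora are not
#' distributed. Note the published head-MRI type-token ratio (0.019) does
#' not equal unique/total from the same row (0.014); the ratio column here
#' is computed from the printed counts.
#'
#' @return Data frame with columns `corpus`, `n_reports`, `total_words`,
#'   `unique_words`, `unique_per_report`.
#' @export
#' @examples
#' reference_corpus_stats()
reference_corpus_stats <- function() {
  df <- data.frame(
    corpus = c("head_mri", "head_ct", "chest_radiograph"),
    n_reports = c(126556L, 96303L, 160861L),
    total_words = c(14183182, 12110849, 2432099),
    unique_words = c(205048L, 145257L, 6481L)
  )
  df$unique_per_report <- df$unique_words / df$n_reports
  df
}
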