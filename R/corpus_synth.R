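#' Configuration for the synthetic report-corpus generator
#'
#' Defines the study conditions a generated corpus emulates: corpus size,
#' patient structure, category prevalences, distant-negation and hedging
#' rates, and reporter-style diversity.
#'
#' Per-category prevalences are *derived*, not free: an abnormal report
#' receives `1 + min(Poisson(mean_granular_per_abnormal - 1), 4)` distinct
#' granular categories (so between 1 and 5), drawn with probability
#' proportional to `granular_weights`. The implied marginal prevalence of
#' category *c* is therefore
#' `prevalence_abnormal * E[k] * w_c` (with `E[k]` the truncated-Poisson
#' mean and `w` the normalised weights); these derived values are stored in
#' the config as `prevalence` and are what a calibration check should
#' recover.
#'
#' @param n_reports Number of reports to generate.
#' @param n_patients Optional number of distinct patients
#'   (`n_patients <= n_reports`). When `NULL` (default), patients are drawn
#'   with `1 + Geometric(0.5)` reports each, capped at 6, until the corpus is
#'   full, so multi-report patients make patient-level splitting non-trivial.
#' @param prevalence_abnormal Probability that a report is abnormal.
#' @param mean_granular_per_abnormal Target mean number of granular labels
#'   per abnormal report (>= 1). Default 1.56.
#' @param granular_weights Positive weights over the seven granular
#'   categories (named or in [granular_categories()] order). Default equal.
#' @param distant_negation_rate Probability that a report carries one or two
#'   distant-negated mentions of categories it does *not* have.
#' @param hedging_rate Probability that a positive finding sentence uses a
#'   hedged frame ("there may be some evidence of ...").
#' @param n_styles Number of simulated reporter styles.
#' @param n_sites Number of simulated hospitals.
#' @param seed Integer seed; the same config yields a byte-identical corpus.
#' @return An object of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_reports = 50, seed = 1)
#' cfg$prevalence
generator_config <- function(n_reports,
                             n_patients = NULL,
                             prevalence_abnormal = 0.5,
                             mean_granular_per_abnormal = 1.56,
                             granular_weights = NULL,
                             distant_negation_rate = 0.3,
                             hedging_rate = 0.1,
                             n_styles = 4,
                             n_sites = 1,
                             seed = 1L) {
  n_reports <- assert_count(n_reports, "n_reports")
  assert_probability(prevalence_abnormal, "prevalence_abnormal")
  assert_probability(distant_negation_rate, "distant_negation_rate")
  assert_probability(hedging_rate, "hedging_rate")
  n_styles <- assert_count(n_styles, "n_styles", positive = TRUE)
  n_sites <- assert_count(n_sites, "n_sites", positive = TRUE)
  if (!is.numeric(mean_granular_per_abnormal) || mean_granular_per_abnormal < 1) {
    stop("`mean_granular_per_abnormal` must be >= 1", call. = FALSE)
  }
  if (!is.null(n_patients)) {
    n_patients <- assert_count(n_patients, "n_patients", positive = n_reports > 0)
    if (n_patients > n_reports) {
      stop("`n_patients` must not exceed `n_reports`", call. = FALSE)
    }
  }
  cats <- granular_categories()
  if (is.null(granular_weights)) {
    granular_weights <- stats::setNames(rep(1, length(cats)), cats)
  }
  if (!is.null(names(granular_weights))) {
    if (!setequal(names(granular_weights), cats)) {
      stop("`granular_weights` names must be the seven granular categories",
           call. = FALSE)
    }
    granular_weights <- granular_weights[cats]
  } else {
    if (length(granular_weights) != length(cats)) {
      stop("`granular_weights` must have length 7", call. = FALSE)
    }
    names(granular_weights) <- cats
  }
  if (any(granular_weights < 0) || sum(granular_weights) <= 0) {
    stop("`granular_weights` must be non-negative with positive sum", call. = FALSE)
  }
  w <- granular_weights / sum(granular_weights)

  # E[k] for k = 1 + min(Poisson(lambda), 4)
  lambda <- mean_granular_per_abnormal - 1
  e_extra <- sum(0:3 * stats::dpois(0:3, lambda)) + 4 * stats::ppois(3, lambda, lower.tail = FALSE)
  e_k <- 1 + e_extra
  prevalence <- c(abnormal = prevalence_abnormal,
                  prevalence_abnormal * e_k * w)
  if (any(prevalence > 1)) {
    stop("implied per-category prevalence exceeds 1; reduce weights or mean",
         call. = FALSE)
  }

  structure(list(
    n_reports = n_reports,
    n_patients = n_patients,
    prevalence_abnormal = prevalence_abnormal,
    mean_granular_per_abnormal = mean_granular_per_abnormal,
    granular_weights = w,
    expected_granular_per_abnormal = e_k,
    prevalence = prevalence,
    distant_negation_rate = distant_negation_rate,
    hedging_rate = hedging_rate,
    n_styles = n_styles,
    n_sites = n_sites,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  reports: %d  patients: %s  seed: %d\n", x$n_reports,
              if (is.null(x$n_patients)) "geometric" else x$n_patients, x$seed))
  cat(sprintf("  P(abnormal): %.2f  mean granular/abnormal: %.2f (E[k] = %.3f)\n",
              x$prevalence_abnormal, x$mean_granular_per_abnormal,
              x$expected_granular_per_abnormal))
  cat(sprintf("  distant negation: %.2f  hedging: %.2f  styles: %d  sites: %d\n",
              x$distant_negation_rate, x$hedging_rate, x$n_styles, x$n_sites))
  invisible(x)
}

# Reports-per-patient sizes: 1 + Geometric(0.5), capped at 6.
draw_patient_sizes <- function(n_reports, n_patients) {
  if (n_reports == 0L) return(integer(0))
  if (is.null(n_patients)) {
    sizes <- integer(0)
    while (sum(sizes) < n_reports) {
      sizes <- c(sizes, pmin(1L + stats::rgeom(max(16L, n_reports %/% 2L), 0.5), 6L))
    }
    keep <- which(cumsum(sizes) >= n_reports)[1]
    sizes <- sizes[seq_len(keep)]
    sizes[keep] <- sizes[keep] - (sum(sizes) - n_reports)
    sizes[sizes > 0L]
  } else {
    sizes <- rep(1L, n_patients)
    extra <- n_reports - n_patients
    while (extra > 0L) {
      open <- which(sizes < 6L)
      i <- if (length(open) == 1L) open else sample(open, 1L)
      sizes[i] <- sizes[i] + 1L
      extra <- extra - 1L
    }
    sizes
  }
}

style_pick <- function(pool, style, n = 1L) {
  # Reporter style biases template choice: the style's preferred rotation of
  # the pool gets triple weight, so corpora mix styles without any style
  # being deterministic.
  m <- length(pool)
  pref <- 1L + (style + seq_len(m)) %% m
  w <- rep(1, m)
  w[pref[1L]] <- 3
  pool[sample.int(m, n, replace = n > m, prob = w)]
}

#' Generate a synthetic neuroradiology report corpus
#'
#' Builds `n_reports` free-text reports (5-10 sentences each: optional
#' clinical-history and protocol sentences, findings sentences, filler
#' normal-anatomy sentences, and a neutral conclusion) together with the
#' eight binary reference labels. Abnormal reports assert their categories'
#' finding phrases inside positive (or hedged) frames; with probability
#' `distant_negation_rate` a report additionally mentions one or two
#' *absent* categories inside distant-negation frames — the finding lexicon
#' appears but the label stays false.
#'
#' @param config A [generator_config()].
#' @param templates Optional template inventory from [report_templates()].
#' @return An object of class `report_corpus`: a list with data frames
#'   `reports` (report_id, patient_id, site_id, style_id, text),
#'   `labels` (report_id, the eight 0/1 label columns, provenance), and
#'   `meta` (per-report negated categories and sentence count, for audits).
#' @export
#' @examples
#' corp <- generate_corpus(generator_config(n_reports = 20, seed = 42))
#' corp
generate_corpus <- function(config, templates = report_templates()) {
  stopifnot(inherits(config, "generator_config"))
  cats <- granular_categories()
  n <- config$n_reports

  empty <- function() {
    reports <- data.frame(report_id = character(0), patient_id = character(0),
                          site_id = character(0), style_id = integer(0),
                          text = character(0), stringsAsFactors = FALSE)
    labs <- data.frame(report_id = character(0), stringsAsFactors = FALSE)
    for (col in label_columns()) labs[[col]] <- integer(0)
    labs$provenance <- character(0)
    meta <- data.frame(report_id = character(0), negated = character(0),
                       n_sentences = integer(0), stringsAsFactors = FALSE)
    structure(list(reports = reports, labels = labs, meta = meta,
                   config = config), class = "report_corpus")
  }
  if (n == 0L) return(empty())

  with_seed(config$seed, {
    sizes <- draw_patient_sizes(n, config$n_patients)
    patient <- rep(sprintf("p%05d", seq_along(sizes)), times = sizes)
    report_id <- sprintf("r%06d", seq_len(n))
    site <- sprintf("site_%02d", sample.int(config$n_sites, n, replace = TRUE))
    style <- sample.int(config$n_styles, n, replace = TRUE)

    abnormal <- stats::runif(n) < config$prevalence_abnormal
    lambda <- config$mean_granular_per_abnormal - 1
    lab <- matrix(0L, n, length(cats), dimnames = list(NULL, cats))
    negated <- character(n)
    text <- character(n)
    n_sent <- integer(n)

    for (i in seq_len(n)) {
      true_cats <- character(0)
      if (abnormal[i]) {
        k <- 1L + min(stats::rpois(1L, lambda), 4L)
        true_cats <- sample(cats, k, prob = config$granular_weights)
        lab[i, true_cats] <- 1L
      }
      neg_cats <- character(0)
      if (stats::runif(1) < config$distant_negation_rate) {
        pool <- setdiff(cats, true_cats)
        if (length(pool) > 0L) {
          neg_cats <- sample(pool, min(sample(1:2, 1L), length(pool)))
        }
      }
      negated[i] <- paste(neg_cats, collapse = ",")

      finding_sents <- character(0)
      for (cc in true_cats) {
        phrase <- style_pick(templates$categories[[cc]], style[i])
        frame <- if (stats::runif(1) < config$hedging_rate) {
          style_pick(templates$hedge_frames, style[i])
        } else {
          style_pick(templates$positive_frames, style[i])
        }
        finding_sents <- c(finding_sents, fill_frame(frame, phrase))
      }
      for (cc in neg_cats) {
        phrase <- style_pick(templates$categories[[cc]], style[i])
        frame <- style_pick(templates$negation_frames, style[i])
        finding_sents <- c(finding_sents, fill_frame(frame, phrase))
      }
      # benign assertions ("preserved parenchymal volumes", ...) occur in
      # abnormal and normal reports alike, as in real reporting practice —
      # so assertion-frame vocabulary carries no class signal on its own
      n_benign <- stats::rbinom(1L, 2L, 0.35)
      for (bb in seq_len(n_benign)) {
        phrase <- style_pick(templates$benign_phrases, style[i])
        frame <- style_pick(templates$positive_frames, style[i])
        finding_sents <- c(finding_sents, fill_frame(frame, phrase))
      }
      if (length(finding_sents) > 1L) {
        finding_sents <- sample(finding_sents)
      }

      conclusion <- style_pick(templates$conclusion_sentences, style[i])
      mandatory <- length(finding_sents) + 1L
      target <- sample(seq(max(5L, mandatory), 10L), 1L)
      head_sents <- character(0)
      room <- target - mandatory
      if (room > 0L && stats::runif(1) < 0.35 + 0.1 * style[i]) {
        head_sents <- c(head_sents, style_pick(templates$history_sentences, style[i]))
        room <- room - 1L
      }
      if (room > 0L && stats::runif(1) < 0.4) {
        head_sents <- c(head_sents, style_pick(templates$protocol_sentences, style[i]))
        room <- room - 1L
      }
      fillers <- if (room > 0L) style_pick(templates$normal_sentences, style[i], room) else character(0)
      sents <- c(head_sents, finding_sents, fillers, conclusion)
      n_sent[i] <- length(sents)
      text[i] <- paste(sents, collapse = " ")
    }

    reports <- data.frame(report_id = report_id, patient_id = patient,
                          site_id = site, style_id = style, text = text,
                          stringsAsFactors = FALSE)
    labels <- data.frame(report_id = report_id, abnormal = as.integer(abnormal),
                         stringsAsFactors = FALSE)
    for (cc in cats) labels[[cc]] <- lab[, cc]
    labels$provenance <- "report"
    meta <- data.frame(report_id = report_id, negated = negated,
                       n_sentences = n_sent, stringsAsFactors = FALSE)
    structure(list(reports = reports, labels = labels, meta = meta,
                   config = config), class = "report_corpus")
  })
}

#' @export
print.report_corpus <- function(x, ...) {
  n <- nrow(x$reports)
  cat(sprintf("<report_corpus> %d reports, %d patients, %d sites\n",
              n, length(unique(x$reports$patient_id)),
              length(unique(x$reports$site_id))))
  if (n > 0) {
    cat(sprintf("  abnormal: %d (%.1f%%)\n", sum(x$labels$abnormal),
                100 * mean(x$labels$abnormal)))
    cat(sprintf("  example: %s\n", substr(x$reports$text[1], 1, 70)))
  }
  invisible(x)
}

#' Write / read a report corpus
#'
#' Corpora are exchanged as UTF-8 JSON-lines (one object per report, label
#' columns inlined) or as a flat CSV with columns report_id, patient_id,
#' site_id, style_id, text and the eight label columns.
#'
#' @param corpus A `report_corpus` (or a list with `reports` and `labels`
#'   data frames).
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`; inferred from the extension when
#'   missing.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` returns a
#'   `report_corpus`.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  flat <- merge(corpus$reports, corpus$labels[, c("report_id", label_columns())],
                by = "report_id", sort = FALSE)
  flat <- flat[order(flat$report_id), , drop = FALSE]
  if (format == "csv") {
    utils::write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(flat))) {
      writeLines(jsonlite::toJSON(as.list(flat[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA),
                 con, useBytes = TRUE)
    }
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  flat <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  } else {
    rows <- lapply(readLines(path, encoding = "UTF-8"), function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  reports <- flat[, c("report_id", "patient_id", "site_id", "style_id", "text")]
  labels <- flat[, c("report_id", label_columns())]
  labels$provenance <- "report"
  structure(list(reports = reports, labels = labels, meta = NULL, config = NULL),
            class = "report_corpus")
}

#' Construct a multi-rater count matrix
#'
#' @param counts An N x k integer matrix: `counts[i, j]` raters assigned
#'   subject i to category j.
#' @param n_raters Number of raters r; every row must sum to r.
#' @return An object of class `rater_matrix`.
#' @export
rater_matrix <- function(counts, n_raters) {
  counts <- as.matrix(counts)
  n_raters <- assert_count(n_raters, "n_raters", positive = TRUE)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  if (!all(rowSums(counts) == n_raters)) {
    stop("every row of `counts` must sum to `n_raters`", call. = FALSE)
  }
  structure(list(counts = counts, n_raters = n_raters), class = "rater_matrix")
}

#' @export
print.rater_matrix <- function(x, ...) {
  cat(sprintf("<rater_matrix> %d subjects x %d categories, %d raters\n",
              nrow(x$counts), ncol(x$counts), x$n_raters))
  invisible(x)
}

#' Simulate independent rater annotations
#'
#' Each of `n_raters` raters reports a subject's true category with
#' probability `1 - disagreement_rate`, and otherwise draws uniformly from
#' all `k` categories (so an "error" can still land on the truth). With
#' `disagreement_rate = 0` every row is concentrated in one category.
#'
#' @param truth True category per subject: a character/factor vector, or a
#'   corpus `labels` data frame combined with `category` (the subject is then
#'   `category` vs `no_<category>`).
#' @param n_raters Number of raters (>= 2).
#' @param disagreement_rate Per-rating probability of deviating from truth.
#' @param seed Integer seed.
#' @param category Label column used when `truth` is a labels data frame.
#' @return A [rater_matrix()].
#' @export
#' @examples
#' m <- generate_rater_annotations(c("a", "b", "a"), n_raters = 3,
#'                                 disagreement_rate = 0, seed = 1)
#' m$counts
generate_rater_annotations <- function(truth, n_raters, disagreement_rate,
                                       seed = 1L, category = "abnormal") {
  if (is.data.frame(truth)) {
    if (!category %in% names(truth)) {
      stop(sprintf("label column `%s` not found", category), call. = FALSE)
    }
    truth <- ifelse(truth[[category]] == 1, category, paste0("no_", category))
  }
  truth <- as.character(truth)
  if (length(truth) == 0L) stop("`truth` must be non-empty", call. = FALSE)
  n_raters <- assert_count(n_raters, "n_raters", positive = TRUE)
  if (n_raters < 2L) stop("`n_raters` must be at least 2", call. = FALSE)
  assert_probability(disagreement_rate, "disagreement_rate")

  levels <- sort(unique(truth))
  k <- length(levels)
  n <- length(truth)
  with_seed(seed, {
    counts <- matrix(0L, n, k, dimnames = list(NULL, levels))
    true_j <- match(truth, levels)
    for (r in seq_len(n_raters)) {
      err <- stats::runif(n) < disagreement_rate
      pick <- true_j
      if (any(err)) pick[err] <- sample.int(k, sum(err), replace = TRUE)
      counts[cbind(seq_len(n), pick)] <- counts[cbind(seq_len(n), pick)] + 1L
    }
    rater_matrix(counts, n_raters)
  })
}
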