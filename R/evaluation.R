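# Evaluation protocol: patient-level splitting with an image-label hold-out,
# ROC/threshold metrics with repeated-split confidence intervals, DeLong
# tests for correlated ROC curves, Fleiss' kappa, and 2-D embedding export.

#' Patient-level train/validation/test split
#'
#' Assigns every patient — and therefore every one of their reports — to
#' exactly one of train/validation/test, after excluding hold-out patients
#' (those with reference-standard image labels). Splitting at the patient
#' level prevents data leakage from patients with multiple reports.
#' Report-count fractions match the targets to within one patient group.
#'
#' @param corpus A `report_corpus` or reports data frame
#'   (`report_id`, `patient_id`).
#' @param fractions Train/validation/test report fractions; must sum to 1.
#' @param holdout Patient ids to mark `excluded` (must be corpus patients).
#' @param seed Integer seed; same seed, same split.
#' @return A `split_spec`: data frame (`patient_id`, `bucket`) with
#'   attribute `seed`.
#' @export
#' @examples
#' corp <- generate_corpus(generator_config(30, seed = 3))
#' sp <- patient_level_split(corp, seed = 1)
#' table(sp$bucket)
patient_level_split <- function(corpus, fractions = c(0.6, 0.2, 0.2),
                                holdout = character(0), seed = 1L) {
  reports <- if (inherits(corpus, "report_corpus")) corpus$reports else corpus
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be three numbers summing to 1", call. = FALSE)
  }
  patients <- unique(reports$patient_id)
  if (!all(holdout %in% patients)) {
    stop("`holdout` contains patients not present in the corpus", call. = FALSE)
  }
  pool <- setdiff(patients, holdout)
  sizes <- table(reports$patient_id)[pool]
  total <- sum(sizes)
  spec <- with_seed(seed, {
    ord <- sample(seq_along(pool))
    bucket <- character(length(pool))
    cum <- 0
    t1 <- fractions[1] * total
    t2 <- (fractions[1] + fractions[2]) * total
    for (i in ord) {
      bucket[i] <- if (cum < t1) "train" else if (cum < t2) "val" else "test"
      cum <- cum + sizes[i]
    }
    data.frame(patient_id = c(pool, holdout),
               bucket = c(bucket, rep("excluded", length(holdout))),
               stringsAsFactors = FALSE)
  })
  attr(spec, "seed") <- as.integer(seed)
  class(spec) <- c("split_spec", "data.frame")
  spec
}

#' Partition a corpus by a split
#'
#' @param corpus A `report_corpus`.
#' @param split A [patient_level_split()] result.
#' @return Named list of `report_corpus` objects
#'   (`train`, `val`, `test`, `excluded`).
#' @export
split_corpus <- function(corpus, split) {
  parts <- corpus_parts(corpus)
  bucket <- split$bucket[match(parts$reports$patient_id, split$patient_id)]
  out <- lapply(c(train = "train", val = "val", test = "test",
                  excluded = "excluded"), function(b) {
    subset_corpus(corpus, parts$reports$report_id[!is.na(bucket) & bucket == b])
  })
  out
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = P(score+ > score-) + 0.5 P(score+ = score-)`, computed from
#' midranks; identical to exhaustive enumeration over all
#' positive-negative pairs.
#'
#' @param scores Numeric classifier scores.
#' @param labels 0/1 (or logical) labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  if (m == 0L || n == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

#' Threshold classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, balanced accuracy
#' (their mean) and `F1 = 2TP/(2TP+FP+FN)` at an operating threshold
#' (default 0.5; a prediction is positive when `score >= threshold`).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes required.
#' @param threshold Operating point.
#' @return Named list: `balanced_accuracy`, `sensitivity`, `specificity`,
#'   `f1`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("metrics undefined: both classes must be present", call. = FALSE)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens,
       specificity = spec,
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
}

#' Youden-J operating threshold
#'
#' The candidate threshold maximising `sensitivity + specificity - 1`;
#' intended to be chosen on validation scores only.
#'
#' @param scores,labels Validation scores and 0/1 labels.
#' @return A threshold value.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(th) {
    m <- classification_metrics(scores, labels, th)
    m$sensitivity + m$specificity - 1
  }, numeric(1))
  cand[which.max(j)]
}

# Mid-rank placement values V10 (per positive) and V01 (per negative);
# the structural components of the Mann-Whitney statistic.
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for a difference between two AUCs
#'
#' Paired mode compares two score vectors over the *same* cases using the
#' structural-component covariance of the two Mann-Whitney statistics;
#' unpaired mode compares AUCs measured on independent test sets, summing
#' the two independent variances. Two-sided p from the normal reference.
#'
#' @param scores_a,scores_b Classifier scores.
#' @param labels Labels for both vectors in paired mode; labels for
#'   `scores_a` in unpaired mode.
#' @param labels_b Labels for `scores_b` (unpaired mode only).
#' @param mode `"paired"` or `"unpaired"`.
#' @return List: `delta_auc` (`auc_a - auc_b`), `auc_a`, `auc_b`, `z`, `p`.
#' @export
#' @examples
#' s <- c(0.9, 0.7, 0.3, 0.2); y <- c(1, 1, 0, 0)
#' delong_test(s, s, y)$p  # identical scores: p = 1
delong_test <- function(scores_a, scores_b, labels,
                        mode = c("paired", "unpaired"), labels_b = NULL) {
  mode <- match.arg(mode)
  labels <- as.integer(labels)
  if (mode == "paired") {
    if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
      stop("paired mode needs both score vectors over the same cases",
           call. = FALSE)
    }
    if (!any(labels == 1L) || !any(labels == 0L)) {
      stop("both classes must be present", call. = FALSE)
    }
    pa <- delong_placements(scores_a, labels)
    pb <- delong_placements(scores_b, labels)
    m <- length(pa$v10); n <- length(pa$v01)
    s10 <- stats::var(cbind(pa$v10, pb$v10))
    s01 <- stats::var(cbind(pa$v01, pb$v01))
    v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
         (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
    auc_a <- pa$auc; auc_b <- pb$auc
  } else {
    if (is.null(labels_b)) {
      stop("unpaired mode needs `labels_b`", call. = FALSE)
    }
    labels_b <- as.integer(labels_b)
    pa <- delong_placements(scores_a, labels)
    pb <- delong_placements(scores_b, labels_b)
    v <- stats::var(pa$v10) / length(pa$v10) + stats::var(pa$v01) / length(pa$v01) +
         stats::var(pb$v10) / length(pb$v10) + stats::var(pb$v01) / length(pb$v01)
    auc_a <- pa$auc; auc_b <- pb$auc
  }
  delta <- auc_a - auc_b
  if (v <= 0) {
    if (abs(delta) < .Machine$double.eps^0.5) {
      return(list(delta_auc = 0, auc_a = auc_a, auc_b = auc_b, z = 0, p = 1))
    }
    stop("degenerate variance: zero estimated variance with non-zero delta AUC",
         call. = FALSE)
  }
  z <- delta / sqrt(v)
  list(delta_auc = delta, auc_a = auc_a, auc_b = auc_b, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Fleiss' kappa for multi-rater agreement
#'
#' `kappa = (Pbar - Pe) / (1 - Pe)` with per-subject agreement
#' `P_i = (sum_j n_ij^2 - r) / (r (r - 1))`, category proportions
#' `p_j = sum_i n_ij / (N r)` and chance agreement `Pe = sum_j p_j^2`.
#'
#' @param m A [rater_matrix()] or an N x k count matrix (rows sum to the
#'   number of raters).
#' @param n_raters Required when `m` is a plain matrix.
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' fleiss_kappa(rater_matrix(rbind(c(2, 0), c(0, 2)), 2))  # 1
fleiss_kappa <- function(m, n_raters = NULL) {
  if (inherits(m, "rater_matrix")) {
    counts <- m$counts
    r <- m$n_raters
  } else {
    counts <- as.matrix(m)
    r <- n_raters %||% unique(rowSums(counts))
    if (length(r) != 1L) {
      stop("rows must all sum to the same number of raters", call. = FALSE)
    }
  }
  if (r < 2L) stop("at least 2 raters required", call. = FALSE)
  if (nrow(counts) < 2L) stop("at least 2 subjects required", call. = FALSE)
  N <- nrow(counts)
  p_j <- colSums(counts) / (N * r)
  pe <- sum(p_j^2)
  if (1 - pe < .Machine$double.eps^0.5) {
    stop("kappa undefined: all ratings fall in a single category", call. = FALSE)
  }
  p_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  (mean(p_i) - pe) / (1 - pe)
}

#' Export 2-D coordinates of pooled report embeddings
#'
#' Reduces pooled report vectors to two dimensions for visual inspection of
#' class structure. The reduction itself is delegated to established
#' implementations: principal components (`stats::prcomp`, default) or
#' classical multidimensional scaling (`stats::cmdscale`). Both are
#' deterministic for a fixed input and seed.
#'
#' @param embeddings Numeric matrix, one row per report (>= 3 rows).
#' @param labels Optional label per report, carried into the output.
#' @param method `"pca"` or `"mds"`.
#' @param seed Kept for interface stability across reduction back ends.
#' @return Data frame with columns `x`, `y` and `label`.
#' @export
export_2d_embeddings <- function(embeddings, labels = NULL,
                                 method = c("pca", "mds"), seed = 1L) {
  X <- as.matrix(embeddings)
  if (nrow(X) < 3L) stop("need at least 3 report vectors", call. = FALSE)
  method <- match.arg(method)
  xy <- with_seed(seed, {
    if (method == "pca") {
      # constant columns carry no variance; guard scale-free prcomp
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
      k <- ncol(pc$x)
      cbind(pc$x[, 1], if (k >= 2) pc$x[, 2] else rep(0, nrow(X)))
    } else {
      d <- stats::dist(X)
      stats::cmdscale(d, k = 2)
    }
  })
  data.frame(x = xy[, 1], y = xy[, 2],
             label = if (is.null(labels)) NA else labels)
}

#' Repeated patient-level evaluation with a fixed image-label hold-out
#'
#' Repeats the 60/20/20 patient-level split `n_repeats` times; for each
#' repeat a classifier is trained on the train/validation parts and
#' evaluated on (i) the repeat's report-label test set and (ii) the fixed
#' hold-out set carrying reference-standard image labels, which never
#' changes across repeats. Metric means are summarised with normal 95%
#' confidence half-widths `1.96 sd / sqrt(n_repeats)`.
#'
#' @param corpus Report-label corpus (reports + labels).
#' @param category Label column to model.
#' @param holdout A corpus whose labels play the role of image labels; its
#'   patients must be disjoint from `corpus` (leakage error otherwise).
#' @param n_repeats Number of repeated splits (default 10).
#' @param hp [hyperparams()] for each repeat's training run.
#' @param threshold Operating threshold, or `"youden"` (chosen on
#'   validation).
#' @param seed Base seed; repeat r uses a seed derived from it.
#' @param ... Architecture arguments passed to [train_model()].
#' @return A `metrics_summary`: list with `per_repeat` (one row per repeat
#'   and test set), `summary` (mean + `ci_halfwidth` per metric; half-width
#'   `NA` when `n_repeats = 1`), `holdout_ids`, `n_repeats`. The `summary`
#'   carries metadata noting that the interval is a normal-approximation
#'   95% CI of the mean.
#' @export
repeated_evaluation <- function(corpus, category = "abnormal", holdout,
                                n_repeats = 10L, hp = hyperparams(),
                                threshold = 0.5, seed = 1L, ...) {
  parts <- corpus_parts(corpus)
  hold <- corpus_parts(holdout)
  overlap <- intersect(parts$reports$patient_id, hold$reports$patient_id)
  if (length(overlap) > 0L) {
    stop(sprintf("data leakage: %d hold-out patient(s) also in the corpus",
                 length(overlap)), call. = FALSE)
  }
  n_repeats <- assert_count(n_repeats, "n_repeats", positive = TRUE)
  y_hold <- hold$labels[[category]][match(hold$reports$report_id,
                                          hold$labels$report_id)]
  rows <- list()
  for (r in seq_len(n_repeats)) {
    sp <- patient_level_split(parts$reports, seed = derive_seed(seed, 300L + r))
    sets <- split_corpus(corpus, sp)
    hp_r <- hp
    hp_r$seed <- derive_seed(hp$seed, 400L + r)
    model <- train_model(sets$train, sets$val, category = category,
                         hp = hp_r, ...)
    th <- threshold
    if (identical(threshold, "youden")) {
      val_scores <- predict_proba(model, sets$val$reports$text)
      y_val <- sets$val$labels[[category]][match(sets$val$reports$report_id,
                                                 sets$val$labels$report_id)]
      th <- youden_threshold(val_scores, y_val)
    }
    eval_one <- function(set_name, reports, labels_y) {
      scores <- predict_proba(model, reports$text)
      m <- classification_metrics(scores, labels_y, th)
      data.frame(repeat_id = r, test_set = set_name,
                 auc = roc_auc(scores, labels_y),
                 balanced_accuracy = m$balanced_accuracy,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 f1 = m$f1)
    }
    y_test <- sets$test$labels[[category]][match(sets$test$reports$report_id,
                                                 sets$test$labels$report_id)]
    rows[[length(rows) + 1L]] <- eval_one("report_label", sets$test$reports, y_test)
    rows[[length(rows) + 1L]] <- eval_one("image_label", hold$reports, y_hold)
  }
  per_repeat <- do.call(rbind, rows)
  metrics <- c("auc", "balanced_accuracy", "sensitivity", "specificity", "f1")
  summary <- do.call(rbind, lapply(unique(per_repeat$test_set), function(ts) {
    sub <- per_repeat[per_repeat$test_set == ts, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(mm) {
      v <- sub[[mm]]
      data.frame(test_set = ts, metric = mm, mean = mean(v),
                 ci_halfwidth = if (n_repeats > 1L) {
                   1.96 * stats::sd(v) / sqrt(n_repeats)
                 } else NA_real_)
    }))
  }))
  attr(summary, "interval") <- "normal-approximation 95% CI of the mean across repeats"
  structure(list(per_repeat = per_repeat, summary = summary,
                 holdout_ids = sort(hold$reports$report_id),
                 n_repeats = n_repeats, category = category),
            class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf("<metrics_summary> category '%s', %d repeat(s)\n", x$category,
              x$n_repeats))
  s <- x$summary
  for (ts in unique(s$test_set)) {
    sub <- s[s$test_set == ts, ]
    cat(sprintf("  %s: %s\n", ts,
                paste(sprintf("%s %.3f±%.3f", sub$metric, sub$mean,
                              sub$ci_halfwidth), collapse = "  ")))
  }
  invisible(x)
}

#' Write metrics as CSV / JSON
#' @param ms A `metrics_summary`.
#' @param path Output path; `.json` gives JSON, anything else CSV with the
#'   per-repeat rows followed by summary rows.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(ms, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(per_repeat = ms$per_repeat, summary = ms$summary,
                              n_repeats = ms$n_repeats,
                              interval = attr(ms$summary, "interval")),
                         path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(ms$per_repeat, path, row.names = FALSE)
    summary_path <- sub("(\\.[^.]*)?$", "_summary.csv", path)
    utils::write.csv(ms$summary, summary_path, row.names = FALSE)
  }
  invisible(path)
}
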