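# Synthetic corpus generator: determinism, calibration, label consistency,
# distant-negation soundness, rater simulation.

test_that("degenerate configurations behave as specified", {
  empty <- generate_corpus(generator_config(n_reports = 0, seed = 1))
  expect_equal(nrow(empty$reports), 0)
  expect_equal(nrow(empty$labels), 0)

  all_abn <- generate_corpus(generator_config(n_reports = 100,
                                              prevalence_abnormal = 1,
                                              seed = 7))
  expect_true(all(all_abn$labels$abnormal == 1))

  expect_error(generator_config(n_reports = 10, prevalence_abnormal = 1.4),
               "probability")
  expect_error(generator_config(n_reports = 10, n_patients = 20),
               "n_patients")
  expect_error(generator_config(n_reports = 10,
                                mean_granular_per_abnormal = 0.5))
})

test_that("the same config yields a byte-identical corpus", {
  cfg <- generator_config(n_reports = 80, seed = 123)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$reports, b$reports)
  expect_identical(a$labels, b$labels)
  tmp1 <- tempfile(fileext = ".jsonl"); tmp2 <- tempfile(fileext = ".jsonl")
  write_corpus(a, tmp1); write_corpus(b, tmp2)
  expect_identical(readBin(tmp1, "raw", file.size(tmp1)),
                   readBin(tmp2, "raw", file.size(tmp2)))
})

test_that("empirical prevalence recovers the configured values within 3 binomial SDs", {
  cfg <- generator_config(n_reports = 2000, prevalence_abnormal = 0.5, seed = 1)
  corp <- generate_corpus(cfg)
  n <- cfg$n_reports
  n_abn <- sum(corp$labels$abnormal)
  expect_lt(abs(n_abn - n * 0.5), 3 * sqrt(n * 0.25))
  for (cc in granular_categories()) {
    p <- cfg$prevalence[[cc]]
    expect_lt(abs(sum(corp$labels[[cc]]) - n * p), 3 * sqrt(n * p * (1 - p)))
  }
})

test_that("granular co-occurrence matches the published shape (mean 1.56, max 5, mode 1)", {
  cfg <- generator_config(n_reports = 4200, prevalence_abnormal = 1,
                          mean_granular_per_abnormal = 1.56, seed = 5)
  corp <- generate_corpus(cfg)
  k <- rowSums(corp$labels[, granular_categories()])
  expect_gte(length(k), 2000)
  expect_gte(mean(k), 1.46)
  expect_lte(mean(k), 1.66)
  expect_lte(max(k), 5)
  expect_gte(min(k), 1)
  expect_equal(as.integer(names(which.max(table(k)))), 1L)  # mode = 1
})

test_that("no granular label ever occurs with abnormal = 0", {
  corp <- tiny_corpus(n = 400, seed = 11)
  k <- rowSums(corp$labels[, granular_categories()])
  expect_true(all(corp$labels$abnormal[k > 0] == 1))
})

test_that("distant-negated findings appear in the text with the label false", {
  tpl <- report_templates()
  corp <- tiny_corpus(n = 300, seed = 13, distant_negation_rate = 0.6)
  negated <- strsplit(corp$meta$negated, ",", fixed = TRUE)
  n_checked <- 0
  for (i in seq_len(nrow(corp$reports))) {
    for (cc in negated[[i]]) {
      if (!nzchar(cc)) next
      # label bit is false and some phrasing of the category is present
      expect_equal(corp$labels[[cc]][i], 0L)
      hit <- any(vapply(tpl$categories[[cc]], grepl,
                        x = corp$reports$text[i], fixed = TRUE, TRUE))
      expect_true(hit)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 50)
})

test_that("reports are 5-10 sentences with multiple reports per patient", {
  corp <- tiny_corpus(n = 500, seed = 17)
  expect_true(all(corp$meta$n_sentences >= 5 & corp$meta$n_sentences <= 10))
  sizes <- table(corp$reports$patient_id)
  expect_gt(max(sizes), 1)        # some patients own several reports
  expect_lte(max(sizes), 6)
  n_pat <- length(sizes)
  expect_lt(n_pat, 500)
})

test_that("explicit n_patients is honoured", {
  corp <- generate_corpus(generator_config(n_reports = 60, n_patients = 25,
                                           seed = 3))
  expect_equal(length(unique(corp$reports$patient_id)), 25)
  expect_equal(nrow(corp$reports), 60)
})

test_that("corpus round-trips through jsonl and csv", {
  corp <- tiny_corpus(n = 25, seed = 19)
  for (ext in c(".jsonl", ".csv")) {
    tmp <- tempfile(fileext = ext)
    write_corpus(corp, tmp)
    back <- read_corpus(tmp)
    expect_equal(back$reports$text, corp$reports$text)
    expect_equal(back$labels$abnormal, corp$labels$abnormal)
    expect_equal(back$labels$mass, corp$labels$mass)
  }
})

test_that("rater simulation obeys its contracts", {
  truth <- rep(c("a", "b"), 10)
  m0 <- generate_rater_annotations(truth, n_raters = 4, disagreement_rate = 0,
                                   seed = 1)
  expect_true(all(rowSums(m0$counts) == 4))
  expect_true(all(apply(m0$counts, 1, max) == 4))  # concentrated rows

  expect_error(generate_rater_annotations(truth, n_raters = 1,
                                          disagreement_rate = 0), "at least 2")

  # forced-disagreement limit: each rating is uniform over the 2 categories,
  # so E[per-row max of 2 raters] = 2 * P(agree) + 1 * P(split) = 1.5
  m1 <- generate_rater_annotations(rep(c("a", "b"), 250), n_raters = 2,
                                   disagreement_rate = 1, seed = 2)
  expect_lt(abs(mean(apply(m1$counts, 1, max)) - 1.5), 0.1)
})

test_that("labels data frame feeds the rater simulator", {
  corp <- tiny_corpus(n = 40, seed = 23)
  m <- generate_rater_annotations(corp$labels, n_raters = 3,
                                  disagreement_rate = 0.2, seed = 4,
                                  category = "abnormal")
  expect_equal(nrow(m$counts), 40)
  expect_true(all(rowSums(m$counts) == 3))
})
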