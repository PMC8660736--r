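# radlabel

Deriving dataset labels from free-text neuroradiology reports — and testing
those labels the hard way.

Training computer-vision models on head MRI examinations needs tens of
thousands of labelled scans, but expert labelling of MRI is slow and
expensive. A practical alternative is to classify the *radiology reports*
and assign the resulting labels to the corresponding examinations.
`radlabel` implements that workflow end-to-end for one binary `abnormal`
label plus seven specialised abnormality categories (acute stroke, mass,
atrophy, vascular, small vessel disease, white matter inflammation,
encephalomalacia), together with the evaluation machinery needed to trust
the result: patient-level repeated splits, a fixed image-label hold-out,
DeLong tests for correlated ROC curves, Fleiss' kappa for rater agreement,
and corpus lexical statistics.

## The model

For each category *c* a classifier maps a report to
P(report describes *c*):

1. a transformer **encoder** turns integer token ids into contextual
   vectors `h_1 … h_T` (a pretrained biomedical encoder at full scale; a
   small randomly initialised encoder at desk scale);
2. **attention pooling** scores each token, `s_i = vᵀ tanh(W h_i + b)`,
   normalises `α = softmax(s)` over non-padding tokens, and forms the
   report vector `r = Σ α_i h_i` (the `α_i` double as word-level
   interpretability);
3. a **single-hidden-layer head** outputs `p = σ(w₂ᵀ relu(W₁ r + b₁) + b₂)`.

All three stages are trained end-to-end on binary cross-entropy with Adam;
after each epoch a checkpoint is saved and the one with the lowest
validation loss is kept. Eight models are trained, one per category.
The comparison baseline is a logistic regression on mean static
(context-independent) word embeddings plus N-gram counts (N = 1, 2, 3) —
exactly the kind of model that cannot resolve a distant negation such as
"there are no features in either hemisphere suggestive of acute stroke".

Because hospital report corpora cannot be redistributed, the package ships
a seeded synthetic-corpus generator reproducing the structure that matters:
5–10 sentence reports, several reporter styles, multiple reports per
patient, 8 binary labels with a calibrated mean of 1.56 granular labels
per abnormal report (max 5, mode 1), and distant-negation mentions of
absent findings.

## Worked example

```r
library(radlabel)

# a 300-report synthetic corpus, 30% of reports with distant negation
cfg  <- generator_config(n_reports = 300, seed = 42)
corp <- generate_corpus(cfg)
corp
#> <report_corpus> 300 reports, 161 patients, 1 sites
#>   abnormal: 160 (53.3%)
#>   example: the appearances do raise concern for progressive cortical atrophy . th

# patient-level 60/20/20 split, then train a desk-scale abnormal classifier
sp   <- patient_level_split(corp, seed = 1)
sets <- split_corpus(corp, sp)
model <- train_model(sets$train, sets$val, category = "abnormal",
                     hp = hyperparams(learning_rate = 1e-3, max_epochs = 6,
                                      seed = 1),
                     max_len = 128, n_layers = 1)

y_test <- sets$test$labels$abnormal[match(sets$test$reports$report_id,
                                          sets$test$labels$report_id)]
scores <- predict_proba(model, sets$test$reports$text)
roc_auc(scores, y_test)
#> [1] 0.9803241
classification_metrics(scores, y_test, threshold = 0.5)$balanced_accuracy
#> [1] 0.931713

# which words did the model weight most?
a <- attention_report(sets$test$reports$text[1], model, drop_special = TRUE)
head(a[order(-a$weight), ], 3)
#>     token     weight
#> 29 change 0.03242720
#> 25     to 0.03191833
#> 23   such 0.03037896
```

A test AUC of 0.98 from a 180-report training set says the desk-scale
model has learned the finding/negation structure rather than memorised it;
the attention table shows weight concentrating inside the assertion
sentence ("… is such as to suggest … change") rather than on boilerplate.
Lexical statistics follow the frequency-spectrum formulas:

```r
lexical_metrics(frequency_spectrum("a b a"))
#> $ttr        [1] 0.6666667   # 2 types / 3 tokens
#> $yule_i     [1] 1.333333    # M1^2 / (M2 - M1) = 4 / 3
#> $unique_per_report [1] 2
```

A command-line interface wrapping the same functions
(`generate`, `train`, `evaluate`, `label`, `lexstats`, `agreement`) ships
in `inst/cli/radlabel.R`.

## Package layout

| Piece | Where |
|---|---|
| Synthetic corpus + rater simulation | `R/corpus_synth.R`, templates in `inst/extdata/` |
| Tokenizer and vocabularies | `R/preprocess.R` |
| Encoder, attention pooling, head (+ hand-verified gradients) | `R/nn_layers.R`, `R/model.R` |
| Training loop with checkpoint selection | `R/training.R` |
| Mean-embedding + N-gram baseline | `R/baseline.R` |
| Splits, metrics, DeLong, kappa, 2-D export | `R/evaluation.R` |
| Lexical statistics | `R/lexical.R` |
| Batch labelling + CLI plumbing | `R/pipeline.R`, `inst/cli/radlabel.R` |

The methods vignette (`vignettes/radlabel-methods.Rmd`) documents the
model, the generator's assumptions and limits, and every numerically
consequential design choice.
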