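#' Granular abnormality categories
#'
#' The seven specialised neuroradiological abnormality categories handled by
#' the package, in canonical column order. Together with the overall
#' `abnormal` flag they make up the eight binary labels attached to every
#' report.
#'
#' @return Character vector of the seven category names.
#' @export
#' @examples
#' granular_categories()
granular_categories <- function() {
  c("acute_stroke", "mass", "atrophy", "vascular",
    "small_vessel_disease", "white_matter_inflammation", "encephalomalacia")
}

#' All label columns (abnormal + granular)
#' @return Character vector of the eight label column names.
#' @export
label_columns <- function() {
  c("abnormal", granular_categories())
}

#' Sentence-template inventory for the synthetic corpus generator
#'
#' Loads the versioned template file shipped with the package: finding
#' phrasings per category (>= 5 each), positive/hedged assertion frames,
#' distant-negation frames (negator separated from the finding phrase by at
#' least three tokens), and filler sentences (normal anatomy, clinical
#' history, protocol, conclusion). Frames contain a `{finding}` placeholder.
#'
#' @param path Optional path to an alternative template JSON file.
#' @return A list with elements `categories`, `benign_phrases`,
#'   `positive_frames`, `negation_frames`, `hedge_frames`,
#'   `normal_sentences`, `history_sentences`, `protocol_sentences`,
#'   `conclusion_sentences` and `version`.
#' @export
report_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "report_templates.json", package = "radlabel")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("template file not found", call. = FALSE)
  }
  tpl <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  stopifnot(all(granular_categories() %in% names(tpl$categories)))
  tpl
}

fill_frame <- function(frame, finding) {
  gsub("{finding}", finding, frame, fixed = TRUE)
}
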