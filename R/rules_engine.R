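#' Hierarchical AS classification
#'
#' The engine combines both evidence channels per study under a strict
#' hierarchy: the reading echocardiographer's written interpretation is
#' definitionally the true severity class, so a qualitative severity mention
#' (or an explicit textual denial of stenosis, which classifies as grade
#' none) always supplies the final grade. Only when the text carries no
#' qualitative AS signal does the quantitative grade (AVA-first, see
#' [grade_quantitative()]) become final. Both grades are always computed and
#' reported, together with a discordance flag, so every classification is
#' auditable.
#'
#' @name rules_engine
NULL

#' Classify one study
#'
#' @param study One-row study data frame or list (fields of the study
#'   table; see [cohort_io]).
#' @param finding A `qualitative_finding` for the study's report text, or
#'   `NULL` to extract it here with `lexicon`.
#' @param thresholds A validated `threshold_table`.
#' @param lexicon A `severity_lexicon`, used only when `finding` is `NULL`.
#' @return An `as_classification`: one-row data frame with `study_id`,
#'   `final_grade`, `source` (`"qualitative"`, `"quantitative"` or
#'   `"ungradeable"`), `qualitative_grade`, `quantitative_grade`,
#'   `quantitative_parameter`, `discordant`, `is_sas`, plus the NLP cue
#'   flags `leaflet_restriction` and `abnormal_gradient_comment`.
#' @examples
#' classify_study(list(study_id = "e1", report_text = "Severe aortic stenosis.",
#'                     ava_cm2 = 1.3),
#'                thresholds = default_thresholds(),
#'                lexicon = default_lexicon())
#' @export
classify_study <- function(study, finding = NULL,
                           thresholds = default_thresholds(),
                           lexicon = NULL) {
  if (is.null(finding)) {
    if (is.null(lexicon)) stop("supply either a finding or a lexicon")
    finding <- extract_findings(study[["report_text"]] %||% "", lexicon)
  }
  stopifnot(inherits(finding, "qualitative_finding"))

  qual <- if (isTRUE(finding$negated_as)) "none" else finding$severity_mention
  quant <- grade_quantitative(study, thresholds)

  if (!is.na(qual)) {
    final <- qual
    source <- "qualitative"
  } else if (!is.na(quant$grade)) {
    final <- quant$grade
    source <- "quantitative"
  } else {
    final <- NA_character_
    source <- "ungradeable"
  }
  discordant <- !is.na(qual) && !is.na(quant$grade) && qual != quant$grade

  out <- data.frame(
    study_id = as.character(study[["study_id"]] %||% NA_character_),
    final_grade = final,
    source = source,
    qualitative_grade = qual,
    quantitative_grade = quant$grade,
    quantitative_parameter = quant$parameter,
    discordant = discordant,
    is_sas = dichotomize(final),
    leaflet_restriction = isTRUE(finding$leaflet_restriction),
    abnormal_gradient_comment = isTRUE(finding$abnormal_gradient_comment),
    stringsAsFactors = FALSE
  )
  class(out) <- c("as_classification", class(out))
  out
}

#' Classify every study in a cohort
#'
#' Applies [extract_findings()] and [classify_study()] to each study and
#' tabulates the result. Studies should already have passed prosthetic
#' exclusion ([exclude_prosthetic()]).
#'
#' @param cohort An `echo_cohort`.
#' @param lexicon A `severity_lexicon`.
#' @param thresholds A validated `threshold_table`.
#' @return List with `classifications` (data frame, one row per study; see
#'   [classify_study()]) and `summary`: grade counts (including
#'   `ungradeable`), the number of discordant studies, and `n_sas`.
#' @export
classify_cohort <- function(cohort, lexicon = default_lexicon(),
                            thresholds = default_thresholds()) {
  stopifnot(inherits(cohort, "echo_cohort"))
  validate_thresholds(thresholds)
  s <- cohort$studies
  rows <- lapply(seq_len(nrow(s)), function(i) {
    classify_study(s[i, , drop = FALSE], finding = NULL,
                   thresholds = thresholds, lexicon = lexicon)
  })
  cls <- if (length(rows)) do.call(rbind, rows) else
    classify_study(list(study_id = "x"), finding = .empty_finding(),
                   thresholds = thresholds)[0, ]
  rownames(cls) <- NULL

  lv <- grade_levels()
  counts <- vapply(lv, function(g) sum(cls$final_grade %in% g), integer(1))
  counts <- c(counts, ungradeable = sum(is.na(cls$final_grade)))
  list(
    classifications = cls,
    summary = list(
      n_studies = nrow(cls),
      grade_counts = counts,
      n_discordant = sum(cls$discordant),
      n_sas = sum(cls$is_sas)
    )
  )
}

#' Grade-count summary table
#'
#' @param classifications Classification data frame from [classify_cohort()].
#' @return Data frame `grade`, `n`, `pct` (percent of gradeable studies,
#'   one decimal), mirroring the engine-grading rows of a cohort
#'   characteristics table.
#' @export
grade_count_table <- function(classifications) {
  lv <- grade_levels()
  n <- vapply(lv, function(g) sum(classifications$final_grade %in% g), integer(1))
  total <- sum(n)
  data.frame(grade = lv, n = unname(n),
             pct = if (total > 0) round(100 * unname(n) / total, 1) else rep(NA_real_, length(lv)),
             stringsAsFactors = FALSE)
}
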