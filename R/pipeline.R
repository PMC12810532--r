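#' End-to-end screening pipeline
#'
#' Chains ingest, prosthetic exclusion, per-patient study selection, NLP,
#' grading, classification, treatment-status assignment and the disparity
#' suite, writing every table plus a replayable run manifest. Stage counts
#' are conserved: studies in = excluded + classified.
#'
#' @param cohort_path Cohort input (directory of CSVs or a JSON-lines file).
#' @param output_dir Directory for artifacts (created if needed).
#' @param format Cohort format, `"csv"` or `"jsonl"`.
#' @param lexicon_path,thresholds_path Optional YAML configs; defaults to
#'   the shipped ones.
#' @param cutoff Follow-up cutoff date for treatment status.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed feeds optional downstream sampling).
#' @return Invisibly, a list with `classifications`, `statuses`,
#'   `disparity` (or `NULL` when the cohort cannot support it), `counts`
#'   and `manifest_path`.
#' @export
run_pipeline <- function(cohort_path, output_dir,
                         format = c("csv", "jsonl"),
                         lexicon_path = NULL, thresholds_path = NULL,
                         cutoff = as.Date("2024-06-10"), seed = 1L) {
  format <- match.arg(format)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "pipeline_log.txt")
  log_con <- file(log_path, open = "w")
  on.exit(close(log_con), add = TRUE)
  stage <- function(name, ...) {
    writeLines(paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "\t", name,
                      "\t", paste(..., collapse = " ")), log_con)
  }

  lexicon <- if (is.null(lexicon_path)) default_lexicon() else
    read_lexicon(lexicon_path)
  thresholds <- if (is.null(thresholds_path)) default_thresholds() else
    read_thresholds(thresholds_path)
  validate_thresholds(thresholds)

  cohort <- read_cohort(cohort_path, format)
  stage("ingest", "studies_in =", nrow(cohort$studies),
        "patients =", nrow(cohort$patients))

  text_flags <- vapply(cohort$studies$report_text, function(tx)
    detect_prosthetic(tx, lexicon), logical(1))
  names(text_flags) <- cohort$studies$study_id
  excl <- exclude_prosthetic(cohort, text_flags)
  stage("exclusions", "excluded =", nrow(excl$exclusions))
  utils::write.csv(excl$exclusions, file.path(output_dir, "exclusions.csv"),
                   row.names = FALSE)

  cohort <- select_latest_per_patient(excl$cohort)
  stage("latest_per_patient", "studies =", nrow(cohort$studies))

  res <- classify_cohort(cohort, lexicon, thresholds)
  cls <- res$classifications
  stage("classify", "classified =", nrow(cls), "sas =", res$summary$n_sas,
        "discordant =", res$summary$n_discordant)
  jl <- file.path(output_dir, "classifications.jsonl")
  con <- file(jl, open = "w"); on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(cls))) {
    writeLines(jsonlite::toJSON(as.list(cls[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  utils::write.csv(grade_count_table(cls),
                   file.path(output_dir, "grade_counts.csv"),
                   row.names = FALSE)

  disparity <- NULL
  statuses <- NULL
  if (nrow(cohort$studies)) {
    study_dates <- cohort$studies$study_date
    names(study_dates) <- cohort$studies$patient_id
    pts <- cohort$patients[cohort$patients$patient_id %in%
                             cohort$studies$patient_id, , drop = FALSE]
    statuses <- assign_treatment_status(pts, study_dates, cutoff)
    stage("treatment_status", "treated =", sum(statuses$treated))
    sas <- cls$is_sas
    names(sas) <- cohort$studies$patient_id[match(cls$study_id,
                                                  cohort$studies$study_id)]
    disparity <- tryCatch(
      run_disparity_suite(pts, statuses, sas),
      error = function(e) {
        stage("disparity_skipped", conditionMessage(e))
        NULL
      })
    if (!is.null(disparity)) {
      stage("disparity", "population =", nrow(disparity$population))
      utils::write.csv(disparity$univariate_treatment,
                       file.path(output_dir, "univariate_treatment.csv"),
                       row.names = FALSE)
      if (!is.null(disparity$univariate_modality)) {
        utils::write.csv(disparity$univariate_modality,
                         file.path(output_dir, "univariate_modality.csv"),
                         row.names = FALSE)
      }
      utils::write.csv(disparity$model_all$table,
                       file.path(output_dir, "model_all.csv"),
                       row.names = FALSE)
      if (!is.null(disparity$model_sdoh)) {
        utils::write.csv(disparity$model_sdoh$table,
                         file.path(output_dir, "model_sdoh.csv"),
                         row.names = FALSE)
      }
    }
  }

  counts <- list(
    studies_in = length(text_flags),
    excluded = nrow(excl$exclusions),
    after_exclusion = length(text_flags) - nrow(excl$exclusions),
    classified = nrow(cls),
    gradeable = sum(!is.na(cls$final_grade)),
    n_sas = res$summary$n_sas,
    n_treated = if (is.null(statuses)) 0L else sum(statuses$treated)
  )
  manifest <- list(
    tool = "echorules",
    version = as.character(utils::packageVersion("echorules")),
    subcommand = "run",
    inputs = list(cohort_path = cohort_path, format = format,
                  lexicon_path = lexicon_path,
                  thresholds_path = thresholds_path),
    cutoff = format(as.Date(cutoff), "%Y-%m-%d"),
    seed = seed,
    output_dir = output_dir,
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  stage("done", "artifacts in", output_dir)
  invisible(list(classifications = cls, statuses = statuses,
                 disparity = disparity, counts = counts,
                 manifest_path = manifest_path))
}
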