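#' Cohort files: record model, validation, I/O
#'
#' A cohort couples one table of transthoracic echo studies (free-text
#' conclusion plus the quantitative measures used for grading) with one
#' table of patients (demographics, insurance, neighbourhood SDoH, opt-out
#' flag, treatment events). The data dictionary is fixed: see
#' [empty_cohort()] for the exact field names and types. On disk a cohort is
#' either a directory of two CSVs (`studies.csv`, `patients.csv`; UTF-8,
#' header row, ISO-8601 dates, empty string = missing) or a single
#' JSON-lines file in which every record carries a `record_type` of
#' `"study"` or `"patient"`.
#'
#' @name cohort_io
NULL

.sex_levels <- c("male", "female", "other_unknown")
.race_levels <- c("White", "Asian", "Black", "NHPI", "AIAN", "Other", "Unknown")
.ethnicity_levels <- c("Hispanic", "Non-Hispanic", "Unknown")
.insurance_levels <- c("Private", "Medicare", "HMO", "MedicareAdvantage",
                       "Medicaid", "Unknown")
.modality_levels <- c("SAVR", "TAVR")

.study_cols <- c(study_id = "character", patient_id = "character",
                 study_date = "Date", report_text = "character",
                 ava_cm2 = "numeric", mean_gradient_mmhg = "numeric",
                 peak_velocity_ms = "numeric", lvef_pct = "numeric",
                 prosthetic_valve_structured = "logical")
.patient_cols <- c(patient_id = "character", age_years = "numeric",
                   sex = "character", race = "character",
                   ethnicity = "character", insurance = "character",
                   hpi_score = "numeric", hpi_percentile = "numeric",
                   opted_out = "logical", avr_date = "Date",
                   avr_modality = "character", carried_forward = "logical")

.typed_frame <- function(spec, n = 0L) {
  cols <- lapply(spec, function(tp) switch(tp,
    character = rep(NA_character_, n),
    numeric = rep(NA_real_, n),
    logical = rep(NA, n),
    Date = as.Date(rep(NA_character_, n))
  ))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Empty cohort skeleton
#'
#' @return An `echo_cohort` with zero studies and zero patients, carrying
#'   the full typed column set (the data dictionary).
#' @export
empty_cohort <- function() {
  as_cohort(.typed_frame(.study_cols), .typed_frame(.patient_cols))
}

#' Construct and validate a cohort
#'
#' @param studies Data frame of echo studies (see [cohort_io]).
#' @param patients Data frame of patient records.
#' @param validate Run invariant checks (default `TRUE`).
#' @return An `echo_cohort` (list with `studies` and `patients`).
#' @export
as_cohort <- function(studies, patients, validate = TRUE) {
  coerce <- function(df, spec, what) {
    missing_cols <- setdiff(names(spec), names(df))
    if (length(missing_cols)) {
      stop(what, " table missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    df <- df[names(spec)]
    for (nm in names(spec)) {
      df[[nm]] <- switch(spec[[nm]],
        character = as.character(df[[nm]]),
        numeric = as.numeric(df[[nm]]),
        logical = as.logical(df[[nm]]),
        Date = as.Date(df[[nm]])
      )
    }
    rownames(df) <- NULL
    df
  }
  x <- structure(list(
    studies = coerce(as.data.frame(studies), .study_cols, "studies"),
    patients = coerce(as.data.frame(patients), .patient_cols, "patients")
  ), class = "echo_cohort")
  if (validate) validate_cohort(x)
  x
}

#' Validate cohort invariants
#'
#' Checks uniqueness of identifiers, numeric ranges, enumeration membership,
#' the treatment-field pairing (modality present iff date present), and
#' referential integrity (every study resolves to exactly one patient).
#' All violations are collected and reported together with row-level
#' diagnostics.
#'
#' @param cohort An `echo_cohort`.
#' @return `TRUE` invisibly, or an error listing every violation.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "echo_cohort"))
  s <- cohort$studies
  p <- cohort$patients
  errs <- character(0)
  add <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      errs[[length(errs) + 1L]] <<- paste0(msg, " [rows: ",
        paste(utils::head(which(rows), 5L), collapse = ", "),
        if (sum(rows, na.rm = TRUE) > 5L) ", ..." else "", "]")
    }
    invisible(NULL)
  }

  dup <- duplicated(s$study_id)
  if (any(dup)) {
    errs[[length(errs) + 1L]] <- paste0("duplicated study_id: ",
      paste(unique(s$study_id[dup]), collapse = ", "))
  }
  add(is.na(s$study_id) | !nzchar(s$study_id), "studies: missing study_id")
  add(is.na(s$patient_id) | !nzchar(s$patient_id), "studies: missing patient_id")
  add(is.na(s$study_date), "studies: missing study_date")
  add(!is.na(s$ava_cm2) & s$ava_cm2 <= 0, "studies: ava_cm2 must be > 0 cm2")
  add(!is.na(s$mean_gradient_mmhg) & s$mean_gradient_mmhg < 0,
      "studies: mean_gradient_mmhg must be >= 0 mmHg")
  add(!is.na(s$peak_velocity_ms) & s$peak_velocity_ms < 0,
      "studies: peak_velocity_ms must be >= 0 m/s")
  add(!is.na(s$lvef_pct) & (s$lvef_pct < 0 | s$lvef_pct > 100),
      "studies: lvef_pct outside [0, 100]")
  add(is.na(s$prosthetic_valve_structured),
      "studies: prosthetic_valve_structured must be TRUE/FALSE")

  dupp <- duplicated(p$patient_id)
  if (any(dupp)) {
    errs[[length(errs) + 1L]] <- paste0("duplicated patient_id: ",
      paste(unique(p$patient_id[dupp]), collapse = ", "))
  }
  add(is.na(p$age_years) | p$age_years < 0, "patients: age_years must be >= 0")
  enum_check <- function(values, levels, field) {
    add(!is.na(values) & !values %in% levels,
        paste0("patients: unknown ", field, " value (allowed: ",
               paste(levels, collapse = "/"), ")"))
  }
  add(is.na(p$sex), "patients: missing sex")
  enum_check(p$sex, .sex_levels, "sex")
  enum_check(p$race, .race_levels, "race")
  enum_check(p$ethnicity, .ethnicity_levels, "ethnicity")
  enum_check(p$insurance, .insurance_levels, "insurance")
  enum_check(p$avr_modality, .modality_levels, "avr_modality")
  add(!is.na(p$hpi_percentile) & (p$hpi_percentile < 0 | p$hpi_percentile > 1),
      "patients: hpi_percentile outside [0, 1]")
  add(is.na(p$opted_out), "patients: opted_out must be TRUE/FALSE")
  add(is.na(p$carried_forward), "patients: carried_forward must be TRUE/FALSE")
  add(xor(is.na(p$avr_date), is.na(p$avr_modality)),
      "patients: avr_modality present iff avr_date present")

  orphan <- !s$patient_id %in% p$patient_id
  add(orphan, "studies: patient_id not found in patients table")

  if (length(errs)) {
    stop("cohort validation failed:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a cohort file
#'
#' @param path For `format = "csv"`, a directory containing `studies.csv`
#'   and `patients.csv`; for `format = "jsonl"`, a single JSON-lines file
#'   whose records carry `record_type` `"study"` or `"patient"`.
#' @param format `"csv"` or `"jsonl"`.
#' @return A validated `echo_cohort`. Missing optional fields are absent
#'   (`NA`), never zero.
#' @export
read_cohort <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    sf <- file.path(path, "studies.csv")
    pf <- file.path(path, "patients.csv")
    if (!file.exists(sf) || !file.exists(pf)) {
      stop("expected ", sf, " and ", pf)
    }
    raw_s <- utils::read.csv(sf, colClasses = "character", na.strings = "",
                             fileEncoding = "UTF-8")
    raw_p <- utils::read.csv(pf, colClasses = "character", na.strings = "",
                             fileEncoding = "UTF-8")
    # report_text may legitimately be the empty string
    if ("report_text" %in% names(raw_s)) {
      raw_s$report_text[is.na(raw_s$report_text)] <- ""
    }
    as_cohort(raw_s, raw_p)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    type <- vapply(recs, function(r) as.character(r$record_type %||% ""), character(1))
    if (any(!type %in% c("study", "patient"))) {
      stop("jsonl record without record_type study/patient")
    }
    bind <- function(recs, spec) {
      out <- .typed_frame(spec, length(recs))
      for (i in seq_along(recs)) {
        r <- recs[[i]]
        for (nm in names(spec)) {
          v <- r[[nm]]
          if (!is.null(v) && !(length(v) == 1L && is.na(v))) {
            out[[nm]][i] <- if (spec[[nm]] == "Date") as.Date(v) else v
          }
        }
      }
      out
    }
    as_cohort(bind(recs[type == "study"], .study_cols),
              bind(recs[type == "patient"], .patient_cols))
  }
}

#' Write a cohort file
#'
#' Inverse of [read_cohort()]: writing then reading reproduces a
#' semantically identical cohort (field-by-field equality after
#' canonicalization).
#'
#' @param cohort An `echo_cohort`.
#' @param path Output directory (`csv`) or file (`jsonl`).
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "echo_cohort"))
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    fmt <- function(df) {
      for (nm in names(df)) {
        if (inherits(df[[nm]], "Date")) df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
      }
      df
    }
    utils::write.csv(fmt(cohort$studies), file.path(path, "studies.csv"),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
    utils::write.csv(fmt(cohort$patients), file.path(path, "patients.csv"),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  } else {
    row_to_json <- function(df, i, type) {
      r <- as.list(df[i, , drop = FALSE])
      r <- lapply(r, function(v) {
        if (inherits(v, "Date")) v <- format(v, "%Y-%m-%d")
        if (length(v) == 1L && is.na(v)) NULL else v
      })
      r <- r[!vapply(r, is.null, logical(1))]
      jsonlite::toJSON(c(list(record_type = type), r), auto_unbox = TRUE,
                       digits = NA)
    }
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(cohort$studies))) {
      writeLines(row_to_json(cohort$studies, i, "study"), con)
    }
    for (i in seq_len(nrow(cohort$patients))) {
      writeLines(row_to_json(cohort$patients, i, "patient"), con)
    }
  }
  invisible(path)
}

#' Exclude prosthetic-valve studies
#'
#' Prosthetic aortic valves produce gradients not interpretable under
#' native-valve criteria, so such studies are removed before any
#' classification. A study is excluded when its structured prosthetic flag
#' is set or when the report text mentions a prosthesis (flags from
#' [detect_prosthetic()]). A study with neither flag is never removed.
#'
#' @param cohort An `echo_cohort`.
#' @param text_flags Named logical vector keyed by `study_id` (typically
#'   from the NLP channel); missing ids count as `FALSE`.
#' @return List with `cohort` (studies retained) and `exclusions`
#'   (data frame `study_id`, `reason`).
#' @export
exclude_prosthetic <- function(cohort, text_flags = logical(0)) {
  stopifnot(inherits(cohort, "echo_cohort"))
  s <- cohort$studies
  tf <- rep(FALSE, nrow(s))
  if (length(text_flags)) {
    hit <- match(s$study_id, names(text_flags))
    tf[!is.na(hit)] <- as.logical(text_flags[hit[!is.na(hit)]])
    tf[is.na(tf)] <- FALSE
  }
  structured <- s$prosthetic_valve_structured %in% TRUE
  drop <- structured | tf
  reason <- ifelse(structured & tf, "structured+text",
                   ifelse(structured, "structured", "text"))
  exclusions <- data.frame(study_id = s$study_id[drop],
                           reason = reason[drop],
                           stringsAsFactors = FALSE)
  out <- cohort
  out$studies <- s[!drop, , drop = FALSE]
  rownames(out$studies) <- NULL
  list(cohort = out, exclusions = exclusions)
}

#' Reduce to one study per patient
#'
#' Retains, for each patient, the study with the latest `study_date`; ties
#' are broken by the lexicographically greatest `study_id`, so the result is
#' deterministic and invariant to input row order. Output studies are sorted
#' by `study_id`.
#'
#' @param cohort An `echo_cohort`.
#' @return An `echo_cohort` with exactly one study per patient.
#' @export
select_latest_per_patient <- function(cohort) {
  stopifnot(inherits(cohort, "echo_cohort"))
  s <- cohort$studies
  if (nrow(s) > 1L) {
    ord <- order(s$patient_id, s$study_date, s$study_id)
    s <- s[ord, , drop = FALSE]
    keep <- !duplicated(s$patient_id, fromLast = TRUE)
    s <- s[keep, , drop = FALSE]
  }
  s <- s[order(s$study_id), , drop = FALSE]
  rownames(s) <- NULL
  out <- cohort
  out$studies <- s
  out
}

#' @export
print.echo_cohort <- function(x, ...) {
  cat("Echo cohort:", nrow(x$studies), "studies,",
      nrow(x$patients), "patients\n")
  if (nrow(x$studies)) {
    cat("  study dates:", format(min(x$studies$study_date)), "to",
        format(max(x$studies$study_date)), "\n")
  }
  invisible(x)
}
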