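#' Treatment-status and disparity analyses
#'
#' Downstream of classification, each patient is dichotomized by whether
#' aortic valve replacement (AVR, surgical or transcatheter) occurred on or
#' before a fixed follow-up cutoff date. The disparity suite then compares
#' treated against untreated-sAS patients (and SAVR against TAVR among the
#' treated) with standard table-one style univariate tests, and fits
#' multivariable logistic models for receipt of AVR -- on the full cohort,
#' and repeated on the subset with neighbourhood SDoH (Healthy Places
#' Index) data available, where the HPI percentile enters as a covariate.
#'
#' @name disparity
NULL

#' Assign treatment status at a cutoff date
#'
#' @param patients Patient table ([cohort_io]).
#' @param study_dates Named `Date` vector keyed by `patient_id` (the
#'   patient's index echo date).
#' @param cutoff Follow-up cutoff `Date`; a patient is treated iff
#'   `avr_date <= cutoff`.
#' @return Data frame `patient_id`, `treated`, `modality`,
#'   `days_echo_to_treatment` (`NA` when untreated), `days_echo_to_cutoff`,
#'   `carried_forward`; with a `"summary"` attribute holding the median
#'   days-to-treatment among treated and median follow-up among untreated.
#'   An AVR date preceding the index echo of a non-carried-forward patient
#'   raises a warning and is retained with days set to 0.
#' @export
assign_treatment_status <- function(patients, study_dates, cutoff) {
  cutoff <- as.Date(cutoff)
  idx <- match(patients$patient_id, names(study_dates))
  if (anyNA(idx)) {
    stop("no study date for patient(s): ",
         paste(utils::head(patients$patient_id[is.na(idx)], 5L), collapse = ", "))
  }
  sd <- as.Date(study_dates[idx])
  if (any(sd > cutoff, na.rm = TRUE)) stop("cutoff precedes a study date")
  treated <- !is.na(patients$avr_date) & patients$avr_date <= cutoff
  days_tx <- ifelse(treated, as.integer(patients$avr_date - sd), NA_integer_)
  neg <- !is.na(days_tx) & days_tx < 0 & !patients$carried_forward
  if (any(neg)) {
    warning(sum(neg), " patient(s) with AVR date before index echo; ",
            "days_echo_to_treatment set to 0", call. = FALSE)
  }
  days_tx[!is.na(days_tx) & days_tx < 0] <- 0L
  out <- data.frame(
    patient_id = patients$patient_id,
    treated = treated,
    modality = ifelse(treated, patients$avr_modality, NA_character_),
    days_echo_to_treatment = days_tx,
    days_echo_to_cutoff = as.integer(cutoff - sd),
    carried_forward = patients$carried_forward,
    stringsAsFactors = FALSE
  )
  attr(out, "summary") <- list(
    cutoff = cutoff,
    n_treated = sum(treated),
    median_days_to_treatment = if (any(treated))
      stats::median(days_tx[treated]) else NA_real_,
    median_followup_days_untreated = if (any(!treated))
      stats::median(out$days_echo_to_cutoff[!treated]) else NA_real_
  )
  out
}

#' Table-one style univariate comparison of two groups
#'
#' Continuous variables are compared with Welch's two-sample t test and
#' summarized as mean (SD); categorical variables with a chi-square test on
#' the full contingency table (no continuity correction), falling back to
#' Fisher's exact test when any expected cell count is below 5, and
#' summarized as n (%). Percentages are column percentages within group,
#' reported to one decimal. All p-values are two-tailed. An all-constant
#' variable yields an `NA` p-value with a diagnostic.
#'
#' @param data Data frame holding the variables.
#' @param group Logical or two-level vector splitting `data` into two groups.
#' @param variables Character vector of column names to compare.
#' @param group_labels Length-2 labels for the groups (defaults derived
#'   from `group`).
#' @return A `univariate_table`: data frame with one row per continuous
#'   variable and one per categorical level (`variable`, `level`, per-group
#'   `n`/`pct` or `mean`/`sd`, `p_value`, `test`).
#' @export
univariate_compare <- function(data, group, variables,
                               group_labels = NULL) {
  g <- if (is.logical(group)) factor(group, levels = c(TRUE, FALSE)) else factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  if (is.null(group_labels)) group_labels <- levels(g)
  rows <- list()
  for (v in variables) {
    x <- data[[v]]
    if (is.null(x)) stop("no such variable: ", v)
    x1 <- x[g == levels(g)[1]]
    x2 <- x[g == levels(g)[2]]
    if (is.numeric(x)) {
      p <- test <- NA
      if (length(unique(stats::na.omit(x))) <= 1L) {
        message("univariate_compare: '", v, "' is constant; no test performed")
        test <- "none"
      } else if (sum(!is.na(x1)) >= 2L && sum(!is.na(x2)) >= 2L) {
        p <- stats::t.test(x1, x2)$p.value
        test <- "welch_t"
      } else {
        stop("'", v, "': need >= 2 observations per group for continuous test")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_,
        g1_n = sum(!is.na(x1)), g1_pct = NA_real_,
        g1_mean = mean(x1, na.rm = TRUE), g1_sd = stats::sd(x1, na.rm = TRUE),
        g2_n = sum(!is.na(x2)), g2_pct = NA_real_,
        g2_mean = mean(x2, na.rm = TRUE), g2_sd = stats::sd(x2, na.rm = TRUE),
        p_value = as.numeric(p), test = as.character(test),
        stringsAsFactors = FALSE
      )
    } else {
      x <- factor(x)
      tab <- table(x, g)
      p <- NA_real_
      test <- "none"
      if (nrow(tab) > 1L && all(colSums(tab) > 0)) {
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expected < 5)) {
          p <- stats::fisher.test(tab, workspace = 2e6,
                                  simulate.p.value = nrow(tab) > 5)$p.value
          test <- "fisher"
        } else {
          p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
          test <- "chisq"
        }
      } else {
        message("univariate_compare: '", v, "' is constant; no test performed")
      }
      n1 <- sum(tab[, 1]); n2 <- sum(tab[, 2])
      for (lv in rownames(tab)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv,
          g1_n = tab[lv, 1],
          g1_pct = if (n1 > 0) round(100 * tab[lv, 1] / n1, 1) else NA_real_,
          g1_mean = NA_real_, g1_sd = NA_real_,
          g2_n = tab[lv, 2],
          g2_pct = if (n2 > 0) round(100 * tab[lv, 2] / n2, 1) else NA_real_,
          g2_mean = NA_real_, g2_sd = NA_real_,
          p_value = p, test = test,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "group_labels") <- group_labels
  class(out) <- c("univariate_table", class(out))
  out
}

#' @export
print.univariate_table <- function(x, digits = 3, ...) {
  gl <- attr(x, "group_labels")
  cat("Univariate comparison:", gl[1], "vs", gl[2], "\n")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    if (is.na(r$level)) {
      cat(sprintf("  %-18s %8.2f (%.2f) | %8.2f (%.2f)  p=%s [%s]\n",
                  r$variable, r$g1_mean, r$g1_sd, r$g2_mean, r$g2_sd,
                  format.pval(r$p_value, digits = digits), r$test))
    } else {
      cat(sprintf("  %-18s %6d (%.1f%%) | %6d (%.1f%%)  p=%s\n",
                  paste0(r$variable, ":", r$level), r$g1_n, r$g1_pct,
                  r$g2_n, r$g2_pct, format.pval(r$p_value, digits = digits)))
    }
  }
  invisible(x)
}

.default_references <- function() {
  list(sex = "female", race = "White", ethnicity = "Non-Hispanic",
       insurance = "Private")
}

#' Multivariable logistic regression with an odds-ratio table
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' `stats::glm`, convergence tolerance 1e-10, up to 100 iterations) with
#' Wald confidence intervals. Categorical covariates are dummy-encoded
#' against declared reference levels (defaults: female sex, White race,
#' Non-Hispanic ethnicity, Private insurance; "Unknown" is modeled as a
#' level, not dropped). Complete separation or non-convergence is reported
#' through the `converged` flag and a diagnostic, never as a silent or
#' crashed fit.
#'
#' @param outcome Binary vector (0/1 or logical), both classes present.
#' @param design Data frame of covariates; character columns are treated as
#'   categorical.
#' @param references Named list mapping categorical columns to their
#'   reference level (missing entries: first level alphabetically).
#' @param ci_level Confidence level for Wald intervals (default 0.95).
#' @return A `logistic_fit`: list with `table` (term, estimate (log-OR),
#'   se, or, ci_lower, ci_upper, p_value), `references`, `converged`,
#'   `diagnostic`, `n`.
#' @export
fit_logistic <- function(outcome, design,
                         references = .default_references(),
                         ci_level = 0.95) {
  y <- as.integer(as.logical(outcome))
  if (length(unique(stats::na.omit(y))) != 2L) {
    stop("outcome must contain both classes")
  }
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  for (nm in names(design)) {
    if (is.character(design[[nm]]) || is.factor(design[[nm]])) {
      lv <- sort(unique(as.character(stats::na.omit(design[[nm]]))))
      ref <- references[[nm]]
      if (!is.null(ref) && ref %in% lv) lv <- c(ref, setdiff(lv, ref))
      design[[nm]] <- factor(as.character(design[[nm]]), levels = lv)
    }
  }
  dat <- cbind(data.frame(.y = y), design)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$.y)) != 2L) stop("outcome must contain both classes")
  constant <- vapply(names(design), function(nm)
    length(unique(dat[[nm]])) < 2L, logical(1))
  dropped <- names(design)[constant]
  if (length(dropped)) {
    message("fit_logistic: dropping constant covariate(s): ",
            paste(dropped, collapse = ", "))
    dat <- dat[, c(".y", setdiff(names(design), dropped)), drop = FALSE]
  }
  glm_warnings <- character(0)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      glm_warnings <<- c(glm_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  tab <- data.frame(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    or = exp(cf[, "Estimate"]),
    ci_lower = exp(cf[, "Estimate"] - z * cf[, "Std. Error"]),
    ci_upper = exp(cf[, "Estimate"] + z * cf[, "Std. Error"]),
    p_value = cf[, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  separated <- any(abs(cf[, "Estimate"]) > 15) || any(cf[, "Std. Error"] > 100)
  converged <- fit$converged && !separated
  structure(list(
    table = tab,
    references = references,
    dropped = dropped,
    converged = converged,
    diagnostic = if (converged) NA_character_ else if (separated)
      "possible complete separation (extreme coefficient or standard error)"
    else "IRLS did not converge",
    warnings = glm_warnings,
    n = nrow(dat)
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat("Logistic fit (n =", x$n, ")",
      if (!x$converged) paste0("  [NOT CONVERGED: ", x$diagnostic, "]"), "\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-28s OR %6.3f (%5.3f, %6.3f)  p=%s\n",
                tab$term[i], tab$or[i], tab$ci_lower[i], tab$ci_upper[i],
                format.pval(tab$p_value[i], digits = digits)))
  }
  invisible(x)
}

#' Run the full treatment-disparity suite
#'
#' Restricts to the analysis population -- treated patients plus patients
#' with untreated sAS -- then produces (a) the treated-vs-untreated
#' univariate table, (b) the SAVR-vs-TAVR univariate table among the
#' treated, (c) a multivariable logistic model for receipt of AVR (age,
#' sex, race, ethnicity, insurance) on all patients in the population, and
#' (d) the same model restricted to patients with SDoH available, with the
#' HPI percentile added. If no patient has SDoH data the stratified model
#' is skipped with a diagnostic.
#'
#' @param patients Patient table ([cohort_io]).
#' @param statuses Output of [assign_treatment_status()].
#' @param sas Named logical vector by `patient_id`: engine-identified sAS.
#' @param references Reference levels for [fit_logistic()].
#' @return List with `population` (analysis data frame),
#'   `univariate_treatment`, `univariate_modality`, `model_all`,
#'   `model_sdoh` (or `NULL`), and `notes`.
#' @export
run_disparity_suite <- function(patients, statuses, sas,
                                references = .default_references()) {
  idx <- match(patients$patient_id, statuses$patient_id)
  if (anyNA(idx)) stop("statuses missing for some patients")
  st <- statuses[idx, , drop = FALSE]
  is_sas <- rep(FALSE, nrow(patients))
  hit <- match(patients$patient_id, names(sas))
  is_sas[!is.na(hit)] <- as.logical(sas[hit[!is.na(hit)]])
  pop <- st$treated | (is_sas & !st$treated)
  dat <- cbind(patients[pop, , drop = FALSE], st[pop, c(
    "treated", "modality", "days_echo_to_treatment", "days_echo_to_cutoff"
  )])
  notes <- character(0)
  if (!nrow(dat) || length(unique(dat$treated)) < 2L) {
    stop("analysis population must contain treated and untreated patients")
  }

  uni_vars <- c("age_years", "sex", "race", "ethnicity", "insurance",
                "hpi_score", "hpi_percentile")
  uni_tx <- univariate_compare(dat, dat$treated, uni_vars,
                               group_labels = c("treated", "untreated_sas"))
  uni_mod <- NULL
  trt <- dat[dat$treated, , drop = FALSE]
  if (length(unique(stats::na.omit(trt$modality))) == 2L) {
    uni_mod <- univariate_compare(trt, trt$modality == "SAVR", uni_vars,
                                  group_labels = c("SAVR", "TAVR"))
  } else {
    notes <- c(notes, "modality comparison skipped: fewer than two modalities")
  }

  model_all <- fit_logistic(
    dat$treated,
    dat[c("age_years", "sex", "race", "ethnicity", "insurance")],
    references = references
  )
  sdoh <- !is.na(dat$hpi_percentile)
  model_sdoh <- NULL
  if (any(sdoh) && length(unique(dat$treated[sdoh])) == 2L) {
    model_sdoh <- fit_logistic(
      dat$treated[sdoh],
      dat[sdoh, c("age_years", "sex", "race", "ethnicity", "insurance",
                  "hpi_percentile")],
      references = references
    )
  } else {
    notes <- c(notes, "SDoH-stratified model skipped: no usable SDoH data")
  }

  list(population = dat, univariate_treatment = uni_tx,
       univariate_modality = uni_mod, model_all = model_all,
       model_sdoh = model_sdoh, notes = notes)
}
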