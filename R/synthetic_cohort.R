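#' Synthetic labelled cohorts
#'
#' The generator emulates the data sources the engine consumes -- severity
#' language in report conclusions (with negations, half-grades and
#' deliberately out-of-lexicon phrasing), quantitative measurements drawn
#' from grade-consistent guideline intervals (optionally perturbed across a
#' boundary to plant text/number discordance), prosthetic-valve studies,
#' missing-measurement and missing-SDoH patterns, and covariate-dependent
#' treatment assignment -- while recording complete ground truth, so every
#' other module is testable without any protected health information.
#' Measurements are sampled from the open interior of each grade's
#' threshold interval (one representation step away from the boundaries),
#' so boundary tie-breaking is exercised by dedicated fixtures rather than
#' by chance.
#'
#' @name synthetic_cohort
NULL

.default_grade_mixture <- c(
  none = 0.001, mild = 0.583, mild_to_moderate = 0.097, moderate = 0.208,
  moderate_to_severe = 0.049, severe = 0.061, critical = 0.001
)

#' Generator configuration
#'
#' Defaults mirror the marginal structure of a large single-center screening
#' cohort: the grade mixture among gradeable studies, 45% missing
#' neighbourhood SDoH, ages Normal(78, 12) truncated at 18, and a treatment
#' model whose odds ratios echo the disparities reported in that setting
#' (treatment less likely with age, Medicare and HMO coverage; more likely
#' for men). The joint structure beyond these marginals is not claimed to be
#' realistic.
#'
#' @param n_patients Number of patients (one index study each).
#' @param grade_mixture Named probability vector over [grade_levels()];
#'   must sum to 1.
#' @param p_text_present Probability a report carries a qualitative AS
#'   signal (severity phrase, or explicit denial for grade none).
#' @param p_discordant Probability (given an in-lexicon severity phrase at a
#'   full grade) that measurements are drawn from a neighbouring full
#'   grade's interval instead of the true one.
#' @param p_negation Probability a texted grade-none report uses an explicit
#'   denial ("no aortic stenosis"); otherwise neutral text plus normal-range
#'   measurements.
#' @param p_out_of_lexicon Probability (full grades with text only) of a
#'   held-out template the lexicon cannot read, forcing quantitative
#'   fallback; measurements are then guaranteed present.
#' @param p_prosthetic Probability of a prosthetic-valve study (flagged
#'   structurally, textually, or both).
#' @param p_opted_out Probability a patient previously opted out of chart
#'   review.
#' @param p_sdoh_missing Probability HPI score and percentile are both
#'   missing.
#' @param measurement_missingness Named vector of per-parameter missingness
#'   probabilities (`ava_cm2`, `mean_gradient_mmhg`, `peak_velocity_ms`).
#'   At least one measurement is forced present whenever the study's truth
#'   is only recoverable quantitatively.
#' @param age_mean,age_sd Age distribution (years), truncated at 18.
#' @param treatment_model Named log-odds coefficients for AVR among true-sAS
#'   patients: `intercept`, `age_per_year` (centered at 78), `male`,
#'   `medicare`, `hmo`, `medicare_advantage`, `medicaid`,
#'   `insurance_unknown`, `hpi_percentile` (centered at 0.66; no
#'   contribution when SDoH missing).
#' @param modality_model Same form for P(SAVR | treated): `intercept`,
#'   `age_per_year`, `male`, `hpi_score`.
#' @param study_year Calendar year of index studies.
#' @param cutoff Follow-up cutoff date.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_patients = 1000L,
    grade_mixture = .default_grade_mixture,
    p_text_present = 0.85,
    p_discordant = 0.10,
    p_negation = 0.80,
    p_out_of_lexicon = 0.05,
    p_prosthetic = 0.03,
    p_opted_out = 0.02,
    p_sdoh_missing = 0.45,
    measurement_missingness = c(ava_cm2 = 0.30, mean_gradient_mmhg = 0.20,
                                peak_velocity_ms = 0.20),
    age_mean = 78, age_sd = 12,
    treatment_model = c(intercept = 1.6, age_per_year = log(0.96),
                        male = log(1.52), medicare = log(0.48),
                        hmo = log(0.24), medicare_advantage = log(3.48),
                        medicaid = log(0.66), insurance_unknown = log(0.29),
                        hpi_percentile = log(0.53)),
    modality_model = c(intercept = -1.3, age_per_year = -0.12,
                       male = 0.83, hpi_score = -0.5),
    study_year = 2023L,
    cutoff = as.Date("2024-06-10"),
    seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    grade_mixture = grade_mixture,
    p_text_present = p_text_present, p_discordant = p_discordant,
    p_negation = p_negation, p_out_of_lexicon = p_out_of_lexicon,
    p_prosthetic = p_prosthetic, p_opted_out = p_opted_out,
    p_sdoh_missing = p_sdoh_missing,
    measurement_missingness = measurement_missingness,
    age_mean = age_mean, age_sd = age_sd,
    treatment_model = treatment_model, modality_model = modality_model,
    study_year = as.integer(study_year), cutoff = as.Date(cutoff),
    seed = as.integer(seed)
  )
  probs <- c(cfg$p_text_present, cfg$p_discordant, cfg$p_negation,
             cfg$p_out_of_lexicon, cfg$p_prosthetic, cfg$p_opted_out,
             cfg$p_sdoh_missing, cfg$measurement_missingness, grade_mixture)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$n_patients < 1L) stop("n_patients must be positive")
  if (!setequal(names(grade_mixture), grade_levels())) {
    stop("grade_mixture must name every grade level")
  }
  if (abs(sum(grade_mixture) - 1) > 1e-8) stop("grade_mixture must sum to 1")
  if (!setequal(names(cfg$measurement_missingness),
                c("ava_cm2", "mean_gradient_mmhg", "peak_velocity_ms"))) {
    stop("measurement_missingness must name the three parameters")
  }
  class(cfg) <- "generator_config"
  cfg
}

# Severity phrases the shipped lexicon can read, one per grade.
.inlex_phrase <- c(
  none = "No aortic stenosis",
  mild = "Mild aortic stenosis",
  mild_to_moderate = "Mild to moderate aortic stenosis",
  moderate = "Moderate aortic stenosis",
  moderate_to_severe = "Moderate to severe aortic stenosis",
  severe = "Severe aortic stenosis",
  critical = "Critical aortic stenosis"
)

# Held-out templates the lexicon deliberately cannot read (quantitative
# fallback path); they avoid every severity phrase and negation cue.
.out_of_lexicon_templates <- c(
  "Calcified aortic valve with diminished opening.",
  "Degenerative aortic valve changes; see measurements.",
  "Aortic valve appears thickened; gradients as measured."
)

.neutral_templates <- c(
  "Normal left ventricular size and function.",
  "Trileaflet aortic valve with normal excursion.",
  "Aortic sclerosis."
)

.prosthetic_phrases <- c(
  "Status post TAVR with normally functioning bioprosthesis.",
  "Mechanical aortic valve in situ.",
  "Prosthetic aortic valve with stable gradients."
)

# Draw a value from the open interior of a grade's interval (one
# representation `step` from each boundary); unbounded intervals use `span`.
.draw_in_interval <- function(tab, grade, step, span) {
  i <- which(tab$grade == grade)
  if (length(i) != 1L) stop("no interval for grade ", grade)
  lo <- tab$lower[i] + step
  hi <- if (is.finite(tab$upper[i])) tab$upper[i] - step else tab$lower[i] + span
  if (hi < lo) hi <- lo
  round(stats::runif(1, lo, hi) / step) * step
}

.full_grades <- c("none", "mild", "moderate", "severe", "critical")

# Nearest full grade at or below (for sampling measurements under a
# half-grade truth: quantitative intervals exist only for full grades).
.quant_target <- function(grade) {
  .full_grades[findInterval(grade_rank(grade), c(0, 1, 2, 3, 3.5))]
}

.neighbour_full_grade <- function(grade) {
  i <- match(grade, .full_grades)
  if (is.na(i)) i <- match(.quant_target(grade), .full_grades)
  cand <- c(i - 1L, i + 1L)
  cand <- cand[cand >= 1L & cand <= length(.full_grades)]
  .full_grades[sample(cand, 1L)]
}

#' Generate a labelled synthetic cohort
#'
#' @param config A `generator_config`.
#' @param thresholds Threshold table used to draw grade-consistent
#'   measurements (default shipped table).
#' @return List with `cohort` (an `echo_cohort` that passes
#'   [validate_cohort()]), `truth` (per-study ground truth: true grade,
#'   text/quantitative channel labels, discordance/negation/prosthetic
#'   flags, per-patient treatment propensity), and `config`.
#' @export
generate_cohort <- function(config, thresholds = default_thresholds()) {
  stopifnot(inherits(config, "generator_config"))
  validate_thresholds(thresholds)
  .with_seed(config$seed, .generate_cohort_impl(config, thresholds))
}

.generate_cohort_impl <- function(config, thresholds) {
  n <- config$n_patients
  study_id <- sprintf("s%06d", seq_len(n))
  patient_id <- sprintf("p%06d", seq_len(n))
  year0 <- as.Date(sprintf("%d-01-01", config$study_year))
  study_date <- year0 + sample.int(365L, n, replace = TRUE) - 1L

  true_grade <- sample(names(config$grade_mixture), n, replace = TRUE,
                       prob = config$grade_mixture)
  prosthetic <- stats::runif(n) < config$p_prosthetic
  text_present <- stats::runif(n) < config$p_text_present
  is_half <- !true_grade %in% .full_grades

  report <- character(n)
  ava <- grad <- vel <- rep(NA_real_, n)
  text_grade <- rep(NA_character_, n)
  quant_grade <- rep(NA_character_, n)
  negated <- out_of_lex <- discordant <- logical(n)
  miss <- config$measurement_missingness

  for (i in seq_len(n)) {
    g <- true_grade[i]
    if (prosthetic[i]) {
      channel <- sample(c("structured", "text", "both"), 1L)
      report[i] <- if (channel %in% c("text", "both"))
        sample(.prosthetic_phrases, 1L) else ""
      next
    }
    quant_needed <- FALSE
    if (text_present[i]) {
      if (g == "none") {
        if (stats::runif(1) < config$p_negation) {
          report[i] <- paste0(.inlex_phrase[["none"]], ".")
          negated[i] <- TRUE
          text_grade[i] <- "none"
        } else {
          report[i] <- sample(.neutral_templates, 1L)
          quant_needed <- TRUE
        }
      } else if (!is_half[i] && stats::runif(1) < config$p_out_of_lexicon) {
        report[i] <- sample(.out_of_lexicon_templates, 1L)
        out_of_lex[i] <- TRUE
        quant_needed <- TRUE
      } else {
        extra <- if (grade_rank(g) >= 2.5)
          " Restricted leaflet excursion with elevated gradients." else ""
        report[i] <- paste0(.inlex_phrase[[g]], ".", extra)
        text_grade[i] <- g
      }
    } else {
      report[i] <- ""
      quant_needed <- TRUE
    }

    # target full grade for measurement sampling
    target <- .quant_target(g)
    if (!is.na(text_grade[i]) && !is_half[i] && g != "none" &&
        stats::runif(1) < config$p_discordant) {
      target <- .neighbour_full_grade(g)
      discordant[i] <- TRUE
    }
    quant_grade[i] <- target

    present <- stats::runif(3) >= miss[c("ava_cm2", "mean_gradient_mmhg",
                                         "peak_velocity_ms")]
    if (quant_needed && !any(present)) present[1] <- TRUE
    if (present[1]) ava[i] <- .draw_in_interval(thresholds$ava_cm2, target,
                                                step = 0.01, span = 1.5)
    if (present[2]) grad[i] <- .draw_in_interval(thresholds$mean_gradient_mmhg,
                                                 target, step = 0.1, span = 25)
    if (present[3]) vel[i] <- .draw_in_interval(thresholds$peak_velocity_ms,
                                                target, step = 0.01, span = 1.2)
  }
  quant_grade[prosthetic] <- NA_character_

  prost_structured <- prosthetic & (report == "" | stats::runif(n) < 0.5)
  # a prosthetic study is always detectable by at least one channel
  prost_structured[prosthetic & report == ""] <- TRUE

  lvef <- pmin(80, pmax(10, round(stats::rnorm(n, 58, 12), 0)))

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  while (any(age < 18)) {
    age[age < 18] <- stats::rnorm(sum(age < 18), config$age_mean, config$age_sd)
  }
  age <- round(age, 1)
  sex <- sample(.sex_levels, n, replace = TRUE, prob = c(0.537, 0.459, 0.004))
  race <- sample(.race_levels, n, replace = TRUE,
                 prob = c(0.736, 0.076, 0.051, 0.002, 0.004, 0.099, 0.032))
  ethnicity <- sample(.ethnicity_levels, n, replace = TRUE,
                      prob = c(0.110, 0.857, 0.033))
  insurance <- sample(.insurance_levels, n, replace = TRUE,
                      prob = c(0.452, 0.432, 0.015, 0.044, 0.017, 0.040))
  hpi_pct <- pmin(0.999, pmax(0.001, stats::rbeta(n, 1.7, 0.9)))
  hpi_score <- round(stats::qnorm(hpi_pct, mean = 0.30, sd = 0.48), 3)
  sdoh_missing <- stats::runif(n) < config$p_sdoh_missing
  hpi_pct[sdoh_missing] <- NA_real_
  hpi_score[sdoh_missing] <- NA_real_
  hpi_pct <- round(hpi_pct, 3)
  opted_out <- stats::runif(n) < config$p_opted_out

  tm <- config$treatment_model
  lin <- tm[["intercept"]] +
    tm[["age_per_year"]] * (age - 78) +
    tm[["male"]] * (sex == "male") +
    tm[["medicare"]] * (insurance == "Medicare") +
    tm[["hmo"]] * (insurance == "HMO") +
    tm[["medicare_advantage"]] * (insurance == "MedicareAdvantage") +
    tm[["medicaid"]] * (insurance == "Medicaid") +
    tm[["insurance_unknown"]] * (insurance == "Unknown") +
    tm[["hpi_percentile"]] * ifelse(is.na(hpi_pct), 0, hpi_pct - 0.66)
  propensity <- stats::plogis(lin)
  eligible <- dichotomize(true_grade) & !prosthetic
  treated <- eligible & stats::runif(n) < propensity

  mm <- config$modality_model
  lin_m <- mm[["intercept"]] + mm[["age_per_year"]] * (age - 78) +
    mm[["male"]] * (sex == "male") +
    mm[["hpi_score"]] * ifelse(is.na(hpi_score), 0, hpi_score - 0.3)
  savr_prop <- stats::plogis(lin_m)
  modality <- rep(NA_character_, n)
  modality[treated] <- ifelse(stats::runif(sum(treated)) < savr_prop[treated],
                              "SAVR", "TAVR")
  avr_date <- as.Date(rep(NA_character_, n))
  avr_date[treated] <- study_date[treated] +
    round(stats::rexp(sum(treated), rate = log(2) / 3))
  over <- treated & avr_date > config$cutoff
  avr_date[over] <- config$cutoff

  studies <- data.frame(
    study_id = study_id, patient_id = patient_id, study_date = study_date,
    report_text = report, ava_cm2 = ava, mean_gradient_mmhg = grad,
    peak_velocity_ms = vel, lvef_pct = lvef,
    prosthetic_valve_structured = prost_structured,
    stringsAsFactors = FALSE
  )
  patients <- data.frame(
    patient_id = patient_id, age_years = age, sex = sex, race = race,
    ethnicity = ethnicity, insurance = insurance, hpi_score = hpi_score,
    hpi_percentile = hpi_pct, opted_out = opted_out, avr_date = avr_date,
    avr_modality = modality, carried_forward = FALSE,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    study_id = study_id, patient_id = patient_id,
    true_grade = true_grade,
    text_grade = text_grade,
    true_quantitative_grade = quant_grade,
    discordant = discordant,
    negated = negated,
    out_of_lexicon = out_of_lex,
    prosthetic = prosthetic,
    treated = treated,
    treatment_propensity = ifelse(eligible, propensity, NA_real_),
    savr_propensity = ifelse(treated, savr_prop, NA_real_),
    stringsAsFactors = FALSE
  )
  list(cohort = as_cohort(studies, patients), truth = truth, config = config)
}

#' Generate adjudication labels from ground truth
#'
#' Adjudicated grade equals the planted true grade, with optional planted
#' adjudication noise. The default error model emulates the
#' false-positive-only regime of a well-tuned screening engine: with
#' probability `sas_fp_rate`, a true-sAS study is adjudicated below the sAS
#' boundary (grade none with probability `fp_to_none_frac`, else moderate),
#' making the engine's call a false positive.
#'
#' @param truth Ground-truth data frame from [generate_cohort()].
#' @param error_model List with `sas_fp_rate` (in \[0,1\]) and
#'   `fp_to_none_frac` (fraction of planted errors adjudicated as no AS).
#' @param seed Integer seed.
#' @return Data frame `study_id`, `adjudicated_grade`.
#' @export
generate_adjudication <- function(truth,
                                  error_model = list(sas_fp_rate = 0,
                                                     fp_to_none_frac = 0.2),
                                  seed = 1L) {
  rate <- error_model$sas_fp_rate %||% 0
  frac <- error_model$fp_to_none_frac %||% 0.2
  if (rate < 0 || rate > 1 || frac < 0 || frac > 1) {
    stop("error model probabilities must lie in [0, 1]")
  }
  .with_seed(seed, {
    adj <- truth$true_grade
    hit <- dichotomize(truth$true_grade) & stats::runif(nrow(truth)) < rate
    adj[hit] <- ifelse(stats::runif(sum(hit)) < frac, "none", "moderate")
    data.frame(study_id = truth$study_id, adjudicated_grade = adj,
               stringsAsFactors = FALSE)
  })
}
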