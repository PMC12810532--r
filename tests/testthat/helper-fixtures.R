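# Shared fixtures and independent oracles for the suite.

make_study <- function(study_id = "s1", patient_id = "p1",
                       study_date = as.Date("2023-06-01"),
                       report_text = "", ava_cm2 = NA_real_,
                       mean_gradient_mmhg = NA_real_,
                       peak_velocity_ms = NA_real_, lvef_pct = 60,
                       prosthetic_valve_structured = FALSE) {
  data.frame(study_id = study_id, patient_id = patient_id,
             study_date = study_date, report_text = report_text,
             ava_cm2 = ava_cm2, mean_gradient_mmhg = mean_gradient_mmhg,
             peak_velocity_ms = peak_velocity_ms, lvef_pct = lvef_pct,
             prosthetic_valve_structured = prosthetic_valve_structured,
             stringsAsFactors = FALSE)
}

make_patient <- function(patient_id = "p1", age_years = 75, sex = "female",
                         race = "White", ethnicity = "Non-Hispanic",
                         insurance = "Private", hpi_score = 0.3,
                         hpi_percentile = 0.6, opted_out = FALSE,
                         avr_date = as.Date(NA), avr_modality = NA_character_,
                         carried_forward = FALSE) {
  data.frame(patient_id = patient_id, age_years = age_years, sex = sex,
             race = race, ethnicity = ethnicity, insurance = insurance,
             hpi_score = hpi_score, hpi_percentile = hpi_percentile,
             opted_out = opted_out, avr_date = avr_date,
             avr_modality = avr_modality, carried_forward = carried_forward,
             stringsAsFactors = FALSE)
}

make_tiny_cohort <- function() {
  studies <- rbind(
    make_study("s1", "p1", report_text = "Severe aortic stenosis.",
               ava_cm2 = 0.8),
    make_study("s2", "p2", report_text = "No aortic stenosis."),
    make_study("s3", "p3", report_text = "", mean_gradient_mmhg = 25)
  )
  patients <- rbind(make_patient("p1"), make_patient("p2"),
                    make_patient("p3"))
  as_cohort(studies, patients)
}

# Independent quantitative-grading oracle: the guideline cut-points written
# as a frozen if/else chain, separate from the interval machinery.
oracle_quant_grade <- function(ava = NA, grad = NA, vel = NA,
                               use_velocity = TRUE) {
  if (!is.na(ava)) {
    if (ava <= 0.6) "critical"
    else if (ava <= 1.0) "severe"
    else if (ava <= 1.5) "moderate"
    else if (ava <= 2.0) "mild"
    else "none"
  } else if (!is.na(grad)) {
    if (grad < 10) "none"
    else if (grad < 20) "mild"
    else if (grad < 40) "moderate"
    else if (grad < 60) "severe"
    else "critical"
  } else if (use_velocity && !is.na(vel)) {
    if (vel < 2) "none"
    else if (vel < 3) "mild"
    else if (vel < 4) "moderate"
    else if (vel < 5) "severe"
    else "critical"
  } else {
    NA_character_
  }
}

# Frozen rank table for concordance oracles, independent of grade_rank().
oracle_rank <- c(none = 0, mild = 1, mild_to_moderate = 1.5, moderate = 2,
                 moderate_to_severe = 2.5, severe = 3, critical = 3.5)

# Independent Newton-Raphson logistic regression (dual-route oracle for
# fit_logistic, which delegates to glm/IRLS).
newton_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- drop(t(X) %*% (y - p))
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, se = sqrt(diag(solve(info))))
}

# Hand-labelled report corpus: text plus expected extraction.
nlp_corpus <- function() {
  lab <- function(text, severity = NA_character_, negated = FALSE,
                  leaflet = FALSE, gradient = FALSE, prosthetic = FALSE) {
    data.frame(text = text, severity = severity, negated = negated,
               leaflet = leaflet, gradient = gradient,
               prosthetic = prosthetic, stringsAsFactors = FALSE)
  }
  rbind(
    lab("Severe aortic stenosis.", "severe"),
    lab("severe aortic stenosis with preserved EF", "severe"),
    lab("Critical aortic stenosis.", "critical"),
    lab("Moderate aortic stenosis.", "moderate"),
    lab("Mild aortic stenosis.", "mild"),
    lab("Mild to moderate aortic stenosis.", "mild_to_moderate"),
    lab("Mild-moderate aortic stenosis.", "mild_to_moderate"),
    lab("Moderate to severe aortic stenosis.", "moderate_to_severe"),
    lab("Moderate-severe aortic stenosis.", "moderate_to_severe"),
    lab("moderate to severe aortic valve stenosis noted", "moderate_to_severe"),
    lab("Severe AS.", "severe"),
    lab("moderate AS with preserved function", "moderate"),
    lab("Moderate to severe aortic stenosis with restricted leaflet excursion.",
        "moderate_to_severe", leaflet = TRUE),
    lab("Severe aortic stenosis. Restricted leaflet excursion with elevated gradients.",
        "severe", leaflet = TRUE, gradient = TRUE),
    lab("Aortic valve leaflets are restricted.", leaflet = TRUE),
    lab("Elevated transvalvular gradient without clear severity statement.",
        gradient = TRUE),
    lab("Abnormal gradient across the aortic valve.", gradient = TRUE),
    lab("No aortic stenosis.", negated = TRUE),
    lab("No aortic stenosis; aortic sclerosis without stenosis.", negated = TRUE),
    lab("Aortic sclerosis without stenosis.", negated = TRUE),
    lab("There is no evidence of aortic stenosis.", negated = TRUE),
    lab("Aortic sclerosis."),           # sclerosis alone: no AS signal
    lab("Sclerosis rather than stenosis of the aortic valve.", negated = TRUE),
    lab("Mild aortic stenosis in the prior study; now moderate aortic stenosis.",
        "moderate"),
    lab("Moderate aortic stenosis, previously reported as severe aortic stenosis.",
        "severe"),                      # most severe non-negated mention wins
    lab("No severe aortic stenosis; mild aortic stenosis present.", "mild"),
    lab("Status post TAVR with normally functioning bioprosthesis.",
        prosthetic = TRUE),
    lab("Mechanical aortic valve in situ.", prosthetic = TRUE),
    lab("Prosthetic aortic valve with stable gradients.", prosthetic = TRUE),
    lab("s/p aortic valve replacement.", prosthetic = TRUE),
    lab("Native trileaflet aortic valve."),
    lab("Normal left ventricular size and function."),
    lab("Trileaflet aortic valve with normal excursion."),
    lab("Calcified aortic valve with diminished opening."),
    lab("Degenerative aortic valve changes; see measurements."),
    lab("The patient was seen as an outpatient."),   # prose "as" is not AS
    lab("")
  )
}
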