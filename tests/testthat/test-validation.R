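test_that("stratified sampling is seeded, reproducible, and handles exhaustion", {
  set.seed(99)
  n <- 1500
  cls <- data.frame(
    study_id = sprintf("s%04d", 1:n),
    final_grade = sample(c(grade_levels(), NA), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cls$is_sas <- dichotomize(cls$final_grade)
  d1 <- suppressWarnings(sample_adjudication_strata(cls, 100, seed = 42))
  d2 <- suppressWarnings(sample_adjudication_strata(cls, 100, seed = 42))
  expect_identical(d1[c("sas", "below", "no_as")],
                   d2[c("sas", "below", "no_as")])
  expect_length(d1$sas, 100)
  expect_length(d1$below, 100)
  expect_length(d1$no_as, 100)
  d3 <- suppressWarnings(sample_adjudication_strata(cls, 100, seed = 43))
  expect_false(identical(d1$sas, d3$sas))
  # draw is invariant to input row order
  perm <- sample(nrow(cls))
  d4 <- suppressWarnings(sample_adjudication_strata(cls[perm, ], 100, seed = 42))
  expect_identical(d1$sas, d4$sas)

  small <- cls[cls$final_grade %in% "critical", , drop = FALSE]
  ws <- testthat::capture_warnings(
    ds <- sample_adjudication_strata(small, 1e4, seed = 1))
  expect_match(ws, "smaller than requested", all = TRUE)
  expect_length(ds$sas, nrow(small))

  expect_error(sample_adjudication_strata(cls, -1, seed = 1), "non-negative")
})

test_that("treated studies never enter the untreated-sAS stratum and opt-outs drop post-draw", {
  cls <- data.frame(
    study_id = sprintf("s%03d", 1:400),
    final_grade = rep("severe", 400),
    stringsAsFactors = FALSE)
  cls$is_sas <- TRUE
  treated <- stats::setNames(rep(c(TRUE, FALSE), each = 200), cls$study_id)
  d <- suppressWarnings(
    sample_adjudication_strata(cls, 1000, seed = 5, treated = treated))
  expect_setequal(d$sas, cls$study_id[201:400])

  # ~10% opt-out: realized stratum below the draw, deterministically per seed
  opt <- stats::setNames(rep(FALSE, 400), cls$study_id)
  opt[sample(names(opt), 40)] <- TRUE
  d1 <- suppressWarnings(sample_adjudication_strata(
    cls, 200, seed = 7, treated = treated, opted_out = opt))
  d2 <- suppressWarnings(sample_adjudication_strata(
    cls, 200, seed = 7, treated = treated, opted_out = opt))
  expect_identical(d1$sas, d2$sas)
  expect_lt(length(d1$sas), 200)
  expect_true(all(!opt[d1$sas]))
})

test_that("concordance matches a brute-force oracle over all grade pairs", {
  lv <- grade_levels()
  for (e in lv) {
    for (a in lv) {
      bin <- concordance(e, a, "binary")
      half <- concordance(e, a, "half_grade")
      bin_oracle <- (oracle_rank[e] >= 2.5) == (oracle_rank[a] >= 2.5)
      half_oracle <- abs(oracle_rank[e] - oracle_rank[a]) <= 0.5
      expect_identical(bin, unname(bin_oracle), label = paste(e, a))
      expect_identical(half, unname(half_oracle), label = paste(e, a))
      # half-grade concordance implies binary concordance for every pair
      # except the single half-step straddling the sAS boundary
      # (moderate vs moderate-to-severe), where the published convention
      # keeps them half-grade concordant but binary splits them
      straddle <- min(oracle_rank[e], oracle_rank[a]) < 2.5 &&
        max(oracle_rank[e], oracle_rank[a]) >= 2.5
      if (isTRUE(half) && !straddle) expect_true(bin, label = paste(e, a))
      if (isTRUE(half) && straddle) expect_false(bin, label = paste(e, a))
    }
  }
  # the published convention: moderate vs moderate-to-severe concordant,
  # moderate vs severe nonconcordant
  expect_true(concordance("moderate_to_severe", "severe", "half_grade"))
  expect_true(concordance("moderate_to_severe", "severe", "binary"))
  expect_false(concordance("moderate", "severe", "half_grade"))
  # not-specified adjudication: moderate-or-less in binary, excluded in half
  expect_true(concordance("mild", NA_character_, "binary"))
  expect_false(concordance("severe", NA_character_, "binary"))
  expect_true(is.na(concordance("severe", NA_character_, "half_grade")))
})

test_that("confusion metrics count correctly and ignore input order", {
  pairs <- data.frame(
    engine_grade = c(rep("severe", 190), rep("severe", 10), rep("mild", 200)),
    adjudicated_grade = c(rep("severe", 190), rep("moderate", 10),
                          rep("mild", 200)),
    stringsAsFactors = FALSE)
  no_as <- data.frame(engine_grade = rep(NA_character_, 200),
                      adjudicated_grade = rep("none", 200),
                      stringsAsFactors = FALSE)
  cm <- confusion_metrics(pairs, no_as)
  expect_equal(cm$tp, 190); expect_equal(cm$fp, 10)
  expect_equal(cm$tn, 400); expect_equal(cm$fn, 0)
  expect_equal(cm$sensitivity, 1.0)
  expect_equal(cm$specificity, 400 / 410)

  perm <- sample(nrow(pairs))
  cm2 <- confusion_metrics(pairs[perm, ], no_as)
  expect_identical(unclass(cm), unclass(cm2))

  # empty input: zero counts, absent metrics
  cm0 <- confusion_metrics(pairs[0, ])
  expect_equal(cm0$tp + cm0$fp + cm0$tn + cm0$fn, 0)
  expect_true(is.na(cm0$sensitivity))
  expect_true(is.na(cm0$specificity))

  # opted-out pairs excluded from all metrics
  pairs$opted_out <- c(rep(TRUE, 10), rep(FALSE, 390))
  cm3 <- confusion_metrics(pairs, no_as)
  expect_equal(cm3$tp, 180)
})

test_that("clean synthetic cohorts give perfect accuracy end to end", {
  sim <- generate_cohort(generator_config(n_patients = 600, seed = 21,
                                          p_discordant = 0,
                                          p_text_present = 1,
                                          p_prosthetic = 0))
  res <- classify_cohort(sim$cohort)
  adj <- generate_adjudication(sim$truth, list(sas_fp_rate = 0), seed = 1)
  pairs <- merge(res$classifications[c("study_id", "final_grade")], adj,
                 by = "study_id")
  names(pairs)[2] <- "engine_grade"
  cm <- confusion_metrics(pairs)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$fp + cm$fn, 0)
})

test_that("misclassification regression behaves under null and planted effects", {
  # degenerate input: no misclassified pairs
  pairs <- data.frame(patient_id = c("p1", "p2"),
                      engine_grade = c("severe", "mild"),
                      adjudicated_grade = c("severe", "mild"),
                      stringsAsFactors = FALSE)
  pts <- rbind(make_patient("p1"), make_patient("p2"))
  expect_error(misclassification_factors(pairs, pts), "at least one")

  # type-I error: misclassification independent of covariates
  set.seed(314)
  n <- 250
  reps <- 40
  p_age <- numeric(reps)
  for (r in seq_len(reps)) {
    pts <- do.call(rbind, lapply(seq_len(n), function(i)
      make_patient(paste0("p", i), age_years = round(runif(1, 50, 95), 1),
                   sex = sample(c("male", "female"), 1),
                   race = sample(c("White", "Black", "Asian"), 1),
                   insurance = sample(c("Private", "Medicare"), 1))))
    mis <- runif(n) < 0.15
    pairs <- data.frame(patient_id = pts$patient_id,
                        engine_grade = ifelse(mis, "severe", "moderate"),
                        adjudicated_grade = "moderate",
                        stringsAsFactors = FALSE)
    fit <- misclassification_factors(pairs, pts)
    p_age[r] <- fit$table$p_value[fit$table$term == "age_years"]
  }
  # nominal 5% rate within 3 binomial SDs
  rate <- mean(p_age < 0.05)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))

  # planted age effect (log-OR 0.693 per SD) recovered at n = 600
  set.seed(2718)
  n <- 600
  age <- rnorm(n, 75, 10)
  z <- (age - 75) / 10
  mis <- runif(n) < plogis(-1.5 + log(2) * z)
  pts <- do.call(rbind, lapply(seq_len(n), function(i)
    make_patient(paste0("p", i), age_years = round(age[i], 1),
                 sex = sample(c("male", "female"), 1))))
  pairs <- data.frame(patient_id = pts$patient_id,
                      engine_grade = ifelse(mis, "severe", "moderate"),
                      adjudicated_grade = "moderate",
                      stringsAsFactors = FALSE)
  fit <- misclassification_factors(pairs, pts)
  row <- fit$table[fit$table$term == "age_years", ]
  beta_per_sd <- row$estimate * 10
  se_per_sd <- row$se * 10
  expect_lt(abs(beta_per_sd - log(2)), 3 * se_per_sd)
})

test_that("reference cross-tabulation reproduces its audited marginals", {
  pairs <- reference_adjudication()
  expect_equal(nrow(pairs), 600L)
  expect_equal(sum(pairs$stratum == "sas"), 200L)
  expect_equal(sum(dichotomize(pairs$adjudicated_grade)), 190L)
  # the ten overestimates sit in the engine-flagged sAS stratum
  over <- dichotomize(pairs$engine_grade) & !dichotomize(pairs$adjudicated_grade)
  expect_equal(sum(over), 10L)
  expect_true(all(pairs$stratum[over] == "sas"))
  # two of them were adjudicated as having no AS at all
  expect_equal(sum(over & pairs$adjudicated_grade %in% "none"), 2L)
})
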