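test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_patients = 200, seed = 12)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c <- generate_cohort(generator_config(n_patients = 200, seed = 13))
  expect_false(identical(a$cohort$studies, c$cohort$studies))

  # file round-trip of a generated cohort is byte-stable
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(a$cohort, d1, "csv")
  write_cohort(b$cohort, d2, "csv")
  expect_identical(readLines(file.path(d1, "studies.csv")),
                   readLines(file.path(d2, "studies.csv")))
})

test_that("config validation rejects impossible settings", {
  expect_error(generator_config(p_discordant = 1.2), "probabilities")
  expect_error(generator_config(n_patients = 0), "positive")
  gm <- c(none = 0.5, mild = 0.6)
  expect_error(generator_config(grade_mixture = gm), "grade")
})

test_that("generated cohorts pass validation and measurements match planted quantitative grades", {
  sim <- generate_cohort(generator_config(n_patients = 800, seed = 4,
                                          p_discordant = 0))
  expect_true(validate_cohort(sim$cohort))
  thr <- default_thresholds()
  s <- sim$cohort$studies
  tr <- sim$truth[match(s$study_id, sim$truth$study_id), ]
  keep <- !tr$prosthetic &
    !(is.na(s$ava_cm2) & is.na(s$mean_gradient_mmhg) & is.na(s$peak_velocity_ms))
  # with discordance off, every recorded measurement set grades to the
  # planted quantitative grade (exhaustive over the generated studies)
  for (i in which(keep)) {
    g <- grade_quantitative(s[i, ], thr)
    expect_identical(g$grade, tr$true_quantitative_grade[i],
                     label = s$study_id[i])
  }
  # and each parameter individually reproduces it, for every grade present
  for (p in c("ava_cm2", "mean_gradient_mmhg", "peak_velocity_ms")) {
    j <- which(keep & !is.na(s[[p]]))
    got <- vapply(j, function(i) {
      st <- list(); st[[p]] <- s[[p]][i]
      grade_quantitative(st, thr)$grade
    }, character(1))
    expect_identical(got, tr$true_quantitative_grade[j], label = p)
  }
})

test_that("grade mixture is reproduced within binomial error at n = 10000", {
  cfg <- generator_config(n_patients = 10000, seed = 8, p_prosthetic = 0)
  sim <- generate_cohort(cfg)
  for (g in grade_levels()) {
    p <- cfg$grade_mixture[[g]]
    phat <- mean(sim$truth$true_grade == g)
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 10000) + 1e-9, label = g)
  }
})

test_that("every prosthetic study is detectable by at least one channel", {
  sim <- generate_cohort(generator_config(n_patients = 2000, seed = 15,
                                          p_prosthetic = 0.1))
  lex <- default_lexicon()
  s <- sim$cohort$studies
  tr <- sim$truth
  pros <- tr$study_id[tr$prosthetic]
  flags <- vapply(s$report_text, detect_prosthetic, logical(1), lexicon = lex)
  detectable <- s$prosthetic_valve_structured | flags
  expect_true(all(detectable[s$study_id %in% pros]))
  expect_false(any(detectable[!s$study_id %in% pros]))
})

test_that("treatment prevalence responds monotonically to model coefficients", {
  prev <- function(male_coef) {
    tm <- c(intercept = 0.5, age_per_year = log(0.96), male = male_coef,
            medicare = log(0.48), hmo = log(0.24),
            medicare_advantage = log(3.48), medicaid = log(0.66),
            insurance_unknown = log(0.29), hpi_percentile = log(0.53))
    sim <- generate_cohort(generator_config(n_patients = 3000, seed = 99,
                                            treatment_model = tm))
    tr <- sim$truth
    mean(tr$treated[dichotomize(tr$true_grade) & !tr$prosthetic])
  }
  expect_lt(prev(-1.5), prev(1.5))

  # higher intercept, higher prevalence
  prev_int <- function(b0) {
    cfg <- generator_config(n_patients = 3000, seed = 99)
    cfg$treatment_model[["intercept"]] <- b0
    sim <- generate_cohort(cfg)
    tr <- sim$truth
    mean(tr$treated[dichotomize(tr$true_grade) & !tr$prosthetic])
  }
  expect_lt(prev_int(-1), prev_int(2))
})

test_that("adjudication noise plants the false-positive-only regime", {
  sim <- generate_cohort(generator_config(n_patients = 4000, seed = 44,
                                          p_discordant = 0,
                                          p_text_present = 1,
                                          p_prosthetic = 0))
  adj0 <- generate_adjudication(sim$truth, list(sas_fp_rate = 0), seed = 2)
  expect_identical(adj0$adjudicated_grade, sim$truth$true_grade)

  adj <- generate_adjudication(sim$truth, list(sas_fp_rate = 0.05,
                                               fp_to_none_frac = 0.2),
                               seed = 2)
  adj_rep <- generate_adjudication(sim$truth, list(sas_fp_rate = 0.05,
                                                   fp_to_none_frac = 0.2),
                                   seed = 2)
  expect_identical(adj, adj_rep)
  sas <- dichotomize(sim$truth$true_grade)
  # only true-sAS rows can be perturbed, and only downward
  expect_identical(adj$adjudicated_grade[!sas], sim$truth$true_grade[!sas])
  changed <- adj$adjudicated_grade != sim$truth$true_grade
  expect_true(all(sas[changed]))
  expect_true(all(adj$adjudicated_grade[changed] %in% c("none", "moderate")))
  # empirical error rate near the planted 5%
  rate <- mean(changed[sas])
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / sum(sas)))
  expect_error(generate_adjudication(sim$truth, list(sas_fp_rate = 2)),
               "\\[0, 1\\]")
})
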