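test_that("treatment status respects the cutoff and computes day counts", {
  pts <- rbind(
    make_patient("p1", avr_date = as.Date("2023-03-04"), avr_modality = "TAVR"),
    make_patient("p2"),
    make_patient("p3", avr_date = as.Date("2024-07-01"), avr_modality = "SAVR")
  )
  dates <- stats::setNames(as.Date(c("2023-03-01", "2023-07-01", "2023-05-01")),
                           c("p1", "p2", "p3"))
  st <- assign_treatment_status(pts, dates, as.Date("2024-06-10"))
  expect_equal(st$treated, c(TRUE, FALSE, FALSE))  # AVR after cutoff = untreated
  expect_equal(st$days_echo_to_treatment[1], 3L)
  expect_equal(st$days_echo_to_cutoff[2],
               as.integer(as.Date("2024-06-10") - as.Date("2023-07-01")))
  expect_identical(st$modality, c("TAVR", NA, NA))
  s <- attr(st, "summary")
  expect_equal(s$median_days_to_treatment, 3)

  # AVR before index echo (not carried forward): warning, days clamp to 0
  pts2 <- make_patient("p9", avr_date = as.Date("2023-01-01"),
                       avr_modality = "TAVR")
  expect_warning(
    st2 <- assign_treatment_status(pts2,
                                   stats::setNames(as.Date("2023-06-01"), "p9"),
                                   as.Date("2024-06-10")),
    "before index echo")
  expect_equal(st2$days_echo_to_treatment, 0L)
  expect_true(st2$treated)
})

test_that("univariate percentages and chi-square agree with hand computation", {
  # sex split observed in a treated (584) vs untreated (242) comparison
  sex <- c(rep("Female", 188), rep("Male", 396),
           rep("Female", 111), rep("Male", 130), "Unknown")
  grp <- c(rep("treated", 584), rep("untreated", 242))
  dat <- data.frame(sex = sex, stringsAsFactors = FALSE)
  tab <- univariate_compare(dat, grp, "sex")
  f <- tab[tab$level == "Female", ]
  expect_equal(f$g1_pct, 32.2)
  expect_equal(f$g2_pct, 45.9)
  expect_lt(f$p_value[1], 0.001)

  # chi-square statistic against hand-computed expected counts (2x2, F/M only)
  m <- matrix(c(188, 396, 111, 130), nrow = 2,
              dimnames = list(c("F", "M"), c("trt", "untrt")))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  stat_hand <- sum((m - expected)^2 / expected)
  dat2 <- data.frame(sex = c(rep("F", 188), rep("M", 396),
                             rep("F", 111), rep("M", 130)))
  grp2 <- c(rep("t", 584), rep("u", 241))
  tab2 <- univariate_compare(dat2, grp2, "sex")
  p_hand <- stats::pchisq(stat_hand, df = 1, lower.tail = FALSE)
  expect_equal(tab2$p_value[1], p_hand, tolerance = 1e-12)
})

test_that("continuous variables use Welch's t and degenerate inputs are flagged", {
  set.seed(5)
  dat <- data.frame(age = c(rnorm(50, 76.6, 12.2), rnorm(50, 81.6, 11.9)),
                    flat = rep(1, 100))
  grp <- rep(c("a", "b"), each = 50)
  expect_message(tab <- univariate_compare(dat, grp, c("age", "flat")),
                 "constant")
  a <- tab[tab$variable == "age", ]
  expect_equal(a$p_value,
               stats::t.test(dat$age[grp == "a"], dat$age[grp == "b"])$p.value)
  expect_true(is.na(tab$p_value[tab$variable == "flat"]))

  # identical groups: exact test gives p = 1
  d2 <- data.frame(x = rep(c("u", "v"), times = c(6, 4)))
  g2 <- rep(c("a", "b"), 5)
  d2 <- data.frame(x = c(rep("u", 3), rep("v", 2), rep("u", 3), rep("v", 2)))
  g2 <- rep(c("a", "b"), each = 5)
  t2 <- univariate_compare(d2, g2, "x")
  expect_equal(t2$p_value[1], 1)
  expect_equal(t2$test[1], "fisher")
})

test_that("logistic fit reproduces the closed-form 2x2 odds ratio exactly", {
  for (counts in list(c(20, 30, 15, 35), c(5, 45, 25, 25), c(60, 10, 30, 40))) {
    a <- counts[1]; b <- counts[2]; c_ <- counts[3]; d <- counts[4]
    x <- c(rep(1, a + b), rep(0, c_ + d))
    y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
    fit <- fit_logistic(y, data.frame(x = x))
    or_hat <- fit$table$or[fit$table$term == "x"]
    expect_lt(abs(or_hat - (a * d) / (b * c_)), 1e-8)
  }
})

test_that("glm route agrees with an independent Newton-Raphson fit", {
  set.seed(1234)
  n <- 100
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x1 - 0.5 * x2))
  fit <- fit_logistic(y, data.frame(x1 = x1, x2 = x2))
  X <- cbind(1, x1, x2)
  nr <- newton_logistic(X, y)
  expect_equal(fit$table$estimate, unname(nr$beta), tolerance = 1e-6)
  expect_equal(fit$table$se, unname(nr$se), tolerance = 1e-6)
})

test_that("logistic fit reports reference levels, CIs, and separation", {
  set.seed(77)
  n <- 400
  sex <- sample(c("male", "female"), n, replace = TRUE)
  y <- rbinom(n, 1, plogis(0.5 * (sex == "male")))
  fit <- fit_logistic(y, data.frame(sex = sex))
  expect_true(fit$converged)
  expect_true(all(fit$table$ci_lower <= fit$table$or + 1e-12))
  expect_true(all(fit$table$or <= fit$table$ci_upper + 1e-12))
  expect_true(any(fit$table$term == "sexmale"))  # female is the reference

  # balanced null: intercept near zero on the log-odds scale
  y0 <- rep(c(0, 1), 200)
  fit0 <- fit_logistic(y0, data.frame(x = rep(0, 400))[, 0, drop = FALSE])
  expect_lt(abs(fit0$table$estimate[1]), 1e-8)

  # complete separation flagged, not crashed
  xs <- c(rep(0, 20), rep(1, 20))
  ys <- xs
  fit_sep <- fit_logistic(ys, data.frame(x = xs))
  expect_false(fit_sep$converged)
  expect_match(fit_sep$diagnostic, "separation|converge")
})

test_that("disparity suite recovers planted effects and strata behave", {
  sim <- generate_cohort(generator_config(n_patients = 6000, seed = 31,
                                          p_text_present = 1,
                                          p_discordant = 0,
                                          p_prosthetic = 0))
  co <- sim$cohort
  # collapse demographic levels too rare to support stable Wald inference in
  # the ~11% sAS analysis population
  co$patients$race[co$patients$race %in% c("NHPI", "AIAN")] <- "Other"
  co$patients$insurance[co$patients$insurance %in%
                          c("HMO", "Medicaid", "MedicareAdvantage")] <- "Unknown"
  co$patients$sex[co$patients$sex == "other_unknown"] <- "female"
  res <- classify_cohort(co)
  dates <- stats::setNames(co$studies$study_date, co$studies$patient_id)
  st <- assign_treatment_status(co$patients, dates, as.Date("2024-06-10"))
  sas <- stats::setNames(res$classifications$is_sas,
                         co$studies$patient_id[match(res$classifications$study_id,
                                                     co$studies$study_id)])
  suite <- run_disparity_suite(co$patients, st, sas)
  expect_s3_class(suite$univariate_treatment, "univariate_table")
  expect_true(suite$model_all$converged)
  # planted male advantage (log-OR 0.419): estimate within 3 SE
  row <- suite$model_all$table[suite$model_all$table$term == "sexmale", ]
  expect_lt(abs(row$estimate - log(1.52)), 3 * row$se)
  # planted Medicare penalty
  row <- suite$model_all$table[suite$model_all$table$term == "insuranceMedicare", ]
  expect_lt(abs(row$estimate - log(0.48)), 3 * row$se)
  # SDoH-stratified model present and uses the HPI percentile
  expect_false(is.null(suite$model_sdoh))
  expect_true("hpi_percentile" %in% suite$model_sdoh$table$term)
  expect_lt(suite$model_sdoh$n, suite$model_all$n)

  # all SDoH missing: stratified model skipped with a note
  pts2 <- co$patients
  pts2$hpi_score <- NA_real_
  pts2$hpi_percentile <- NA_real_
  suite2 <- run_disparity_suite(pts2, st, sas)
  expect_null(suite2$model_sdoh)
  expect_match(paste(suite2$notes, collapse = " "), "SDoH")
})
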