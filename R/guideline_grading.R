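#' Quantitative AS grading against guideline threshold tables
#'
#' Quantitative grading maps the three standard continuous measures of
#' stenosis severity -- calculated aortic valve area (AVA, cm2), mean
#' transvalvular gradient (mmHg) and peak jet velocity (m/s) -- onto the
#' ordinal grade scale through a table of disjoint, exhaustive intervals per
#' parameter. The engine applies a strict fallback hierarchy: AVA when
#' recorded, else mean gradient, else (optionally) peak velocity. Boundary
#' values at severity-defining cut-points resolve toward the more severe
#' grade (AVA exactly 1.0 cm2 is severe; mean gradient exactly 40 mmHg is
#' severe), biasing the screening tool toward sensitivity.
#'
#' Quantitative grading never emits half-grades: the interval tables cover
#' only the full grades, and half-grades arise exclusively from the
#' qualitative text channel.
#'
#' @name guideline_grading
NULL

.threshold_params <- c("ava_cm2", "mean_gradient_mmhg", "peak_velocity_ms")

.interval_table <- function(lower, upper, lower_closed, upper_closed, grade) {
  data.frame(
    lower = lower, upper = upper,
    lower_closed = lower_closed, upper_closed = upper_closed,
    grade = grade, stringsAsFactors = FALSE
  )
}

#' Default guideline threshold table
#'
#' Default cut-points follow the contemporary valvular-heart-disease
#' guideline convention: severe AS at AVA <= 1.0 cm2, mean gradient >= 40
#' mmHg or peak velocity >= 4.0 m/s, with a "critical" stratum at the
#' extreme (AVA <= 0.6 cm2, gradient >= 60 mmHg, velocity >= 5.0 m/s) and
#' normal-range intervals mapping to grade none (AVA > 2.0 cm2, gradient
#' < 10 mmHg, velocity < 2.0 m/s). The table is plain data and is also
#' shipped as an editable YAML config (`system.file("extdata",
#' "thresholds.yaml", package = "echorules")`) because cut-point conventions
#' vary by site.
#'
#' @return A `threshold_table`: named list with one interval data frame per
#'   parameter (`ava_cm2`, `mean_gradient_mmhg`, `peak_velocity_ms`) and a
#'   `use_peak_velocity` flag controlling the tertiary fallback.
#' @examples
#' thr <- default_thresholds()
#' validate_thresholds(thr)
#' @export
default_thresholds <- function() {
  thr <- list(
    ava_cm2 = .interval_table(
      lower = c(0, 0.6, 1.0, 1.5, 2.0),
      upper = c(0.6, 1.0, 1.5, 2.0, Inf),
      lower_closed = c(TRUE, FALSE, FALSE, FALSE, FALSE),
      upper_closed = c(TRUE, TRUE, TRUE, TRUE, FALSE),
      grade = c("critical", "severe", "moderate", "mild", "none")
    ),
    mean_gradient_mmhg = .interval_table(
      lower = c(0, 10, 20, 40, 60),
      upper = c(10, 20, 40, 60, Inf),
      lower_closed = c(TRUE, TRUE, TRUE, TRUE, TRUE),
      upper_closed = c(FALSE, FALSE, FALSE, FALSE, FALSE),
      grade = c("none", "mild", "moderate", "severe", "critical")
    ),
    peak_velocity_ms = .interval_table(
      lower = c(0, 2.0, 3.0, 4.0, 5.0),
      upper = c(2.0, 3.0, 4.0, 5.0, Inf),
      lower_closed = c(TRUE, TRUE, TRUE, TRUE, TRUE),
      upper_closed = c(FALSE, FALSE, FALSE, FALSE, FALSE),
      grade = c("none", "mild", "moderate", "severe", "critical")
    ),
    use_peak_velocity = TRUE
  )
  class(thr) <- "threshold_table"
  thr
}

#' Read a threshold table from a YAML config
#'
#' @param path Path to a YAML file with one block per parameter, each a list
#'   of intervals (`lower`, `upper`, `lower_closed`, `upper_closed`,
#'   `grade`; `upper: .inf` for unbounded), plus `use_peak_velocity`.
#' @return A validated `threshold_table`.
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  thr <- lapply(.threshold_params, function(p) {
    if (is.null(cfg[[p]])) stop("threshold config missing parameter block: ", p)
    rows <- cfg[[p]]
    .interval_table(
      lower = vapply(rows, function(r) as.numeric(r$lower), numeric(1)),
      upper = vapply(rows, function(r) as.numeric(r$upper), numeric(1)),
      lower_closed = vapply(rows, function(r) isTRUE(r$lower_closed), logical(1)),
      upper_closed = vapply(rows, function(r) isTRUE(r$upper_closed), logical(1)),
      grade = vapply(rows, function(r) as.character(r$grade), character(1))
    )
  })
  names(thr) <- .threshold_params
  thr$use_peak_velocity <- isTRUE(cfg$use_peak_velocity)
  class(thr) <- "threshold_table"
  validate_thresholds(thr)
  thr
}

#' Validate a threshold table
#'
#' Asserts, for every parameter, that the intervals are pairwise disjoint,
#' exhaustive over `[0, Inf)`, and monotone in severity (more abnormal
#' values never map to a less severe grade). Configuration errors fail fast
#' here, never at grading time.
#'
#' @param thresholds A `threshold_table`.
#' @return `TRUE` invisibly; otherwise an error naming the offending
#'   parameter and interval pair.
#' @export
validate_thresholds <- function(thresholds) {
  if (!inherits(thresholds, "threshold_table")) {
    stop("not a threshold_table")
  }
  for (p in .threshold_params) {
    tab <- thresholds[[p]]
    if (is.null(tab) || nrow(tab) == 0L) stop("no intervals for parameter ", p)
    check_grades(tab$grade)
    ord <- order(tab$lower, tab$upper)
    tab <- tab[ord, , drop = FALSE]
    if (!(tab$lower[1] <= 0 && (tab$lower_closed[1] || tab$lower[1] < 0))) {
      stop(p, ": intervals do not cover 0")
    }
    if (is.finite(tab$upper[nrow(tab)])) {
      stop(p, ": intervals do not extend to +Inf (gap above ",
           tab$upper[nrow(tab)], ")")
    }
    if (nrow(tab) > 1L) {
      for (i in seq_len(nrow(tab) - 1L)) {
        lo_next <- tab$lower[i + 1L]
        up <- tab$upper[i]
        # adjacency: upper_i == lower_{i+1} with exactly one side closed
        if (up < lo_next || (up == lo_next && !tab$upper_closed[i] && !tab$lower_closed[i + 1L])) {
          stop(p, ": gap between intervals ", i, " and ", i + 1L,
               " (", up, ", ", lo_next, ")")
        }
        if (up > lo_next || (up == lo_next && tab$upper_closed[i] && tab$lower_closed[i + 1L])) {
          stop(p, ": overlapping intervals ", i, " and ", i + 1L)
        }
      }
      r <- grade_rank(tab$grade)
      severity_increases_with_value <- p != "ava_cm2"
      d <- diff(r)
      if (severity_increases_with_value && any(d < 0)) {
        stop(p, ": grades not monotone non-decreasing in value")
      }
      if (!severity_increases_with_value && any(d > 0)) {
        stop(p, ": grades not monotone non-increasing in value")
      }
    }
  }
  invisible(TRUE)
}

.lookup_interval <- function(tab, x) {
  ge_lo <- ifelse(tab$lower_closed, x >= tab$lower, x > tab$lower)
  le_up <- ifelse(tab$upper_closed, x <= tab$upper, x < tab$upper)
  hit <- which(ge_lo & le_up)
  if (length(hit) != 1L) {
    stop("value ", x, " matched ", length(hit),
         " intervals; threshold table not validated?")
  }
  tab$grade[hit]
}

#' Grade one study from quantitative measurements
#'
#' Applies the AVA-first hierarchy: the grade comes from AVA when recorded;
#' otherwise from the mean gradient; otherwise, if the tertiary fallback is
#' enabled in the table (`use_peak_velocity`), from the peak velocity. When
#' a parameter determines the grade, values of the lower-priority parameters
#' never influence the result.
#'
#' @param study A one-row study data frame (or list) with numeric fields
#'   `ava_cm2`, `mean_gradient_mmhg`, `peak_velocity_ms` (`NA` = not
#'   recorded).
#' @param thresholds A validated `threshold_table`.
#' @return A list with `grade` (grade label, or `NA` when no usable
#'   measurement exists) and `parameter` (which measurement determined it,
#'   or `NA`).
#' @examples
#' grade_quantitative(list(ava_cm2 = 0.8), default_thresholds())
#' @export
grade_quantitative <- function(study, thresholds = default_thresholds()) {
  val <- function(f) {
    v <- study[[f]]
    if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v[[1]])
  }
  order_used <- c("ava_cm2", "mean_gradient_mmhg")
  if (isTRUE(thresholds$use_peak_velocity)) {
    order_used <- c(order_used, "peak_velocity_ms")
  }
  for (p in order_used) {
    x <- val(p)
    if (!is.na(x)) {
      return(list(grade = .lookup_interval(thresholds[[p]], x), parameter = p))
    }
  }
  list(grade = NA_character_, parameter = NA_character_)
}
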