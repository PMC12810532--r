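#' Ordinal aortic stenosis severity scale
#'
#' The engine grades AS on a seven-level ordinal scale including the
#' half-grades routinely used by reading echocardiographers
#' ("mild to moderate", "moderate to severe"). Each level carries a numeric
#' rank so that grade distances are well defined; adjacent full grades differ
#' by 1 and a half-grade sits 0.5 between its neighbours.
#'
#' @return Character vector of the seven grade labels, ordered from least to
#'   most severe.
#' @examples
#' grade_levels()
#' grade_rank("moderate_to_severe")
#' @export
grade_levels <- function() {
  c("none", "mild", "mild_to_moderate", "moderate",
    "moderate_to_severe", "severe", "critical")
}

.grade_ranks <- c(
  none = 0, mild = 1, mild_to_moderate = 1.5, moderate = 2,
  moderate_to_severe = 2.5, severe = 3, critical = 3.5
)

#' Numeric rank of an AS grade
#'
#' @param grade Character vector of grade labels (see [grade_levels()]);
#'   `NA` entries stay `NA`.
#' @return Numeric vector of ranks (none = 0 ... critical = 3.5).
#' @export
grade_rank <- function(grade) {
  if (length(grade) == 0L) return(numeric(0))
  bad <- !is.na(grade) & !grade %in% names(.grade_ranks)
  if (any(bad)) {
    stop("unknown AS grade label(s): ", paste(unique(grade[bad]), collapse = ", "))
  }
  unname(.grade_ranks[match(grade, names(.grade_ranks))])
}

#' Validate grade labels
#'
#' @param grade Character vector; `NA` allowed.
#' @return The input, invisibly, after checking every non-missing entry is a
#'   known grade label.
#' @keywords internal
check_grades <- function(grade) {
  grade_rank(grade)
  invisible(grade)
}

# Rank at or above which a grade counts as sAS (moderate-to-severe or worse).
.sas_rank <- 2.5

#' Dichotomize a grade at the sAS boundary
#'
#' "sAS" denotes AS of grade moderate-to-severe or worse, the severity band
#' for which valve replacement is guideline-recommended. An absent
#' (ungradeable) grade is never sAS.
#'
#' @param grade Character vector of grade labels, `NA` for ungradeable.
#' @return Logical vector: `TRUE` iff the grade is present and ranks at or
#'   above moderate-to-severe.
#' @examples
#' dichotomize(c("moderate", "moderate_to_severe", NA))
#' @export
dichotomize <- function(grade) {
  r <- grade_rank(grade)
  !is.na(r) & r >= .sas_rank
}
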