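#' Rule-based extraction from echo-report free text
#'
#' The qualitative channel of the engine is a deterministic pattern lexicon
#' over report conclusions. It recovers four signals: a severity mention on
#' the ordinal grade scale (including half-grades such as "moderate to
#' severe"), leaflet-restriction and abnormal-gradient comments (detection
#' cues that never map to a grade by themselves), and prosthetic-valve
#' mentions used for study exclusion. Negation is handled NegEx-style: a cue
#' ("no", "without", "absence of", ...) negates matches within a forward
#' window of tokens, with the scope terminated at sentence punctuation.
#' "Aortic sclerosis" alone is deliberately absent from the lexicon --
#' sclerosis without stenosis is a distinct entity and must not create a
#' false positive.
#'
#' @name report_nlp
NULL

#' Read a severity lexicon from a YAML config
#'
#' Patterns are compiled (and therefore syntax-checked) at load; a malformed
#' pattern is a configuration failure here, never a match-time error.
#'
#' @param path Path to a lexicon YAML (see the shipped
#'   `extdata/lexicon.yaml` for the schema: `severity` entries with
#'   `id`/`pattern`/`grade`/`priority`, `negation_cues`, `generic_as`,
#'   `leaflet_restriction`, `abnormal_gradient`, `prosthetic` pattern lists,
#'   and the integer `scope_window`).
#' @return A validated `severity_lexicon` object.
#' @export
read_lexicon <- function(path) {
  cfg <- yaml::read_yaml(path)
  sev <- cfg$severity
  if (is.null(sev) || length(sev) == 0L) stop("lexicon has no severity entries")
  entries <- data.frame(
    id = vapply(sev, function(e) as.character(e$id), character(1)),
    pattern = vapply(sev, function(e) as.character(e$pattern), character(1)),
    grade = vapply(sev, function(e) as.character(e$grade), character(1)),
    priority = vapply(sev, function(e) as.integer(e$priority), integer(1)),
    stringsAsFactors = FALSE
  )
  check_grades(entries$grade)
  if (anyDuplicated(entries$priority)) stop("severity priorities must be unique")
  if (anyDuplicated(entries[c("pattern", "grade")])) {
    stop("duplicate (pattern, grade) severity entry")
  }
  lex <- list(
    entries = entries,
    negation_cues = as.character(unlist(cfg$negation_cues)),
    generic_as = as.character(unlist(cfg$generic_as)),
    leaflet_restriction = as.character(unlist(cfg$leaflet_restriction)),
    abnormal_gradient = as.character(unlist(cfg$abnormal_gradient)),
    prosthetic = as.character(unlist(cfg$prosthetic)),
    scope_window = as.integer(cfg$scope_window %||% 6L)
  )
  for (p in c(lex$entries$pattern, lex$negation_cues, lex$generic_as,
              lex$leaflet_restriction, lex$abnormal_gradient, lex$prosthetic)) {
    ok <- tryCatch({
      gregexpr(p, "probe text", ignore.case = TRUE, perl = TRUE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("malformed lexicon pattern: ", p)
  }
  class(lex) <- "severity_lexicon"
  lex
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default shipped lexicon
#'
#' @return The `severity_lexicon` read from the package's
#'   `extdata/lexicon.yaml`.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.yaml",
                           package = "echorules", mustWork = TRUE))
}

# All matches of one pattern: data.frame(start, end) in character offsets.
.match_all <- function(text, pattern) {
  m <- gregexpr(pattern, text, ignore.case = TRUE, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
}

.match_patterns <- function(text, patterns, ids = patterns) {
  out <- lapply(seq_along(patterns), function(i) {
    hits <- .match_all(text, patterns[i])
    if (nrow(hits)) hits$pattern_id <- ids[i]
    hits
  })
  out <- out[vapply(out, nrow, integer(1)) > 0L]
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      pattern_id = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Character ranges negated by a forward-scoping cue. Scope runs from the cue
# over the next `window` tokens, stopping at sentence punctuation (. ; :).
.negation_scopes <- function(text, cues, window) {
  cue_hits <- .match_patterns(text, cues)
  if (!nrow(cue_hits)) return(cue_hits[c("start", "end")])
  tok <- .match_all(text, "[A-Za-z0-9/']+")
  bounds <- .match_all(text, "[.;:]")
  scopes <- lapply(seq_len(nrow(cue_hits)), function(i) {
    e <- cue_hits$end[i]
    following <- which(tok$start > e)
    if (!length(following)) return(NULL)
    take <- following[seq_len(min(window, length(following)))]
    scope_end <- tok$end[take[length(take)]]
    wall <- bounds$start[bounds$start > e]
    if (length(wall)) scope_end <- min(scope_end, wall[1] - 1L)
    if (scope_end <= e) return(NULL)
    c(start = e + 1L, end = scope_end)
  })
  scopes <- scopes[!vapply(scopes, is.null, logical(1))]
  if (!length(scopes)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  as.data.frame(do.call(rbind, scopes))
}

.in_scope <- function(starts, scopes) {
  if (!length(starts)) return(logical(0))
  if (!nrow(scopes)) return(rep(FALSE, length(starts)))
  vapply(starts, function(s) any(s >= scopes$start & s <= scopes$end), logical(1))
}

# Drop matches strictly contained in a longer match, so "moderate to severe
# aortic stenosis" is not also read as "severe aortic stenosis".
.suppress_contained <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  len <- hits$end - hits$start
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    !any(hits$start <= hits$start[i] & hits$end >= hits$end[i] &
           (hits$end - hits$start) > len[i])
  }, logical(1))
  hits[keep, , drop = FALSE]
}

.empty_finding <- function() {
  structure(list(
    severity_mention = NA_character_,
    leaflet_restriction = FALSE,
    abnormal_gradient_comment = FALSE,
    prosthetic_mention = FALSE,
    negated_as = FALSE,
    matched_spans = data.frame(start = integer(0), end = integer(0),
                               pattern_id = character(0),
                               stringsAsFactors = FALSE)
  ), class = "qualitative_finding")
}

#' Extract qualitative findings from one report text
#'
#' Deterministic, case-insensitive extraction. When several severity phrases
#' survive negation and containment resolution, the most severe one wins --
#' the engine is a screening tool for which a missed severe stenosis is the
#' costly error. `negated_as` is `TRUE` when the text explicitly denies
#' stenosis and carries no non-negated severity mention; in that case
#' `severity_mention` is always absent.
#'
#' @param text A single report string (may be empty or `NA`).
#' @param lexicon A `severity_lexicon`.
#' @return A `qualitative_finding`: list with `severity_mention` (grade
#'   label or `NA`), logical `leaflet_restriction`,
#'   `abnormal_gradient_comment`, `prosthetic_mention`, `negated_as`, and a
#'   `matched_spans` data frame (start, end, pattern_id) for audit.
#' @examples
#' lex <- default_lexicon()
#' extract_findings("Moderate to severe aortic stenosis.", lex)$severity_mention
#' extract_findings("No aortic stenosis.", lex)$negated_as
#' @export
extract_findings <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "severity_lexicon"))
  if (is.null(text) || length(text) == 0L || is.na(text) || !nzchar(text)) {
    return(.empty_finding())
  }
  text <- as.character(text)
  scopes <- .negation_scopes(text, lexicon$negation_cues, lexicon$scope_window)

  sev_hits <- .match_patterns(text, lexicon$entries$pattern, lexicon$entries$id)
  sev_hits <- .suppress_contained(sev_hits)
  if (nrow(sev_hits)) {
    idx <- match(sev_hits$pattern_id, lexicon$entries$id)
    sev_hits$grade <- lexicon$entries$grade[idx]
    sev_hits$priority <- lexicon$entries$priority[idx]
    sev_hits$negated <- .in_scope(sev_hits$start, scopes)
  }

  flag_hits <- function(patterns, prefix) {
    hits <- .match_patterns(text, patterns,
                            paste0(prefix, "_", seq_along(patterns)))
    if (nrow(hits)) hits$negated <- .in_scope(hits$start, scopes)
    hits
  }
  leaf <- flag_hits(lexicon$leaflet_restriction, "leaflet")
  grad <- flag_hits(lexicon$abnormal_gradient, "gradient")
  pros <- flag_hits(lexicon$prosthetic, "prosthetic")
  gen <- flag_hits(lexicon$generic_as, "generic_as")

  active_sev <- if (nrow(sev_hits))
    sev_hits[!sev_hits$negated, , drop = FALSE] else sev_hits
  severity <- NA_character_
  if (nrow(active_sev)) {
    severity <- active_sev$grade[which.max(active_sev$priority)]
  }
  negated_as <- is.na(severity) && nrow(gen) > 0 && any(gen$negated)

  spans <- rbind(
    if (nrow(sev_hits)) sev_hits[c("start", "end", "pattern_id")],
    if (nrow(leaf)) leaf[c("start", "end", "pattern_id")],
    if (nrow(grad)) grad[c("start", "end", "pattern_id")],
    if (nrow(pros)) pros[c("start", "end", "pattern_id")]
  )
  if (is.null(spans)) spans <- .empty_finding()$matched_spans
  stopifnot(all(spans$end <= nchar(text)))

  structure(list(
    severity_mention = severity,
    leaflet_restriction = nrow(leaf) > 0 && any(!leaf$negated),
    abnormal_gradient_comment = nrow(grad) > 0 && any(!grad$negated),
    prosthetic_mention = nrow(pros) > 0 && any(!pros$negated),
    negated_as = negated_as,
    matched_spans = spans
  ), class = "qualitative_finding")
}

#' Detect a prosthetic aortic valve mention
#'
#' @param text A single report string.
#' @param lexicon A `severity_lexicon`.
#' @return `TRUE` iff a prosthetic/bioprosthesis/mechanical-valve or
#'   post-replacement phrase matches outside negation scope.
#' @export
detect_prosthetic <- function(text, lexicon) {
  extract_findings(text, lexicon)$prosthetic_mention
}

#' @export
print.qualitative_finding <- function(x, ...) {
  cat("Qualitative echo-report finding\n")
  cat("  severity mention :", ifelse(is.na(x$severity_mention), "<absent>",
                                     x$severity_mention), "\n")
  cat("  negated AS       :", x$negated_as, "\n")
  cat("  leaflet restr.   :", x$leaflet_restriction, "\n")
  cat("  abnormal gradient:", x$abnormal_gradient_comment, "\n")
  cat("  prosthetic       :", x$prosthetic_mention, "\n")
  cat("  matched spans    :", nrow(x$matched_spans), "\n")
  invisible(x)
}
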