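#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper around the base Wilcoxon rank-sum machinery exposing the two
#' modes used for biomarker screening: `exact` uses the exact U distribution
#' (equivalent to enumerating all C(n+m, n) group labelings) and is forced
#' to the normal approximation, with mid-rank tie handling and continuity
#' correction, whenever ties are present; `normal_approx` always uses the
#' approximation.
#'
#' @param x,y Numeric replicate vectors (each of length >= 3 for biomarker
#'   use; >= 1 accepted here).
#' @param mode `"exact"` or `"normal_approx"`.
#' @return A list with `U`, `p` (two-sided) and `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    stop_mixtox("Both groups must be non-empty.", "mixtoxsys_usage_error")
  }
  ties <- any(duplicated(c(x, y)))
  exact <- mode == "exact" && !ties
  if (mode == "exact" && ties) {
    inform("Ties present: falling back to the normal approximation.",
           class = "mixtoxsys_tie_fallback")
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Convert a biomarker comparison into an alteration level
#'
#' A biomarker is unaltered (AL0) when the exposed and control replicates do
#' not differ (Mann-Whitney p >= alpha). A significant change is AL1, and it
#' escalates to AL2 (severe) when the median fractional change, taken in the
#' biomarker's harmful direction, reaches the biomarker-specific severity
#' threshold.
#'
#' @param exposed,control Numeric replicate vectors (>= 3 each).
#' @param harmful_direction `"decrease"` or `"increase"`: the direction of
#'   change that indicates harm (e.g. decrease for membrane stability,
#'   increase for lipid accumulation).
#' @param severity_threshold Fractional change marking severe alteration
#'   (0.5 = 50%).
#' @param alpha Significance level.
#' @return A tibble with `al` (`"AL0"`, `"AL1"`, `"AL2"`), `p` and
#'   `fractional_change` (signed, positive in the harmful direction).
#' @export
alteration_level <- function(exposed, control,
                             harmful_direction = c("decrease", "increase"),
                             severity_threshold = 1, alpha = 0.05) {
  harmful_direction <- match.arg(harmful_direction)
  if (length(exposed) < 3 || length(control) < 3) {
    stop_mixtox("At least 3 replicates per group are required.",
                "mixtoxsys_validation_error")
  }
  med_c <- median(control)
  if (med_c == 0) {
    stop_mixtox("Control median is zero: fractional change is undefined.",
                "mixtoxsys_normalization_error")
  }
  mw <- mann_whitney_u(exposed, control, mode = "exact")
  fc <- (median(exposed) - med_c) / med_c
  harm <- if (harmful_direction == "decrease") -fc else fc
  al <- if (mw$p >= alpha) "AL0"
  else if (harm >= severity_threshold) "AL2"
  else "AL1"
  tibble::tibble(al = al, p = mw$p, fractional_change = harm)
}

#' Default biomarker metadata for the digestive-gland / gill battery
#'
#' Ships the conventional battery: lysosomal membrane stability (LMS, the
#' guide biomarker, cell level, harmful when decreased, severe at a 50%
#' reduction of labilization time), lysosome/cytoplasm volume ratio
#' (LYS/CYT, cell level, harmful when increased), neutral-lipid accumulation
#' (NL, tissue level, harmful when increased) and gill acetylcholinesterase
#' activity (AChE, organism level, harmful when inhibited). Severity
#' thresholds other than the LMS 50% default to a 100% change. All fields
#' can be overridden by supplying a modified tibble.
#'
#' @return A tibble with columns `biomarker`, `level`, `harmful_direction`,
#'   `severity_threshold`, `guide`.
#' @export
biomarker_defaults <- function() {
  tibble::tibble(
    biomarker = c("LMS", "LYS/CYT", "NL", "AChE"),
    level = c("cell", "cell", "tissue", "organism"),
    harmful_direction = c("decrease", "increase", "increase", "decrease"),
    severity_threshold = c(0.5, 1, 1, 1),
    guide = c(TRUE, FALSE, FALSE, FALSE)
  )
}

#' Default rule table of the health-status expert system
#'
#' Five ordered "if ... then ..." rules grade the stress syndrome from A
#' (healthy) to E (pathologically stressed), driven by the number of altered
#' biomarkers, the severity of the alterations and the biological
#' organisation level (cell < tissue < organism) they span:
#' \itemize{
#'   \item E: the guide biomarker is severely altered (AL2) and at least two
#'     further biomarkers are AL2.
#'   \item D: at least two AL2 biomarkers spanning at least two organisation
#'     levels.
#'   \item C: any AL2, or at least two altered biomarkers of which at least
#'     one is above the cell level.
#'   \item B: any alteration.
#'   \item A: no alteration.
#' }
#' Rules are evaluated first-match from most to least severe; every
#' predicate is monotone in the alteration levels, so raising any single AL
#' can never improve the grade. Conditions are R expressions over the
#' summary variables `n_al1`, `n_al2`, `n_altered`, `n_altered_above_cell`,
#' `n_levels_al2`, `guide_al` and can be replaced wholesale by a custom
#' table (validated by [validate_rule_table()]).
#'
#' @return A tibble with columns `id`, `grade`, `condition`.
#' @export
default_rule_table <- function() {
  tibble::tribble(
    ~id,  ~grade, ~condition,
    "E1", "E", "guide_al == 2 & n_al2 >= 3",
    "D1", "D", "n_al2 >= 2 & n_levels_al2 >= 2",
    "C1", "C", "n_al2 >= 1",
    "C2", "C", "n_altered >= 2 & n_altered_above_cell >= 1",
    "B1", "B", "n_altered >= 1",
    "A1", "A", "TRUE"
  )
}

#' Validate a health-status rule table
#'
#' Checks required columns, known grades, parseable conditions and
#' exhaustiveness (the last rule must be a catch-all `TRUE`).
#'
#' @param rules A rule-table tibble (see [default_rule_table()]).
#' @return The validated table, invisibly; errors otherwise.
#' @export
validate_rule_table <- function(rules) {
  check_columns(rules, c("id", "grade", "condition"), "rule table")
  if (!all(rules$grade %in% LETTERS[1:5])) {
    stop_mixtox("Rule grades must be within A-E.", "mixtoxsys_validation_error")
  }
  parsed <- tryCatch(lapply(rules$condition, function(s) parse(text = s)),
                     error = function(e) NULL)
  if (is.null(parsed)) {
    stop_mixtox("Rule conditions must be parseable R expressions.",
                "mixtoxsys_validation_error")
  }
  last <- trimws(rules$condition[nrow(rules)])
  if (last != "TRUE") {
    stop_mixtox("Rule table is not exhaustive: last rule must be 'TRUE'.",
                "mixtoxsys_validation_error")
  }
  invisible(rules)
}

al_to_int <- function(al) match(al, c("AL0", "AL1", "AL2")) - 1L

#' Grade a panel of alteration levels with the rule-based expert system
#'
#' The core engine behind [health_status_index()], usable directly when the
#' alteration levels are already known.
#'
#' @param als Tibble with columns `biomarker`, `level` (cell/tissue/
#'   organism), `al` (`"AL0"`/`"AL1"`/`"AL2"`) and optionally `guide`
#'   (logical; defaults to no guide biomarker).
#' @param rules Rule table (default [default_rule_table()]).
#' @return List with `grade` and `triggered_rules` (first matching rule id).
#' @export
grade_panel <- function(als, rules = default_rule_table()) {
  check_columns(als, c("biomarker", "level", "al"), "alteration panel")
  validate_rule_table(rules)
  if (nrow(als) == 0) {
    stop_mixtox("Panel must contain at least one biomarker.",
                "mixtoxsys_validation_error")
  }
  ali <- al_to_int(als$al)
  if (any(is.na(ali))) {
    stop_mixtox("Alteration levels must be AL0, AL1 or AL2.",
                "mixtoxsys_validation_error")
  }
  guide <- if ("guide" %in% names(als)) als$guide else rep(FALSE, nrow(als))
  env <- list(
    n_al1 = sum(ali == 1L),
    n_al2 = sum(ali == 2L),
    n_altered = sum(ali >= 1L),
    n_altered_above_cell = sum(ali >= 1L & als$level != "cell"),
    n_levels_al2 = length(unique(als$level[ali == 2L])),
    guide_al = if (any(guide)) max(ali[guide]) else 0L
  )
  for (i in seq_len(nrow(rules))) {
    hit <- isTRUE(eval(parse(text = rules$condition[i]), envir = env))
    if (hit) {
      return(list(grade = rules$grade[i], triggered_rules = rules$id[i]))
    }
  }
  stop_mixtox("No rule matched (rule table not exhaustive).",
              "mixtoxsys_validation_error")
}

#' Health status index (A-E) from a biomarker panel
#'
#' Tests each biomarker against its control with the exact Mann-Whitney U
#' test, converts significant changes into alteration levels via the
#' per-biomarker severity thresholds, and grades the stress syndrome with
#' the rule-based expert system.
#'
#' @param panel Long-format tibble with columns `biomarker`, `group`
#'   (`"control"`/`"exposed"`) and `value`.
#' @param meta Biomarker metadata ([biomarker_defaults()] layout); rows are
#'   matched to `panel` by `biomarker` name.
#' @param rules Rule table (default [default_rule_table()]).
#' @param alpha Significance level for the alteration calls.
#' @return A `mixtox_hsi` object with `grade`, `triggered_rules` and the
#'   `per_biomarker` tibble of alteration levels.
#' @export
health_status_index <- function(panel, meta = biomarker_defaults(),
                                rules = default_rule_table(), alpha = 0.05) {
  check_columns(panel, c("biomarker", "group", "value"), "biomarker panel")
  check_columns(meta, c("biomarker", "level", "harmful_direction",
                        "severity_threshold", "guide"), "biomarker metadata")
  if (sum(meta$guide) > 1) {
    stop_mixtox("At most one guide biomarker is allowed per panel.",
                "mixtoxsys_validation_error")
  }
  biomarkers <- unique(panel$biomarker)
  missing <- setdiff(biomarkers, meta$biomarker)
  if (length(missing) > 0) {
    stop_mixtox(sprintf("No metadata for biomarker(s): %s",
                        paste(missing, collapse = ", ")),
                "mixtoxsys_validation_error")
  }
  per <- purrr::map_dfr(biomarkers, function(bm) {
    m <- meta[meta$biomarker == bm, ]
    ex <- panel$value[panel$biomarker == bm & panel$group == "exposed"]
    ct <- panel$value[panel$biomarker == bm & panel$group == "control"]
    alr <- alteration_level(ex, ct, m$harmful_direction,
                            m$severity_threshold, alpha)
    tibble::tibble(biomarker = bm, level = m$level, guide = m$guide,
                   al = alr$al, p = alr$p,
                   fractional_change = alr$fractional_change)
  })
  g <- grade_panel(per, rules)
  structure(
    list(grade = g$grade, triggered_rules = g$triggered_rules,
         per_biomarker = per, alpha = alpha),
    class = "mixtox_hsi"
  )
}

#' @export
print.mixtox_hsi <- function(x, ...) {
  cat(sprintf("Health status index: %s (rule %s)\n", x$grade,
              x$triggered_rules))
  print(x$per_biomarker)
  invisible(x)
}
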