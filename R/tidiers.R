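# broom-style tidiers for the fitted objects

#' @export
tidy.mixtox_drc <- function(x, ...) {
  tibble::tibble(
    term = c("theta_max", "theta_min", "ec50", "beta"),
    estimate = c(x$theta_max, x$theta_min, x$ec50, x$beta)
  )
}

#' @export
glance.mixtox_drc <- function(x, ...) {
  fs <- x$fit_stats
  tibble::tibble(
    chemical = x$chemical, direction = x$direction,
    SS_res = fs$SS_res %||% NA_real_, R2 = fs$R2 %||% NA_real_,
    n = fs$n %||% NA_integer_
  )
}

#' @export
tidy.mixtox_surface <- function(x, ...) {
  p <- x$params
  terms <- c("theta_max", "ec50_1", "beta_1", "ec50_2", "beta_2")
  est <- c(p$theta_max, p$ec50_1, p$beta_1, p$ec50_2, p$beta_2)
  if (!is.null(p$a)) { terms <- c(terms, "a"); est <- c(est, p$a) }
  if (!is.null(p$b)) { terms <- c(terms, "b"); est <- c(est, p$b) }
  tibble::tibble(term = terms, estimate = est)
}

#' @export
glance.mixtox_surface <- function(x, ...) {
  tibble::tibble(
    model_type = x$model_type, deviation = x$params$deviation_kind,
    SS_res = x$SS_res, R2 = x$R2, logLik = x$logLik,
    p_regression = x$p_regression, k_params = x$k_params, n = x$n
  )
}

#' Tidy summary of an interaction ladder
#'
#' One row per step of the nested deviation ladder (reference fit, SA
#' extension, DL extension) with the fit quality and LR-test columns laid
#' out like a published interaction-testing table.
#'
#' @param x A `mixtox_interaction` object.
#' @param ... Unused.
#' @export
tidy.mixtox_interaction <- function(x, ...) {
  f <- x$fits; t <- x$tests
  tibble::tibble(
    step = c(paste("Fit of", x$framework),
             paste(x$framework, "vs A"), "A vs DL"),
    R2 = c(f$reference$R2, f$SA$R2, f$DL$R2),
    chi2 = c(NA, t$ref_vs_A$chi2, t$A_vs_DL$chi2),
    df = c(NA, t$ref_vs_A$df, t$A_vs_DL$df),
    p = c(f$reference$p_regression, t$ref_vs_A$p, t$A_vs_DL$p)
  )
}

#' @export
glance.mixtox_interaction <- function(x, ...) {
  tibble::tibble(
    framework = x$framework, pattern = x$pattern,
    dose_level_dependent = x$dose_level_dependent,
    a_hat = x$supporting$a_hat, b_hat = x$supporting$b_hat,
    p_ref_vs_A = x$supporting$p_ref_vs_A,
    p_A_vs_DL = x$supporting$p_A_vs_DL, alpha = x$alpha
  )
}

#' @export
tidy.mixtox_elimination <- function(x, ...) {
  tibble::tibble(term = c("k", "C0"), estimate = c(x$k, x$C0))
}

#' @export
glance.mixtox_elimination <- function(x, ...) {
  tibble::tibble(
    chemical = x$chemical, k = x$k, C0 = x$C0, R2 = x$R2,
    half_life = x$half_life, no_elimination = x$no_elimination,
    method = x$method, n = x$n
  )
}

#' @export
tidy.mixtox_hsi <- function(x, ...) x$per_biomarker

#' @export
glance.mixtox_hsi <- function(x, ...) {
  tibble::tibble(grade = x$grade, triggered_rules = x$triggered_rules,
                 n_biomarkers = nrow(x$per_biomarker), alpha = x$alpha)
}

#' @export
tidy.mixtox_overlap <- function(x, ...) {
  dplyr::left_join(x$sizes, x$unique, by = "condition")
}
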