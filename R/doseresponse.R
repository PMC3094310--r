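#' Fit a log-logistic dose-response curve
#'
#' Fits the two- or three-parameter log-logistic model by least squares.
#' For a decreasing endpoint (e.g. % labilization time of the lysosomal
#' membrane) the expected response is
#' \deqn{y(c) = \theta_{min} + \frac{\theta_{max}-\theta_{min}}{1+(c/EC_{50})^\beta}}
#' so the control response (c = 0) is \eqn{\theta_{max}} and the response at
#' \eqn{c = EC_{50}} is the midpoint. For an increasing endpoint (e.g. lipid
#' accumulation) the curve rises from \eqn{\theta_{min}} at c = 0 towards
#' \eqn{\theta_{max}}. Errors are assumed additive Gaussian on the response
#' scale, so least squares is maximum likelihood and nested fits can be
#' compared by likelihood ratio downstream.
#'
#' Optimisation is multi-start Nelder-Mead (EC50 seeds spread over the tested
#' concentration range crossed with slope seeds 0.5/1/2/4) followed by a BFGS
#' polish, on the scale (theta, log EC50, log beta).
#'
#' @param data A data frame with columns `concentration` and `response`
#'   (optionally `chemical` and `replicate`). Must contain a control
#'   (concentration 0) and at least 3 distinct concentrations.
#' @param direction `"decreasing"` or `"increasing"`.
#' @param theta_min Fixed lower asymptote (default 0). Ignored when
#'   `theta_min_free = TRUE`.
#' @param theta_min_free Estimate the lower asymptote as a free parameter.
#'   Requires at least 4 distinct concentrations.
#' @param n_starts Number of multi-starts (default 8).
#'
#' @return An object of class `mixtox_drc` with elements `theta_max`,
#'   `theta_min`, `ec50`, `beta`, `direction`, `chemical`, `fit_stats`
#'   (`SS_res`, `R2`, `n`) and `data`.
#' @examples
#' d <- gen_dose_response(loglogistic_model(100, 1, 2), doses = c(0, 0.25, 0.5, 1, 2, 4),
#'                        n_per_dose = 3, noise_sd = 4, seed = 1)
#' fit <- fit_loglogistic(d)
#' tidy(fit)
#' ec_x(fit, c(12.5, 25, 50))
#' @export
fit_loglogistic <- function(data, direction = c("decreasing", "increasing"),
                            theta_min = 0, theta_min_free = FALSE,
                            n_starts = 8) {
  direction <- match.arg(direction)
  check_columns(data, c("concentration", "response"), "dose-response data")
  conc <- data$concentration
  resp <- data$response
  validate_dose_response(conc, resp)
  n_distinct_conc <- length(unique(conc))
  if (isTRUE(all.equal(min(resp), max(resp)))) {
    stop_mixtox("All responses are equal: curve parameters are not identifiable.",
                "mixtoxsys_identifiability_error")
  }
  if (theta_min_free && n_distinct_conc < 4) {
    stop_mixtox(
      "Freeing the lower asymptote needs at least 4 distinct concentrations.",
      "mixtoxsys_identifiability_error"
    )
  }

  pos <- conc[conc > 0]
  ec50_seeds <- exp(seq(log(min(pos)), log(max(pos)), length.out = max(2, ceiling(n_starts / 4))))
  beta_seeds <- c(0.5, 1, 2, 4)
  starts <- expand.grid(ec50 = ec50_seeds, beta = beta_seeds)
  starts <- starts[seq_len(min(nrow(starts), n_starts)), , drop = FALSE]

  theta_max0 <- if (direction == "decreasing") max(resp) else max(resp)
  theta_min0 <- min(resp)

  obj <- function(p) {
    tmax <- p[1]
    tmin <- if (theta_min_free) p[2] else theta_min
    e <- exp(p[if (theta_min_free) 3 else 2])
    b <- exp(p[if (theta_min_free) 4 else 3])
    sum((resp - loglogistic_curve(conc, tmax, tmin, e, b, direction))^2)
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- if (theta_min_free) {
      c(theta_max0, theta_min0, log(starts$ec50[i]), log(starts$beta[i]))
    } else {
      c(theta_max0, log(starts$ec50[i]), log(starts$beta[i]))
    }
    fit <- tryCatch({
      nm <- optim(p0, obj, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
      optim(nm$par, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12))
    }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop_mixtox("Log-logistic fit did not converge from any start.",
                "mixtoxsys_convergence_error")
  }

  p <- best$par
  tmax <- p[1]
  tmin <- if (theta_min_free) p[2] else theta_min
  ec50 <- exp(p[if (theta_min_free) 3 else 2])
  beta <- exp(p[if (theta_min_free) 4 else 3])
  ss_res <- best$value
  ss_tot <- sum((resp - mean(resp))^2)
  chem <- if ("chemical" %in% names(data)) as.character(data$chemical[1]) else NA_character_

  structure(
    list(
      theta_max = tmax, theta_min = tmin, ec50 = ec50, beta = beta,
      direction = direction, chemical = chem,
      fit_stats = list(SS_res = ss_res, R2 = 1 - ss_res / ss_tot, n = length(resp)),
      data = tibble::as_tibble(data)
    ),
    class = "mixtox_drc"
  )
}

validate_dose_response <- function(conc, resp) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop_mixtox("Concentrations must be finite and non-negative.",
                "mixtoxsys_validation_error")
  }
  if (any(!is.finite(resp))) {
    stop_mixtox("Responses must be finite.", "mixtoxsys_validation_error")
  }
  if (!any(conc == 0)) {
    stop_mixtox("A control (concentration 0) is required.",
                "mixtoxsys_validation_error")
  }
  if (length(unique(conc)) < 3) {
    stop_mixtox("At least 3 distinct concentrations are required.",
                "mixtoxsys_validation_error")
  }
  invisible(TRUE)
}

loglogistic_curve <- function(conc, theta_max, theta_min, ec50, beta, direction) {
  q <- 1 / (1 + (conc / ec50)^beta)
  if (direction == "decreasing") theta_min + (theta_max - theta_min) * q
  else theta_min + (theta_max - theta_min) * (1 - q)
}

#' Construct a log-logistic model directly from its parameters
#'
#' Useful to set up generating models for the synthetic-data functions or to
#' encode published curve parameters.
#'
#' @param theta_max Upper asymptote (response at the unharmed extreme for a
#'   decreasing endpoint).
#' @param ec50 Median effective concentration (same units as the data).
#' @param beta Positive slope parameter.
#' @param theta_min Lower asymptote (default 0).
#' @param direction `"decreasing"` or `"increasing"`.
#' @param chemical Optional chemical label.
#' @return A `mixtox_drc` object without fit statistics.
#' @export
loglogistic_model <- function(theta_max, ec50, beta, theta_min = 0,
                              direction = c("decreasing", "increasing"),
                              chemical = NA_character_) {
  direction <- match.arg(direction)
  if (!is.numeric(ec50) || ec50 <= 0) {
    stop_mixtox("`ec50` must be positive.", "mixtoxsys_validation_error")
  }
  if (!is.numeric(beta) || beta <= 0) {
    stop_mixtox("`beta` must be positive.", "mixtoxsys_validation_error")
  }
  if (theta_max == theta_min) {
    stop_mixtox("`theta_max` must differ from `theta_min`.",
                "mixtoxsys_validation_error")
  }
  structure(
    list(theta_max = theta_max, theta_min = theta_min, ec50 = ec50,
         beta = beta, direction = direction, chemical = chemical,
         fit_stats = NULL, data = NULL),
    class = "mixtox_drc"
  )
}

#' @export
predict.mixtox_drc <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration
  else if (is.data.frame(newdata)) newdata$concentration
  else newdata
  loglogistic_curve(conc, object$theta_max, object$theta_min, object$ec50,
                    object$beta, object$direction)
}

#' @export
print.mixtox_drc <- function(x, ...) {
  cat("Log-logistic dose-response model",
      if (!is.na(x$chemical)) paste0(" [", x$chemical, "]"), "\n", sep = "")
  cat(sprintf("  direction: %s\n", x$direction))
  cat(sprintf("  theta_max = %.4g, theta_min = %.4g, EC50 = %.4g, beta = %.4g\n",
              x$theta_max, x$theta_min, x$ec50, x$beta))
  if (!is.null(x$fit_stats)) {
    cat(sprintf("  n = %d, SS_res = %.4g, R2 = %.4f\n",
                x$fit_stats$n, x$fit_stats$SS_res, x$fit_stats$R2))
  }
  invisible(x)
}

#' Invert a log-logistic model to effective concentrations (ECx)
#'
#' Closed-form inversion \eqn{EC_x = EC_{50} (x/(100-x))^{1/\beta}}. The
#' effect level x is the percentage of the maximal effect
#' (\eqn{\theta_{max}\to\theta_{min}} span), for either direction.
#'
#' @param model A `mixtox_drc` object.
#' @param x Effect level(s) in percent, strictly between 0 and 100.
#' @return A tibble with columns `x` and `concentration`.
#' @export
ec_x <- function(model, x) {
  stopifnot(inherits(model, "mixtox_drc"))
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 100)) {
    stop_mixtox("Effect level `x` must lie strictly between 0 and 100.",
                "mixtoxsys_domain_error")
  }
  tibble::tibble(
    x = x,
    concentration = model$ec50 * (x / (100 - x))^(1 / model$beta)
  )
}

#' Express a concentration in toxic units
#'
#' One toxic unit is the model's EC50, so `TU = c / EC50`.
#'
#' @param concentration Non-negative concentration(s).
#' @param model A `mixtox_drc` object.
#' @return Numeric vector of toxic units.
#' @export
toxic_units <- function(concentration, model) {
  stopifnot(inherits(model, "mixtox_drc"))
  if (any(concentration < 0)) {
    stop_mixtox("Concentrations must be non-negative.", "mixtoxsys_domain_error")
  }
  concentration / model$ec50
}

#' Design an equitoxic mixture at a nominal toxic-unit level
#'
#' Builds the fixed equitoxic design in which the nominal toxic units are
#' shared equally by the k mixture components, each contributing its
#' EC(50 TU / k) under the TU-to-ECx labelling convention (0.25 TU for a
#' single chemical is its EC12.5, 0.5 TU its EC25, 1.0 TU its EC50). A
#' binary mixture at 1.0 nominal TU therefore pairs the two EC25s, and at
#' 0.5 TU the two EC12.5s; a "mixture" of one chemical at 1.0 TU is simply
#' its EC50.
#'
#' @param models Named list of `mixtox_drc` objects (one per chemical), or
#'   `NULL` when `ecx_table` is supplied.
#' @param tu_level Nominal toxic-unit level of the whole mixture;
#'   `50 * tu_level / k` must lie in (0, 100).
#' @param ecx_table Optional lookup table with columns `chemical`, `x`,
#'   `concentration` (takes precedence over model inversion; useful to
#'   encode published effective-concentration tables).
#' @return A tibble with columns `tu_level`, `chemical`, `concentration`.
#' @export
design_equitoxic_mixture <- function(models = NULL, tu_level, ecx_table = NULL) {
  if (!is.numeric(tu_level) || length(tu_level) != 1 || tu_level <= 0) {
    stop_mixtox("`tu_level` must be a positive number.",
                "mixtoxsys_domain_error")
  }
  k <- if (!is.null(ecx_table)) length(unique(ecx_table$chemical))
  else length(models)
  if (k == 0) {
    stop_mixtox("Provide a named list of models or an `ecx_table`.",
                "mixtoxsys_lookup_error")
  }
  x <- 50 * tu_level / k
  if (x <= 0 || x >= 100) {
    stop_mixtox("`tu_level` must satisfy 0 < 50 * tu_level / k < 100.",
                "mixtoxsys_domain_error")
  }
  if (!is.null(ecx_table)) {
    check_columns(ecx_table, c("chemical", "x", "concentration"), "ECx table")
    hit <- ecx_table[abs(ecx_table$x - x) < 1e-9, , drop = FALSE]
    missing <- setdiff(unique(ecx_table$chemical), hit$chemical)
    if (length(missing) > 0) {
      stop_mixtox(sprintf("No EC%.4g entry for chemical(s): %s", x,
                          paste(missing, collapse = ", ")),
                  "mixtoxsys_lookup_error")
    }
    return(tibble::tibble(tu_level = tu_level, chemical = hit$chemical,
                          concentration = hit$concentration))
  }
  if (is.null(names(models))) {
    stop_mixtox("`models` must be a named list.", "mixtoxsys_lookup_error")
  }
  conc <- vapply(models, function(m) ec_x(m, x)$concentration, numeric(1))
  tibble::tibble(tu_level = tu_level, chemical = names(models),
                 concentration = unname(conc))
}
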