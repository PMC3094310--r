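#' Fit a first-order elimination (depuration) model
#'
#' Fits \eqn{C_t = C_0 e^{-kt}} to a tissue-concentration time course taken
#' after transfer to clean water. The default `log_linear` method regresses
#' \eqn{\ln C_t} on t by ordinary least squares (k = -slope, closed form,
#' maximum likelihood under multiplicative lognormal noise); `nonlinear`
#' refits on the raw concentration scale seeded by the log-linear estimates.
#'
#' @param data Data frame with columns `time` (days) and `concentration`
#'   (> 0), optionally `chemical`. Times must be strictly increasing with at
#'   least 3 points.
#' @param method `"log_linear"` or `"nonlinear"`.
#' @return A `mixtox_elimination` object with `k` (per day), `C0`, `R2`
#'   (log scale for `log_linear`, raw scale otherwise), `half_life`
#'   (ln 2 / k, `NA` when k <= 0), `no_elimination` flag, `method`, `n`.
#' @examples
#' d <- gen_elimination(k = 0.047, C0 = 12, times = c(0.125, 0.25, 0.5, 1, 3, 6),
#'                      noise_cv = 0, seed = 1)
#' fit_elimination(d)
#' @export
fit_elimination <- function(data, method = c("log_linear", "nonlinear")) {
  method <- match.arg(method)
  check_columns(data, c("time", "concentration"), "elimination series")
  t <- data$time
  conc <- data$concentration
  if (length(t) < 3) {
    stop_mixtox("At least 3 time points are required.",
                "mixtoxsys_validation_error")
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop_mixtox("Times must be strictly increasing.",
                "mixtoxsys_validation_error")
  }
  if (any(conc <= 0)) {
    stop_mixtox("Concentrations must be positive for the exponential model.",
                "mixtoxsys_domain_error")
  }
  chem <- if ("chemical" %in% names(data)) as.character(data$chemical[1]) else NA_character_

  logc <- log(conc)
  flat <- isTRUE(all.equal(var(logc), 0))
  if (flat) {
    fit <- list(k = 0, C0 = conc[1], R2 = 0)
    warn("Concentrations are constant: no elimination detected (k = 0).",
         class = "mixtoxsys_no_elimination")
  } else {
    ll <- lm(logc ~ t)
    k_ll <- -unname(coef(ll)[2])
    c0_ll <- exp(unname(coef(ll)[1]))
    if (method == "log_linear") {
      r2 <- suppressWarnings(summary(ll)$r.squared)
      fit <- list(k = k_ll, C0 = c0_ll, R2 = r2)
    } else {
      obj <- function(p) sum((conc - exp(p[1]) * exp(-p[2] * t))^2)
      op <- optim(c(log(c0_ll), k_ll), obj, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-14))
      ss_tot <- sum((conc - mean(conc))^2)
      fit <- list(k = op$par[2], C0 = exp(op$par[1]),
                  R2 = 1 - op$value / ss_tot)
    }
    if (fit$k <= 0 && !flat) {
      warn("Fitted elimination constant is non-positive (no depuration).",
           class = "mixtoxsys_no_elimination")
    }
  }

  structure(
    list(chemical = chem, k = fit$k, C0 = fit$C0, R2 = fit$R2,
         half_life = if (fit$k > 0) log(2) / fit$k else NA_real_,
         no_elimination = fit$k <= 0, method = method, n = length(t),
         data = tibble::as_tibble(data)),
    class = "mixtox_elimination"
  )
}

#' Elimination half-life
#'
#' @param k Positive first-order elimination rate constant (per day).
#' @return Half-life in days, `ln(2)/k`.
#' @export
half_life <- function(k) {
  if (any(!is.numeric(k)) || any(k <= 0)) {
    stop_mixtox("Half-life requires k > 0.", "mixtoxsys_domain_error")
  }
  log(2) / k
}

#' @export
print.mixtox_elimination <- function(x, ...) {
  cat("First-order elimination fit",
      if (!is.na(x$chemical)) paste0(" [", x$chemical, "]"), "\n", sep = "")
  cat(sprintf("  k = %.4g d^-1, C0 = %.4g, R2 = %.3f (%s, n = %d)\n",
              x$k, x$C0, x$R2, x$method, x$n))
  if (x$no_elimination) cat("  flag: no elimination (k <= 0)\n")
  else cat(sprintf("  half-life = %.3g d\n", x$half_life))
  invisible(x)
}
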