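#' Deviation term G for mixture response surfaces
#'
#' The reference Concentration-Addition (CA) and Independent-Action (IA)
#' surfaces assume non-interaction. Interaction is encoded by a parametric
#' deviation term G added on the appropriate scale of each reference model:
#' \itemize{
#'   \item `none`: G = 0 (reference).
#'   \item `SA` (synergism/antagonism): \eqn{G = a z_1 z_2}. Positive `a`
#'     lifts the surface towards lower toxicity (antagonism), negative `a`
#'     towards synergism.
#'   \item `DR` (dose-ratio dependent): \eqn{G = (a + b z_1) z_1 z_2}.
#'   \item `DL` (dose-level dependent): \eqn{G = a z_1 z_2 (1 - b\,TU_{tot})},
#'     which changes sign at a total dose of 1/b toxic units.
#' }
#' Here \eqn{z_i} is chemical i's share of the total toxic units and
#' \eqn{TU_{tot}} the summed toxic units, so G vanishes on the
#' single-chemical axes and the surfaces collapse to the component curves.
#'
#' @param a Deviation magnitude.
#' @param b Dose-ratio / dose-level modifier (required for `DR` and `DL`).
#' @param z1,z2 Toxic-unit shares of the two chemicals (non-negative; sum to
#'   1 whenever both doses are positive).
#' @param tu_total Total toxic units (used by `DL` only).
#' @param kind One of `"none"`, `"SA"`, `"DR"`, `"DL"`.
#' @return Numeric vector of deviation values.
#' @export
deviation_g <- function(a = 0, b = NULL, z1, z2, tu_total = 0,
                        kind = c("none", "SA", "DR", "DL")) {
  kind <- match.arg(kind)
  if (kind %in% c("DR", "DL") && is.null(b)) {
    stop_mixtox(sprintf("Deviation kind '%s' requires parameter `b`.", kind),
                "mixtoxsys_parameter_error")
  }
  switch(kind,
         none = rep(0, length(z1)),
         SA   = a * z1 * z2,
         DR   = (a + b * z1) * z1 * z2,
         DL   = a * z1 * z2 * (1 - b * tu_total))
}

#' Construct mixture response-surface parameters
#'
#' Bundles the single-chemical log-logistic parameters of both mixture
#' components (shared upper asymptote, per-chemical EC50 and slope) with an
#' optional deviation term. Responses are modelled on the decreasing effect
#' scale (response falls from `theta_max` towards 0 with dose).
#'
#' @param theta_max Shared control-level response.
#' @param ec50_1,beta_1 Log-logistic parameters of chemical 1.
#' @param ec50_2,beta_2 Log-logistic parameters of chemical 2.
#' @param deviation_kind `"none"`, `"SA"`, `"DR"` or `"DL"`.
#' @param a,b Deviation parameters (see [deviation_g()]).
#' @return A `surface_params` list.
#' @export
surface_params <- function(theta_max, ec50_1, beta_1, ec50_2, beta_2,
                           deviation_kind = c("none", "SA", "DR", "DL"),
                           a = NULL, b = NULL) {
  deviation_kind <- match.arg(deviation_kind)
  if (any(c(ec50_1, ec50_2, beta_1, beta_2) <= 0)) {
    stop_mixtox("EC50 and beta parameters must be positive.",
                "mixtoxsys_validation_error")
  }
  if (deviation_kind != "none" && is.null(a)) {
    stop_mixtox("Deviation models require parameter `a`.",
                "mixtoxsys_parameter_error")
  }
  if (deviation_kind %in% c("DR", "DL") && is.null(b)) {
    stop_mixtox(sprintf("Deviation kind '%s' requires parameter `b`.",
                        deviation_kind), "mixtoxsys_parameter_error")
  }
  if (deviation_kind == "none") a <- b <- NULL
  if (deviation_kind == "SA") b <- NULL
  structure(
    list(theta_max = theta_max, ec50_1 = ec50_1, beta_1 = beta_1,
         ec50_2 = ec50_2, beta_2 = beta_2, deviation_kind = deviation_kind,
         a = a, b = b),
    class = "surface_params"
  )
}

n_surface_params <- function(params) {
  5L + as.integer(!is.null(params$a)) + as.integer(!is.null(params$b))
}

surface_g <- function(params, c1, c2) {
  tu1 <- c1 / params$ec50_1
  tu2 <- c2 / params$ec50_2
  tu <- tu1 + tu2
  z1 <- ifelse(tu > 0, tu1 / tu, 0)
  z2 <- ifelse(tu > 0, tu2 / tu, 0)
  deviation_g(a = params$a %||% 0, b = params$b, z1 = z1, z2 = z2,
              tu_total = tu, kind = params$deviation_kind)
}

#' Predict the Concentration-Addition surface
#'
#' For each dose pair, solves the implicit CA relation
#' \deqn{\frac{c_1}{EC_{y,1}} + \frac{c_2}{EC_{y,2}} = e^{G}}
#' for the response y, where \eqn{EC_{y,i} = EC_{50,i}
#' ((\theta_{max}-y)/y)^{1/\beta_i}} is the concentration of chemical i alone
#' giving response y. With G = 0 this is classical concentration addition
#' (toxic units summing to one on iso-effect contours); the deviation term
#' tilts the iso-boles. The root is found by monotone bisection (vectorised
#' over points) to a tolerance well below 1e-8 * theta_max.
#'
#' @param params A `surface_params` object.
#' @param c1,c2 Dose vectors (recycled to common length).
#' @return Predicted responses.
#' @export
predict_ca <- function(params, c1, c2) {
  stopifnot(inherits(params, "surface_params"))
  n <- max(length(c1), length(c2))
  c1 <- rep_len(c1, n); c2 <- rep_len(c2, n)
  tm <- params$theta_max
  tu1 <- c1 / params$ec50_1
  tu2 <- c2 / params$ec50_2
  out <- rep(tm, n)
  act <- which(tu1 + tu2 > 0)
  if (length(act) == 0) return(out)
  eg <- exp(surface_g(params, c1[act], c2[act]))
  # solve tu1 * s^(1/b1) + tu2 * s^(1/b2) = exp(G) for s = y/(tm - y),
  # strictly increasing in s: bisection on t = log(s)
  t1 <- tu1[act]; t2 <- tu2[act]
  ib1 <- 1 / params$beta_1; ib2 <- 1 / params$beta_2
  lo <- rep(-60, length(act)); hi <- rep(60, length(act))
  f <- function(t) t1 * exp(t * ib1) + t2 * exp(t * ib2) - eg
  if (any(f(lo) > 0) || any(f(hi) < 0)) {
    stop_mixtox("CA bisection bracket failed to enclose a root.",
                "mixtoxsys_numerical_error",
                diagnostics = list(tu1 = t1, tu2 = t2, expG = eg))
  }
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    pos <- f(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  s <- exp((lo + hi) / 2)
  out[act] <- tm * s / (1 + s)
  out
}

#' Predict the Independent-Action surface
#'
#' The IA reference multiplies the unaffected fractions of the two
#' chemicals: \eqn{y = \theta_{max} q_1(c_1) q_2(c_2)} with
#' \eqn{q_i = 1/(1+(c_i/EC_{50,i})^{\beta_i})}. Deviations act as a power
#' transform, \eqn{y = \theta_{max} (q_1 q_2)^{\exp(-G)}}: G = 0 recovers
#' the reference and positive G (antagonism) raises the surface.
#'
#' @inheritParams predict_ca
#' @return Predicted responses in `[0, theta_max]`.
#' @export
predict_ia <- function(params, c1, c2) {
  stopifnot(inherits(params, "surface_params"))
  n <- max(length(c1), length(c2))
  c1 <- rep_len(c1, n); c2 <- rep_len(c2, n)
  q1 <- 1 / (1 + (c1 / params$ec50_1)^params$beta_1)
  q2 <- 1 / (1 + (c2 / params$ec50_2)^params$beta_2)
  g <- surface_g(params, c1, c2)
  params$theta_max * (q1 * q2)^(exp(-g))
}

predict_surface <- function(params, model_type, c1, c2) {
  if (model_type == "CA") predict_ca(params, c1, c2)
  else predict_ia(params, c1, c2)
}

# hot path used inside the optimiser: raw parameter values, no object
# construction or validation per evaluation
g_raw <- function(kind, a, b, z1, z2, tu) {
  switch(kind,
         none = 0,
         SA   = a * z1 * z2,
         DR   = (a + b * z1) * z1 * z2,
         DL   = a * z1 * z2 * (1 - b * tu))
}

predict_surface_raw <- function(model_type, kind, tm, e1, b1, e2, b2, a, b,
                                c1, c2) {
  if (!all(is.finite(c(tm, e1, b1, e2, b2, a, b))) ||
      e1 <= 0 || e2 <= 0 || b1 <= 0 || b2 <= 0) {
    return(rep(NA_real_, max(length(c1), length(c2))))
  }
  tu1 <- c1 / e1
  tu2 <- c2 / e2
  tu <- tu1 + tu2
  pos <- tu > 0
  z1 <- ifelse(pos, tu1 / tu, 0)
  z2 <- ifelse(pos, tu2 / tu, 0)
  g <- g_raw(kind, a, b, z1, z2, tu)
  if (model_type == "IA") {
    q1 <- 1 / (1 + tu1^b1)
    q2 <- 1 / (1 + tu2^b2)
    return(tm * (q1 * q2)^(exp(-g)))
  }
  out <- rep(tm, length(tu))
  act <- which(pos)
  if (length(act) == 0) return(out)
  eg <- exp(if (length(g) > 1) g[act] else g)
  t1 <- tu1[act]; t2 <- tu2[act]
  ib1 <- 1 / b1; ib2 <- 1 / b2
  lo <- rep(-60, length(act)); hi <- rep(60, length(act))
  # exponent capped at 700 so axis points (t = 0) never produce 0 * Inf
  fval <- function(t) {
    t1 * exp(pmin(t * ib1, 700)) + t2 * exp(pmin(t * ib2, 700)) - eg
  }
  if (any(fval(lo) > 0) || any(fval(hi) < 0)) {
    return(rep(NA_real_, length(tu)))
  }
  for (i in 1:42) {
    mid <- (lo + hi) / 2
    up <- fval(mid) > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
  }
  s <- exp((lo + hi) / 2)
  out[act] <- tm * s / (1 + s)
  out
}

# ---- fitting ---------------------------------------------------------------

surface_par_vec <- function(params) {
  p <- c(params$theta_max, log(params$ec50_1), log(params$beta_1),
         log(params$ec50_2), log(params$beta_2))
  if (!is.null(params$a)) p <- c(p, params$a)
  if (!is.null(params$b)) p <- c(p, params$b)
  p
}

surface_par_unvec <- function(p, deviation_kind) {
  a <- b <- NULL
  if (deviation_kind == "SA") a <- p[6]
  if (deviation_kind %in% c("DR", "DL")) { a <- p[6]; b <- p[7] }
  surface_params(theta_max = p[1], ec50_1 = exp(p[2]), beta_1 = exp(p[3]),
                 ec50_2 = exp(p[4]), beta_2 = exp(p[5]),
                 deviation_kind = deviation_kind, a = a, b = b)
}

# axis-informed starting values: on each single-chemical margin the
# log-logistic linearises as logit((tm - y)/tm) = beta (log c - log ec50),
# so a simple regression gives (ec50, beta) seeds; controls give theta_max
surface_start <- function(data) {
  resp <- data$response
  ctrl <- resp[data$c1 == 0 & data$c2 == 0]
  tm0 <- if (length(ctrl) > 0) mean(ctrl) else max(resp)
  tm_eff <- max(tm0, max(resp) * 1.001)
  axis_seed <- function(cc, keep) {
    sub <- data[keep & data[[cc]] > 0, , drop = FALSE]
    pos_all <- data[[cc]][data[[cc]] > 0]
    out <- c(ec50 = if (length(pos_all)) exp(mean(log(pos_all))) else 1,
             beta = 1)
    if (nrow(sub) >= 2) {
      eff <- pmin(pmax((tm_eff - sub$response) / tm_eff, 0.02), 0.98)
      lg <- log(eff / (1 - eff))
      fit <- tryCatch(lm(lg ~ log(sub[[cc]])), error = function(e) NULL)
      if (!is.null(fit) && is.finite(coef(fit)[2]) && coef(fit)[2] > 0.05) {
        b <- unname(coef(fit)[2])
        out <- c(ec50 = exp(-unname(coef(fit)[1]) / b), beta = b)
      }
    }
    out
  }
  a1 <- axis_seed("c1", data$c2 == 0)
  a2 <- axis_seed("c2", data$c1 == 0)
  list(theta_max = tm0, ec50_1 = a1[["ec50"]], beta_1 = a1[["beta"]],
       ec50_2 = a2[["ec50"]], beta_2 = a2[["beta"]])
}

#' Fit a CA or IA response surface to pooled mixture + axis data
#'
#' Jointly estimates the shared upper asymptote, both single-chemical curves
#' and (optionally) the deviation parameters by least squares over all
#' points of a mixture design (single-chemical axis rows are rows with one
#' concentration equal to zero). Starting values come from single-chemical
#' fits on the axes; deviation fits are warm-started from their parent
#' reference fit so the nested sum of squares never exceeds the parent's.
#'
#' @param data Data frame with columns `c1`, `c2`, `response`.
#' @param model_type `"CA"` or `"IA"`.
#' @param deviation_kind `"none"`, `"SA"`, `"DR"` or `"DL"`.
#' @param warm_start Optional `surface_params` (or `mixtox_surface` fit) used
#'   as an additional start, e.g. the parent fit in the nested ladder.
#' @param n_starts Extra jittered starts around the axis-informed seed.
#' @return A `mixtox_surface` object with the fitted `params`, `SS_res`,
#'   `n`, `k_params`, `logLik`, `R2` and the regression F-test p-value
#'   against the grand-mean model (`p_regression`).
#' @export
fit_surface <- function(data, model_type = c("CA", "IA"),
                        deviation_kind = c("none", "SA", "DR", "DL"),
                        warm_start = NULL, n_starts = 4) {
  model_type <- match.arg(model_type)
  deviation_kind <- match.arg(deviation_kind)
  check_columns(data, c("c1", "c2", "response"), "mixture data")
  if (any(data$c1 < 0 | data$c2 < 0) || any(!is.finite(data$response))) {
    stop_mixtox("Doses must be non-negative and responses finite.",
                "mixtoxsys_validation_error")
  }
  n <- nrow(data)
  k <- 5L + (deviation_kind != "none") + (deviation_kind %in% c("DR", "DL"))
  if (n <= k) {
    stop_mixtox(sprintf("Need more points (n = %d) than parameters (k = %d).",
                        n, k), "mixtoxsys_validation_error")
  }
  if (deviation_kind != "none" && !any(data$c1 > 0 & data$c2 > 0)) {
    stop_mixtox("Deviation models need at least one interior mixture point.",
                "mixtoxsys_validation_error")
  }
  if (inherits(warm_start, "mixtox_surface")) warm_start <- warm_start$params

  resp <- data$response
  c1 <- data$c1; c2 <- data$c2
  kind <- deviation_kind
  has_a <- kind != "none"
  has_b <- kind %in% c("DR", "DL")
  obj <- function(p) {
    pr <- predict_surface_raw(
      model_type, kind, p[1], exp(p[2]), exp(p[3]), exp(p[4]), exp(p[5]),
      if (has_a) p[6] else 0, if (has_b) p[7] else 0, c1, c2)
    if (anyNA(pr)) return(1e30)
    sum((resp - pr)^2)
  }

  dev_pad <- switch(deviation_kind, none = numeric(0), SA = 0, DR = c(0, 0),
                    DL = c(0, 0))
  starts <- list()
  if (!is.null(warm_start)) {
    wp <- c(warm_start$theta_max, log(warm_start$ec50_1),
            log(warm_start$beta_1), log(warm_start$ec50_2),
            log(warm_start$beta_2))
    wa <- warm_start$a %||% 0
    wb <- warm_start$b %||% 0
    pad <- switch(deviation_kind, none = numeric(0), SA = wa, DR = c(wa, wb),
                  DL = c(wa, wb))
    starts <- c(starts, list(c(wp, pad)))
    if (deviation_kind == "SA") {
      starts <- c(starts, list(c(wp, 2)), list(c(wp, -2)))
    }
    if (deviation_kind %in% c("DR", "DL")) {
      starts <- c(starts, list(c(wp, wa, 0.5)), list(c(wp, wa, -0.5)))
    }
  }
  base_par <- NULL
  if (is.null(warm_start) || n_starts > length(starts)) {
    st <- surface_start(data)
    base_par <- c(st$theta_max, log(st$ec50_1), log(st$beta_1),
                  log(st$ec50_2), log(st$beta_2))
    starts <- c(starts, list(c(base_par, dev_pad)))
  }
  while (length(starts) < n_starts) {
    jit <- (base_par %||% starts[[1]][1:5]) + c(0, rnorm(4, sd = 0.3))
    starts <- c(starts, list(c(jit, dev_pad)))
  }
  starts <- starts[seq_len(min(length(starts), max(n_starts, 1)))]

  # per start: quasi-Newton descent (cheap, smooth objective), then a short
  # simplex pass to step off any ridge, then a final quasi-Newton polish
  best <- NULL
  diagnostics <- list()
  for (p0 in starts) {
    fit <- tryCatch({
      bf <- tryCatch(
        optim(p0, obj, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) list(par = p0, value = obj(p0)))
      nm <- optim(bf$par, obj, method = "Nelder-Mead",
                  control = list(maxit = 1500, reltol = 1e-10))
      if (nm$value < bf$value) nm else bf
    }, error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      diagnostics <- c(diagnostics, list(list(start = p0, error = fit)))
      next
    }
    diagnostics <- c(diagnostics, list(list(start = p0, SS = fit$value,
                                            convergence = fit$convergence)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e29) {
    stop_mixtox("Surface fit failed to converge from any start.",
                "mixtoxsys_convergence_error", diagnostics = diagnostics)
  }
  pol <- tryCatch(optim(best$par, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12)),
                  error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) best <- pol

  params <- surface_par_unvec(best$par, deviation_kind)
  ss_res <- best$value
  ss_tot <- sum((resp - mean(resp))^2)
  loglik <- -(n / 2) * (log(2 * pi * ss_res / n) + 1)
  # regression F-test of the fitted surface against the grand-mean model
  f_stat <- ((ss_tot - ss_res) / (k - 1)) / (ss_res / (n - k))
  p_reg <- pf(f_stat, k - 1, n - k, lower.tail = FALSE)

  structure(
    list(model_type = model_type, params = params, SS_res = ss_res, n = n,
         k_params = k, logLik = loglik, R2 = 1 - ss_res / ss_tot,
         p_regression = p_reg, data = tibble::as_tibble(data)),
    class = "mixtox_surface"
  )
}

#' @export
print.mixtox_surface <- function(x, ...) {
  p <- x$params
  cat(sprintf("%s response surface (deviation: %s)\n", x$model_type,
              p$deviation_kind))
  cat(sprintf("  theta_max = %.4g; EC50 = (%.4g, %.4g); beta = (%.4g, %.4g)\n",
              p$theta_max, p$ec50_1, p$ec50_2, p$beta_1, p$beta_2))
  if (!is.null(p$a)) cat(sprintf("  a = %.4g", p$a))
  if (!is.null(p$b)) cat(sprintf(", b = %.4g", p$b))
  if (!is.null(p$a)) cat("\n")
  cat(sprintf("  n = %d, k = %d, SS_res = %.4g, R2 = %.4f, logLik = %.3f\n",
              x$n, x$k_params, x$SS_res, x$R2, x$logLik))
  invisible(x)
}

#' Likelihood-ratio test between two nested surface fits
#'
#' For Gaussian errors with profiled variance the deviance difference is
#' \eqn{\chi^2 = n \ln(SS_{reduced}/SS_{full})} on \eqn{\Delta k} degrees of
#' freedom (clipped at zero if the optimizer left the full fit marginally
#' worse).
#'
#' @param reduced,full `mixtox_surface` fits on the same data, with
#'   `reduced$k_params < full$k_params`.
#' @return A tibble with `chi2`, `df` and `p`.
#' @export
lr_test <- function(reduced, full) {
  stopifnot(inherits(reduced, "mixtox_surface"), inherits(full, "mixtox_surface"))
  if (reduced$n != full$n) {
    stop_mixtox("Fits being compared use different numbers of points.",
                "mixtoxsys_usage_error")
  }
  if (reduced$k_params >= full$k_params) {
    stop_mixtox("`reduced` must have fewer parameters than `full`.",
                "mixtoxsys_usage_error")
  }
  chi2 <- max(0, reduced$n * log(reduced$SS_res / full$SS_res))
  df <- full$k_params - reduced$k_params
  tibble::tibble(chi2 = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Classify the mixture interaction via the nested deviation ladder
#'
#' Runs the reference fit, the synergism/antagonism (SA) extension and the
#' dose-level (DL) extension, then tests reference vs SA and SA vs DL by
#' likelihood ratio. The verdict is antagonism when the SA term is needed
#' (p < alpha) with a > 0, synergism when a < 0, and dose-level dependence
#' when the DL extension is itself supported.
#'
#' @param data Data frame with columns `c1`, `c2`, `response`.
#' @param framework `"CA"` or `"IA"`.
#' @param alpha Significance level (default 0.05).
#' @param n_starts Multi-start budget passed to each [fit_surface()] call
#'   (smaller values speed up simulation studies; deviation fits always
#'   retain their parent warm start, preserving the nesting).
#' @return A `mixtox_interaction` object carrying the three fits, both LR
#'   tests and a verdict; `tidy()` gives a Table-style summary.
#' @export
classify_interaction <- function(data, framework = c("CA", "IA"),
                                 alpha = 0.05, n_starts = 4) {
  framework <- match.arg(framework)
  if (!is_prob(alpha)) {
    stop_mixtox("`alpha` must be in (0, 1).", "mixtoxsys_validation_error")
  }
  ref <- fit_surface(data, framework, "none", n_starts = n_starts)
  sa <- fit_surface(data, framework, "SA", warm_start = ref,
                    n_starts = n_starts)
  dl <- fit_surface(data, framework, "DL", warm_start = sa,
                    n_starts = n_starts)
  t_ref_sa <- lr_test(ref, sa)
  t_sa_dl <- lr_test(sa, dl)
  a_hat <- sa$params$a
  b_hat <- dl$params$b
  pattern <- if (t_ref_sa$p < alpha) {
    if (a_hat > 0) "antagonism" else "synergism"
  } else "no_interaction"
  structure(
    list(framework = framework, alpha = alpha,
         pattern = pattern,
         dose_level_dependent = t_sa_dl$p < alpha,
         supporting = list(p_ref_vs_A = t_ref_sa$p, p_A_vs_DL = t_sa_dl$p,
                           a_hat = a_hat, b_hat = b_hat),
         fits = list(reference = ref, SA = sa, DL = dl),
         tests = list(ref_vs_A = t_ref_sa, A_vs_DL = t_sa_dl)),
    class = "mixtox_interaction"
  )
}

#' @export
print.mixtox_interaction <- function(x, ...) {
  cat(sprintf("Mixture interaction assessment (%s framework, alpha = %g)\n",
              x$framework, x$alpha))
  cat(sprintf("  Fit of %s:  R2 = %.2f, P = %.3g\n", x$framework,
              x$fits$reference$R2, x$fits$reference$p_regression))
  cat(sprintf("  %s vs A:    R2 = %.2f, chi2 = %.3g, P = %.3g\n", x$framework,
              x$fits$SA$R2, x$tests$ref_vs_A$chi2, x$tests$ref_vs_A$p))
  cat(sprintf("  A vs DL:    R2 = %.2f, chi2 = %.3g, P = %.3g\n",
              x$fits$DL$R2, x$tests$A_vs_DL$chi2, x$tests$A_vs_DL$p))
  cat(sprintf("  verdict: %s%s (a_hat = %.3g)\n", x$pattern,
              if (x$dose_level_dependent) ", dose-level dependent" else "",
              x$supporting$a_hat))
  invisible(x)
}
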