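test_that("deviation term has the documented closed forms", {
  expect_equal(deviation_g(a = 0, z1 = 0.3, z2 = 0.7, kind = "SA"), 0)
  expect_equal(deviation_g(a = 2, z1 = 0.5, z2 = 0.5, kind = "SA"), 0.5)
  expect_equal(deviation_g(a = 2, b = 1, z1 = 0.5, z2 = 0.5, tu_total = 1,
                           kind = "DL"), 0)
  expect_equal(deviation_g(a = 1.5, b = 2, z1 = 0.4, z2 = 0.6, kind = "DR"),
               (1.5 + 2 * 0.4) * 0.4 * 0.6)
  expect_error(deviation_g(a = 1, z1 = 0.5, z2 = 0.5, kind = "DL"),
               class = "mixtoxsys_parameter_error")

  # dose-level deviation changes sign exactly at TU_total = 1/b
  tus <- seq(0.1, 3, by = 0.01)
  g <- deviation_g(a = 2, b = 1, z1 = 0.5, z2 = 0.5, tu_total = tus,
                   kind = "DL")
  expect_true(all(g[tus < 1] > 0))
  expect_true(all(g[tus > 1] < 0))
})

test_that("CA surface honours sham combination and axis reduction", {
  p <- surface_params(100, 1, 2, 1, 2)
  expect_equal(predict_ca(p, 0.5, 0.5), 50, tolerance = 1e-8)
  # sham: two copies of one chemical depend only on the total dose
  withr::with_seed(5, {
    for (i in 1:20) {
      tot <- runif(1, 0.2, 4)
      f <- runif(1)
      expect_equal(predict_ca(p, f * tot, (1 - f) * tot),
                   predict_ca(p, tot, 0), tolerance = 1e-8)
    }
  })
  # axes reduce to the single-chemical curves for both frameworks
  p2 <- surface_params(90, 0.8, 1.7, 2.5, 2.4)
  cc <- c(0.1, 0.5, 1, 3)
  single1 <- 90 / (1 + (cc / 0.8)^1.7)
  single2 <- 90 / (1 + (cc / 2.5)^2.4)
  expect_equal(predict_ca(p2, cc, rep(0, 4)), single1, tolerance = 1e-8)
  expect_equal(predict_ca(p2, rep(0, 4), cc), single2, tolerance = 1e-8)
  expect_equal(predict_ia(p2, cc, rep(0, 4)), single1, tolerance = 1e-12)
  expect_equal(predict_ia(p2, rep(0, 4), cc), single2, tolerance = 1e-12)
  expect_equal(predict_ca(p2, 0, 0), 90)
  expect_equal(predict_ia(p2, 0, 0), 90)
})

test_that("IA surface multiplies unaffected fractions and responds to G", {
  p <- surface_params(100, 1, 2, 1, 2)
  expect_equal(predict_ia(p, 1, 1), 25) # q1 = q2 = 0.5
  # G = ln 2 at the equitoxic midpoint turns 0.25 into 0.5
  a_for_ln2 <- log(2) / 0.25
  pg <- surface_params(100, 1, 2, 1, 2, deviation_kind = "SA", a = a_for_ln2)
  expect_equal(predict_ia(pg, 1, 1), 50, tolerance = 1e-12)
})

test_that("zero deviation reproduces the reference surface exactly", {
  withr::with_seed(8, {
    for (i in 1:10) {
      p0 <- random_surface_params()
      psa <- surface_params(p0$theta_max, p0$ec50_1, p0$beta_1, p0$ec50_2,
                            p0$beta_2, deviation_kind = "SA", a = 0)
      c1 <- runif(8, 0, 3); c2 <- runif(8, 0, 3)
      expect_equal(predict_ca(psa, c1, c2), predict_ca(p0, c1, c2),
                   tolerance = 1e-10)
      expect_equal(predict_ia(psa, c1, c2), predict_ia(p0, c1, c2),
                   tolerance = 1e-10)
    }
  })
})

test_that("positive deviation lifts both surfaces in the interior", {
  withr::with_seed(13, {
    for (i in 1:5) {
      p0 <- random_surface_params()
      pa <- surface_params(p0$theta_max, p0$ec50_1, p0$beta_1, p0$ec50_2,
                           p0$beta_2, deviation_kind = "SA",
                           a = runif(1, 0.5, 4))
      c1 <- runif(20, 0.05, 3) * p0$ec50_1
      c2 <- runif(20, 0.05, 3) * p0$ec50_2
      expect_true(all(predict_ca(pa, c1, c2) > predict_ca(p0, c1, c2)))
      expect_true(all(predict_ia(pa, c1, c2) > predict_ia(p0, c1, c2)))
    }
  })
})

test_that("CA bisection agrees with the grid-scan oracle", {
  withr::with_seed(21, {
    for (i in 1:20) {
      kind <- sample(c("none", "SA", "DL"), 1)
      p <- random_surface_params(kind,
                                 a = if (kind != "none") runif(1, -2, 2),
                                 b = if (kind == "DL") runif(1, 0, 1))
      c1 <- runif(1, 0.1, 2) * p$ec50_1
      c2 <- runif(1, 0.1, 2) * p$ec50_2
      expect_equal(predict_ca(p, c1, c2), ca_grid_oracle(p, c1, c2),
                   tolerance = 1e-6)
    }
  })
})

test_that("noise-free surfaces are recovered by the joint fit", {
  truth <- sim_surface()
  g <- sim_grid(truth, noise_sd = 0, seed = 1)
  fit <- fit_surface(g, "CA", "none")
  expect_lt(fit$SS_res, 1e-10)
  expect_equal(tidy(fit)$estimate, c(100, 1, 2, 2, 1.5), tolerance = 1e-4)

  gi <- sim_grid(truth, noise_sd = 0, seed = 2, model_type = "IA")
  fi <- fit_surface(gi, "IA", "none")
  expect_lt(fi$SS_res, 1e-10)
  expect_equal(tidy(fi)$estimate, c(100, 1, 2, 2, 1.5), tolerance = 1e-4)
})

test_that("fit preconditions are enforced", {
  truth <- sim_surface()
  small <- sim_grid(truth, noise_sd = 0, seed = 1)[1:5, ]
  expect_error(fit_surface(small, "CA", "none"),
               class = "mixtoxsys_validation_error")
  axis_only <- sim_grid(truth, noise_sd = 0, seed = 1)
  axis_only <- axis_only[axis_only$c1 == 0 | axis_only$c2 == 0, ]
  expect_error(fit_surface(axis_only, "CA", "SA"),
               class = "mixtoxsys_validation_error")
})

test_that("likelihood-ratio test matches its Gaussian closed form", {
  truth <- sim_surface()
  g <- sim_grid(truth, noise_sd = 5, seed = 4)
  ref <- fit_surface(g, "CA", "none", n_starts = 2)
  sa <- fit_surface(g, "CA", "SA", warm_start = ref, n_starts = 2)
  lt <- lr_test(ref, sa)
  expect_equal(lt$chi2, max(0, ref$n * log(ref$SS_res / sa$SS_res)))
  expect_equal(lt$df, 1)

  # frozen example: n = 100, SS ratio 1.5, df 1; tail checked against the
  # normal-tail identity for chi-square with one degree of freedom
  chi2 <- 100 * log(1.5)
  expect_equal(chi2, 40.54651, tolerance = 1e-6)
  p_oracle <- 2 * pnorm(-sqrt(chi2))
  expect_equal(pchisq(chi2, 1, lower.tail = FALSE), p_oracle,
               tolerance = 1e-12)
  expect_equal(p_oracle, 1.919911e-10, tolerance = 1e-6)

  # degenerate and misuse cases
  same <- lr_test(ref, sa)
  expect_gte(same$p, 0)
  expect_error(lr_test(sa, ref), class = "mixtoxsys_usage_error")
  g2 <- sim_grid(truth, noise_sd = 5, seed = 5)[1:40, ]
  other <- fit_surface(g2, "CA", "none", n_starts = 2)
  expect_error(lr_test(other, sa), class = "mixtoxsys_usage_error")
})

test_that("nested fits never lose ground to their parent", {
  truth <- sim_surface("SA", a = 2)
  g <- sim_grid(truth, noise_sd = 5, seed = 9)
  ref <- fit_surface(g, "CA", "none", n_starts = 2)
  sa <- fit_surface(g, "CA", "SA", warm_start = ref, n_starts = 2)
  dl <- fit_surface(g, "CA", "DL", warm_start = sa, n_starts = 2)
  expect_lte(sa$SS_res, ref$SS_res * (1 + 1e-9))
  expect_lte(dl$SS_res, sa$SS_res * (1 + 1e-9))
  expect_equal(dl$logLik,
               -(dl$n / 2) * (log(2 * pi * dl$SS_res / dl$n) + 1))
})

test_that("strong antagonism is classified with its direction", {
  truth <- sim_surface("SA", a = 3)
  g <- sim_grid(truth, noise_sd = 5, seed = 7)
  verdict <- classify_interaction(g, "CA", n_starts = 2)
  expect_equal(verdict$pattern, "antagonism")
  expect_gt(verdict$supporting$a_hat, 0)
  td <- tidy(verdict)
  expect_equal(nrow(td), 3)
  expect_true(all(c("R2", "chi2", "p") %in% names(td)))

  synergy <- sim_surface("SA", a = -3)
  gs <- sim_grid(synergy, noise_sd = 5, seed = 8)
  vs <- classify_interaction(gs, "CA", n_starts = 2)
  expect_equal(vs$pattern, "synergism")
})
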