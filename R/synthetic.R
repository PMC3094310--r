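# Seeded generators emulating every input the assessment consumes. Each one
# draws from a private RNG stream (the caller's RNG state is untouched) and
# records its generating parameters in a `provenance` attribute so recovery
# tests can close the loop.

provenance <- function(x) attr(x, "provenance")

#' Generate a single-chemical dose-response table
#'
#' Responses follow a log-logistic model plus iid additive Gaussian noise.
#' Controls (concentration 0) are always included.
#'
#' @param model A `mixtox_drc` model (e.g. [loglogistic_model()]).
#' @param doses Concentration levels; 0 is prepended when absent.
#' @param n_per_dose Replicates per dose.
#' @param noise_sd Gaussian noise standard deviation (response units).
#' @param seed Integer seed.
#' @return Tibble `chemical`, `concentration`, `response`, `replicate`, with
#'   a `provenance` attribute.
#' @export
gen_dose_response <- function(model, doses, n_per_dose = 1, noise_sd = 0,
                              seed = 1) {
  stopifnot(inherits(model, "mixtox_drc"))
  if (noise_sd < 0) {
    stop_mixtox("`noise_sd` must be non-negative.", "mixtoxsys_validation_error")
  }
  if (!any(doses == 0)) doses <- c(0, doses)
  conc <- rep(doses, each = n_per_dose)
  mu <- predict(model, conc)
  out <- with_gen_seed(seed, {
    tibble::tibble(
      chemical = model$chemical %||% NA_character_,
      concentration = conc,
      response = mu + rnorm(length(conc), sd = noise_sd),
      replicate = rep(seq_len(n_per_dose), times = length(doses))
    )
  })
  attr(out, "provenance") <- list(model = model, doses = doses,
                                  n_per_dose = n_per_dose,
                                  noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a fixed-ray equitoxic mixture design with axis data
#'
#' Produces mixture points along a fixed toxic-unit ray (chemical 1 holding
#' a share `ray_ratio` of the nominal toxic units) at the requested TU
#' levels, plus single-chemical axis points at the same TU levels and
#' controls -- the layout of an equitoxic mixture experiment. Toxic units
#' follow the TU-to-ECx labelling convention, so chemical i's dose at
#' nominal level T is its EC(50 T z_i) where z_i is its TU share; with
#' `ray_ratio = 0.5` the mixture points coincide with
#' [design_equitoxic_mixture()]. Gaussian noise is added on the response
#' scale.
#'
#' @param params A `surface_params` object (the generating surface,
#'   deviation included).
#' @param model_type `"CA"` or `"IA"`.
#' @param tu_levels Toxic-unit levels, e.g. `c(0.25, 0.5, 1)`.
#' @param ray_ratio Toxic-unit share of chemical 1 in the mixture, in (0,1)
#'   (0.5 = equitoxic).
#' @param n_per_point Replicates per design point.
#' @param noise_sd Gaussian noise sd (response units).
#' @param seed Integer seed.
#' @return Tibble `c1`, `c2`, `response`, `point` with a `provenance`
#'   attribute.
#' @export
gen_mixture_ray <- function(params, model_type = c("CA", "IA"),
                            tu_levels = c(0.25, 0.5, 1), ray_ratio = 0.5,
                            n_per_point = 5, noise_sd = 0, seed = 1) {
  model_type <- match.arg(model_type)
  stopifnot(inherits(params, "surface_params"))
  if (ray_ratio <= 0 || ray_ratio >= 1) {
    stop_mixtox("`ray_ratio` must lie in (0, 1).", "mixtoxsys_validation_error")
  }
  ecx <- function(ec50, beta, x) ec50 * (x / (100 - x))^(1 / beta)
  if (any(50 * tu_levels >= 100)) {
    stop_mixtox("Axis TU levels must satisfy 50 * TU < 100.",
                "mixtoxsys_validation_error")
  }
  design <- dplyr::bind_rows(
    tibble::tibble(c1 = 0, c2 = 0, point = "control"),
    tibble::tibble(c1 = ecx(params$ec50_1, params$beta_1, 50 * tu_levels),
                   c2 = 0, point = "axis1"),
    tibble::tibble(c1 = 0,
                   c2 = ecx(params$ec50_2, params$beta_2, 50 * tu_levels),
                   point = "axis2"),
    tibble::tibble(
      c1 = ecx(params$ec50_1, params$beta_1, 50 * tu_levels * ray_ratio),
      c2 = ecx(params$ec50_2, params$beta_2,
               50 * tu_levels * (1 - ray_ratio)),
      point = "mixture")
  )
  design <- design[rep(seq_len(nrow(design)), each = n_per_point), ]
  mu <- predict_surface(params, model_type, design$c1, design$c2)
  out <- with_gen_seed(seed, {
    dplyr::mutate(design, response = mu + rnorm(nrow(design), sd = noise_sd),
                  .before = "point")
  })
  attr(out, "provenance") <- list(params = params, model_type = model_type,
                                  tu_levels = tu_levels,
                                  ray_ratio = ray_ratio,
                                  n_per_point = n_per_point,
                                  noise_sd = noise_sd, seed = seed)
  tibble::as_tibble(out)
}

#' Generate a factorial mixture design (full concentration grid)
#'
#' Crosses the two chemicals' concentration levels (each including 0, so
#' the grid contains the controls and both single-chemical axes) and adds
#' Gaussian noise to the surface prediction. A grid of 7 x 7 levels gives
#' the n = 49 layout used in the surface-inference simulations.
#'
#' @inheritParams gen_mixture_ray
#' @param c1_levels,c2_levels Concentration levels per chemical (0 is
#'   prepended when absent).
#' @return Tibble `c1`, `c2`, `response` with a `provenance` attribute.
#' @export
gen_mixture_grid <- function(params, model_type = c("CA", "IA"),
                             c1_levels, c2_levels, n_per_point = 1,
                             noise_sd = 0, seed = 1) {
  model_type <- match.arg(model_type)
  stopifnot(inherits(params, "surface_params"))
  if (!any(c1_levels == 0)) c1_levels <- c(0, c1_levels)
  if (!any(c2_levels == 0)) c2_levels <- c(0, c2_levels)
  grid <- expand.grid(c1 = c1_levels, c2 = c2_levels)
  grid <- grid[rep(seq_len(nrow(grid)), each = n_per_point), ]
  mu <- predict_surface(params, model_type, grid$c1, grid$c2)
  out <- with_gen_seed(seed, {
    tibble::tibble(c1 = grid$c1, c2 = grid$c2,
                   response = mu + rnorm(nrow(grid), sd = noise_sd))
  })
  attr(out, "provenance") <- list(params = params, model_type = model_type,
                                  c1_levels = c1_levels,
                                  c2_levels = c2_levels,
                                  n_per_point = n_per_point,
                                  noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a depuration time course
#'
#' First-order elimination with multiplicative lognormal noise:
#' \eqn{C_t = C_0 e^{-kt} e^{\varepsilon}},
#' \eqn{\varepsilon \sim N(0, \ln(1 + cv))}.
#'
#' @param k Elimination rate constant (per day, >= 0).
#' @param C0 Concentration at the start of depuration.
#' @param times Sampling times in days (strictly increasing).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @param chemical Optional label.
#' @return Tibble `chemical`, `time`, `concentration` with a `provenance`
#'   attribute.
#' @export
gen_elimination <- function(k, C0, times = c(0.125, 0.25, 0.5, 1, 3, 6),
                            noise_cv = 0, seed = 1, chemical = NA_character_) {
  if (k < 0 || noise_cv < 0) {
    stop_mixtox("`k` and `noise_cv` must be non-negative.",
                "mixtoxsys_validation_error")
  }
  mu <- C0 * exp(-k * times)
  out <- with_gen_seed(seed, {
    eps <- rnorm(length(times), sd = log(1 + noise_cv))
    tibble::tibble(chemical = chemical, time = times,
                   concentration = mu * exp(eps))
  })
  attr(out, "provenance") <- list(k = k, C0 = C0, times = times,
                                  noise_cv = noise_cv, seed = seed)
  out
}

#' Generate three DEG tables with a prescribed exclusive-overlap structure
#'
#' Builds three differential-expression tables (per-gene M and B) whose
#' called DEG lists reproduce the requested list sizes, exclusive pairwise
#' overlaps, triple intersection and per-pair trend splits exactly (set
#' identities, not in expectation). Member genes receive B drawn uniformly
#' inside `B_range` (above the calling threshold of 0) and |M| inside
#' `effect_M_range`; background genes receive negative B.
#'
#' @param list_sizes Named integer vector of three DEG list sizes, e.g.
#'   `c(Ni = 135, CHP = 43, Mix = 103)`.
#' @param exclusive_overlaps Named integer vector of exclusive pairwise
#'   overlap counts with names `"A/B"` using the condition names, e.g.
#'   `c("Ni/CHP" = 15, "Ni/Mix" = 19, "CHP/Mix" = 15)`.
#' @param triple Size of the triple intersection.
#' @param trend_split Optional named list: per pair, `c(same = , opposite = )`
#'   counts summing to that pair's exclusive overlap. Pairs left out are
#'   fully same-trend.
#' @param effect_M_range Range of |M| for called genes.
#' @param B_range Range of B for called genes (must be positive).
#' @param n_background Extra never-called genes appended to every table.
#' @param seed Integer seed.
#' @return Tibble with columns `condition`, `gene_id`, `M`, `B` (one block
#'   per condition) and a `provenance` attribute.
#' @export
gen_deg_study <- function(list_sizes, exclusive_overlaps, triple = 0,
                          trend_split = NULL, effect_M_range = c(0.5, 3),
                          B_range = c(0.5, 12), n_background = 100, seed = 1) {
  conds <- names(list_sizes)
  if (length(conds) != 3 || is.null(conds)) {
    stop_mixtox("`list_sizes` must be a named vector of three conditions.",
                "mixtoxsys_validation_error")
  }
  pair_names <- combn(conds, 2, FUN = function(p)
    canonical_pair(p[1], p[2], conds))
  eo <- setNames(integer(3), pair_names)
  for (nm in names(exclusive_overlaps)) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% conds)) {
      stop_mixtox(sprintf("Unknown pair '%s'.", nm),
                  "mixtoxsys_validation_error")
    }
    eo[[canonical_pair(parts[1], parts[2], conds)]] <- exclusive_overlaps[[nm]]
  }
  uniques <- vapply(conds, function(cd) {
    touching <- pair_names[vapply(strsplit(pair_names, "/", fixed = TRUE),
                                  function(p) cd %in% p, logical(1))]
    list_sizes[[cd]] - sum(eo[touching]) - triple
  }, numeric(1))
  if (any(uniques < 0)) {
    stop_mixtox("Infeasible overlap structure: a unique count is negative.",
                "mixtoxsys_validation_error")
  }

  splits <- setNames(vector("list", 3), pair_names)
  for (nm in pair_names) splits[[nm]] <- c(same = eo[[nm]], opposite = 0L)
  for (nm in names(trend_split %||% list())) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    cn <- canonical_pair(parts[1], parts[2], conds)
    ts <- trend_split[[nm]]
    if (sum(ts) != eo[[cn]]) {
      stop_mixtox(sprintf("Trend split for '%s' must sum to its overlap (%d).",
                          cn, eo[[cn]]), "mixtoxsys_validation_error")
    }
    splits[[cn]] <- c(same = unname(ts[["same"]]),
                      opposite = unname(ts[["opposite"]]))
  }

  n_members <- sum(uniques) + sum(eo) + triple
  total <- n_members + n_background
  ids <- sprintf("gene%05d", seq_len(total))

  with_gen_seed(seed, {
    pool <- sample(ids[seq_len(n_members)]) # shuffle membership assignment
    take <- function(n) {
      if (n == 0) return(character(0))
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    membership <- list()
    for (cd in conds) membership[[cd]] <- tibble::tibble(gene_id = take(uniques[[cd]]),
                                                         sgn = sample(c(-1, 1), uniques[[cd]], replace = TRUE))
    for (nm in pair_names) {
      parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
      sp <- splits[[nm]]
      g_same <- take(sp[["same"]])
      g_opp <- take(sp[["opposite"]])
      s_same <- sample(c(-1, 1), length(g_same), replace = TRUE)
      s_opp <- sample(c(-1, 1), length(g_opp), replace = TRUE)
      membership[[parts[1]]] <- dplyr::bind_rows(
        membership[[parts[1]]],
        tibble::tibble(gene_id = c(g_same, g_opp), sgn = c(s_same, s_opp)))
      membership[[parts[2]]] <- dplyr::bind_rows(
        membership[[parts[2]]],
        tibble::tibble(gene_id = c(g_same, g_opp), sgn = c(s_same, -s_opp)))
    }
    g3 <- take(triple)
    s3 <- sample(c(-1, 1), triple, replace = TRUE)
    for (cd in conds) {
      membership[[cd]] <- dplyr::bind_rows(
        membership[[cd]], tibble::tibble(gene_id = g3, sgn = s3))
    }

    out <- purrr::map_dfr(conds, function(cd) {
      mem <- membership[[cd]]
      bg <- setdiff(ids, mem$gene_id)
      tibble::tibble(
        condition = cd,
        gene_id = c(mem$gene_id, bg),
        M = c(mem$sgn * runif(nrow(mem), effect_M_range[1], effect_M_range[2]),
              runif(length(bg), -0.4, 0.4)),
        B = c(runif(nrow(mem), B_range[1], B_range[2]),
              runif(length(bg), -8, -0.5))
      )
    })
    attr(out, "provenance") <- list(list_sizes = list_sizes,
                                    exclusive_overlaps = eo, triple = triple,
                                    trend_split = splits, seed = seed)
    out
  })
}

#' Generate a random annotation set, GO DAG and spiked study list
#'
#' Builds a layered random is_a DAG, annotates a sequence universe with its
#' terms, and draws a study list in which one chosen term is enriched at
#' the requested odds (`spike_odds` multiplies the annotation odds for
#' study members; 1 = null). Ground truth is recorded in the `provenance`
#' attribute.
#'
#' @param universe_size Number of sequences on the array (> 0).
#' @param dag_depth Number of DAG layers below the root.
#' @param n_terms Total number of terms.
#' @param study_size Size of the study list.
#' @param spike_odds Odds multiplier (>= 1) for the spiked term among study
#'   members.
#' @param base_prob Baseline annotation probability per (sequence, term).
#' @param seed Integer seed.
#' @return List with `annotation` (tibble), `dag` (`go_dag`), `study`
#'   (character), `spiked_term`; carries a `provenance` attribute.
#' @export
gen_annotation <- function(universe_size = 1673, dag_depth = 4, n_terms = 40,
                           study_size = 100, spike_odds = 1,
                           base_prob = 0.05, seed = 1) {
  if (universe_size <= 0) {
    stop_mixtox("`universe_size` must be positive.",
                "mixtoxsys_validation_error")
  }
  if (spike_odds < 1) {
    stop_mixtox("`spike_odds` must be >= 1.", "mixtoxsys_validation_error")
  }
  with_gen_seed(seed, {
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    layer <- c(0, sort(sample(seq_len(dag_depth), n_terms - 1, replace = TRUE)))
    parents <- vector("list", n_terms)
    names(parents) <- terms
    parents[[1]] <- character(0)
    for (i in 2:n_terms) {
      cand <- terms[layer < layer[i]]
      parents[[terms[i]]] <- sample(cand, min(length(cand),
                                              sample(1:2, 1)))
    }
    dag <- go_dag(parents)

    seqs <- sprintf("seq%05d", seq_len(universe_size))
    study <- sample(seqs, study_size)
    spiked_term <- terms[n_terms] # a leaf-layer term
    odds0 <- base_prob / (1 - base_prob)
    p_spiked_study <- (odds0 * spike_odds) / (1 + odds0 * spike_odds)

    rows <- purrr::map_dfr(terms, function(tm) {
      p <- rep(base_prob, universe_size)
      if (tm == spiked_term) p[seqs %in% study] <- p_spiked_study
      hit <- runif(universe_size) < p
      tibble::tibble(seq_id = seqs[hit], term = tm)
    })
    out <- list(annotation = rows, dag = dag, study = study,
                universe = seqs, spiked_term = spiked_term)
    attr(out, "provenance") <- list(universe_size = universe_size,
                                    dag_depth = dag_depth, n_terms = n_terms,
                                    study_size = study_size,
                                    spike_odds = spike_odds,
                                    base_prob = base_prob, seed = seed)
    out
  })
}

#' Generate a biomarker panel with prescribed shifts
#'
#' Draws control and exposed replicates for each biomarker from Gaussian
#' distributions, shifting the exposed mean by the requested fractional
#' amount. The default scenario covers the standard battery
#' ([biomarker_defaults()]) with no shift.
#'
#' @param scenario Tibble with columns `biomarker`, `shift` (fractional mean
#'   change; negative = decrease) and optionally `baseline` (default 100)
#'   and `cv` (replicate coefficient of variation, default 0.15).
#' @param n Replicates per group (>= 3).
#' @param seed Integer seed.
#' @return Long tibble `biomarker`, `group`, `replicate`, `value` with a
#'   `provenance` attribute.
#' @export
gen_biomarker_panel <- function(scenario = tibble::tibble(
                                  biomarker = biomarker_defaults()$biomarker,
                                  shift = 0),
                                n = 10, seed = 1) {
  check_columns(scenario, c("biomarker", "shift"), "scenario")
  if (n < 3) {
    stop_mixtox("At least 3 replicates per group are required.",
                "mixtoxsys_validation_error")
  }
  baseline <- scenario[["baseline"]] %||% rep(100, nrow(scenario))
  cv <- scenario[["cv"]] %||% rep(0.15, nrow(scenario))
  out <- with_gen_seed(seed, {
    purrr::map_dfr(seq_len(nrow(scenario)), function(i) {
      mu0 <- baseline[i]
      sdv <- cv[i] * mu0
      tibble::tibble(
        biomarker = scenario$biomarker[i],
        group = rep(c("control", "exposed"), each = n),
        replicate = rep(seq_len(n), 2),
        value = c(rnorm(n, mu0, sdv),
                  rnorm(n, mu0 * (1 + scenario$shift[i]), sdv))
      )
    })
  })
  attr(out, "provenance") <- list(scenario = scenario, n = n, seed = seed)
  out
}
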