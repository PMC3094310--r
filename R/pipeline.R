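#' Run the full mixture-toxicity assessment from a configuration
#'
#' Orchestrates every analysis stage the package implements, driven by a
#' single configuration: single-chemical dose-response fits and ECx tables,
#' equitoxic mixture design, CA/IA response-surface interaction testing,
#' toxicokinetic elimination fits, biomarker health-status grading,
#' transcriptomic overlap/concordance accounting, and GO enrichment. Only
#' the sections present in the configuration are run; failures in one
#' endpoint are isolated and reported in the block's `error` field.
#'
#' The configuration is either a YAML file path or an equivalent nested
#' list. File-based sections reference input tables by path; in-memory
#' sections can pass data frames directly (list form only). Recognised
#' sections (all optional, at least one required):
#' \describe{
#'   \item{dose_response}{`tables` (named by chemical: path or data frame),
#'     `direction`, `tu_levels` for the mixture design.}
#'   \item{mixture}{named list of endpoints, each with `data` (path or data
#'     frame) and optional `framework` (`"CA"`, `"IA"` or `"both"`).}
#'   \item{toxicokinetics}{`tables` (named by chemical), `method`.}
#'   \item{biomarkers}{named list of conditions, each a panel (path or data
#'     frame); optional `meta`, `rules` (path to YAML rule table or data
#'     frame).}
#'   \item{transcriptomics}{`deg_tables` (named by condition), optional
#'     `b_threshold`, `focal`, `concordance` (path or data frame).}
#'   \item{enrichment}{`annotation` (path or data frame), `obo` (path) or
#'     `dag`, `study` (path with one id per line, or character vector),
#'     optional `universe`, `alpha`, `correction`.}
#' }
#' Global keys: `alpha` (default 0.05), `seed`.
#'
#' @param config YAML file path or nested list.
#' @return A `mixtox_assessment` list of per-stage blocks plus `provenance`
#'   (package version, alpha, seed, config digest).
#' @export
run_assessment <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop_mixtox(sprintf("Config file not found: %s", config),
                  "mixtoxsys_validation_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || length(config) == 0) {
    stop_mixtox("Config must be a non-empty list or a YAML file path.",
                "mixtoxsys_validation_error")
  }
  alpha <- config$alpha %||% 0.05
  if (!is_prob(alpha)) {
    stop_mixtox("`alpha` must lie in (0, 1).", "mixtoxsys_validation_error")
  }
  seed <- config$seed %||% 1L
  sections <- intersect(names(config),
                        c("dose_response", "mixture", "toxicokinetics",
                          "biomarkers", "transcriptomics", "enrichment"))
  if (length(sections) == 0) {
    stop_mixtox("Config contains no analysis section.",
                "mixtoxsys_validation_error")
  }
  validate_config_paths(config[sections])

  report <- list()
  run_block <- function(name, fn) {
    if (!name %in% sections) return(NULL)
    tryCatch(fn(config[[name]]), error = function(e) list(error = conditionMessage(e)))
  }

  report$dose_response <- run_block("dose_response", function(cfg) {
    tables <- lapply(cfg$tables, resolve_table, read_dose_response)
    fits <- lapply(tables, fit_loglogistic,
                   direction = cfg$direction %||% "decreasing")
    ecx <- purrr::map_dfr(names(fits), function(ch) {
      dplyr::mutate(ec_x(fits[[ch]], c(12.5, 25, 50)), chemical = ch,
                    .before = 1)
    })
    designs <- purrr::map_dfr(cfg$tu_levels %||% c(0.5, 1),
                              function(tu) design_equitoxic_mixture(fits, tu))
    list(fits = fits, ecx = ecx, design = designs)
  })

  report$mixture <- run_block("mixture", function(cfg) {
    lapply(cfg, function(endpoint) {
      data <- resolve_table(endpoint$data, read_mixture_points)
      fw <- endpoint$framework %||% "both"
      fws <- if (fw == "both") c("CA", "IA") else fw
      setNames(lapply(fws, function(f)
        classify_interaction(data, f, alpha = alpha)), fws)
    })
  })

  report$toxicokinetics <- run_block("toxicokinetics", function(cfg) {
    fits <- lapply(cfg$tables, function(tb)
      fit_elimination(resolve_table(tb, read_elimination_series),
                      method = cfg$method %||% "log_linear"))
    list(fits = fits, summary = purrr::map_dfr(fits, tidy_elimination_row,
                                               .id = "series"))
  })

  report$biomarkers <- run_block("biomarkers", function(cfg) {
    meta <- if (!is.null(cfg$meta)) resolve_table(cfg$meta, readr::read_tsv)
    else biomarker_defaults()
    rules <- if (!is.null(cfg$rules)) resolve_rules(cfg$rules)
    else default_rule_table()
    panels <- cfg$panels %||% cfg[setdiff(names(cfg), c("meta", "rules"))]
    res <- lapply(panels, function(p)
      health_status_index(resolve_table(p, read_biomarker_panel),
                          meta = meta, rules = rules, alpha = alpha))
    list(results = res,
         grades = tibble::tibble(condition = names(res),
                                 grade = unname(vapply(res, `[[`, "", "grade"))))
  })

  report$transcriptomics <- run_block("transcriptomics", function(cfg) {
    out <- list()
    if (!is.null(cfg$deg_tables)) {
      degs <- purrr::map_dfr(names(cfg$deg_tables), function(cd) {
        tb <- resolve_table(cfg$deg_tables[[cd]], read_deg_table)
        dplyr::mutate(call_degs(tb, b_threshold = cfg$b_threshold %||% 0),
                      condition = cd, .before = 1)
      })
      out$degs <- degs
      out$overlap <- overlap_accounting(degs, focal = cfg$focal)
    }
    if (!is.null(cfg$concordance)) {
      rows <- resolve_table(cfg$concordance, read_table_auto,
                            col_types = readr::cols())
      out$concordance <- concordance(rows)
    }
    out
  })

  report$enrichment <- run_block("enrichment", function(cfg) {
    annot <- resolve_table(cfg$annotation, read_annotation)
    dag <- cfg$dag %||% read_obo(cfg$obo)
    study <- if (is.character(cfg$study) && length(cfg$study) == 1 &&
                 file.exists(cfg$study)) readLines(cfg$study) else cfg$study
    res <- enrich(study, annot, dag, universe = cfg$universe,
                  alpha = cfg$alpha %||% alpha,
                  correction = cfg$correction %||% "none")
    sig <- res$term[res$enriched]
    list(results = res, lowest_nodes = lowest_nodes(sig, dag))
  })

  report <- report[!vapply(report, is.null, logical(1))]
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("mixtoxsys")),
    alpha = alpha, seed = seed,
    config_hash = rlang::hash(config),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(report, class = "mixtox_assessment")
}

validate_config_paths <- function(cfg) {
  paths <- character(0)
  walk <- function(x) {
    if (is.character(x) && length(x) == 1 &&
        grepl("\\.(tsv|csv|obo|yaml|yml|txt)$", x, ignore.case = TRUE)) {
      paths <<- c(paths, x)
    } else if (is.list(x)) {
      lapply(x, walk)
    }
    invisible(NULL)
  }
  walk(cfg)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop_mixtox(sprintf("Referenced input file(s) not found: %s",
                        paste(missing, collapse = ", ")),
                "mixtoxsys_validation_error")
  }
  invisible(TRUE)
}

resolve_table <- function(x, reader, ...) {
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  reader(x, ...)
}

resolve_rules <- function(x) {
  if (is.data.frame(x)) return(validate_rule_table(x))
  rules <- yaml::read_yaml(x)
  validate_rule_table(purrr::map_dfr(rules, tibble::as_tibble))
}

tidy_elimination_row <- function(fit) {
  tibble::tibble(chemical = fit$chemical, k = fit$k, C0 = fit$C0,
                 R2 = fit$R2, half_life = fit$half_life,
                 no_elimination = fit$no_elimination)
}

#' @export
print.mixtox_assessment <- function(x, ...) {
  blocks <- setdiff(names(x), "provenance")
  cat("Mixture-toxicity assessment report\n")
  cat(sprintf("  stages run: %s\n", paste(blocks, collapse = ", ")))
  cat(sprintf("  package %s, alpha = %g, config hash %s\n",
              x$provenance$package_version, x$provenance$alpha,
              substr(x$provenance$config_hash, 1, 8)))
  invisible(x)
}
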