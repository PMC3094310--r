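#' Read a minimal OBO ontology subset
#'
#' Parses `[Term]` stanzas keeping only `id`, `name`, `namespace` and `is_a`
#' relations (part_of and other relationship types are ignored); obsolete
#' terms are skipped. The resulting DAG is checked for acyclicity.
#'
#' @param path Path to an OBO file.
#' @return A `go_dag` object: named lists `parents`, `name`, `namespace`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  parents <- list(); names_ <- list(); ns <- list()
  bounds <- c(term_starts, length(lines) + 1L)
  for (i in seq_along(term_starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[!grepl("^\\[", block)]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), block,
                                                 value = TRUE))
      if (length(v)) v[1] else NA_character_
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    isa <- sub("^is_a: *", "", grep("^is_a:", block, value = TRUE))
    isa <- trimws(sub("!.*$", "", isa))
    parents[[id]] <- isa
    names_[[id]] <- get1("name")
    ns[[id]] <- get1("namespace")
  }
  go_dag(parents, name = names_, namespace = ns)
}

#' Construct a GO DAG from parent lists
#'
#' @param parents Named list mapping each term id to a character vector of
#'   is_a parents (empty vector for roots).
#' @param name,namespace Optional named lists of term names and namespaces.
#' @return A validated (acyclic) `go_dag` object.
#' @export
go_dag <- function(parents, name = NULL, namespace = NULL) {
  dag <- structure(list(parents = parents,
                        name = name %||% setNames(as.list(names(parents)),
                                                  names(parents)),
                        namespace = namespace %||%
                          setNames(as.list(rep("biological_process",
                                               length(parents))),
                                   names(parents))),
                   class = "go_dag")
  assert_acyclic(dag)
  dag
}

assert_acyclic <- function(dag) {
  # Kahn topological sort over is_a edges
  terms <- names(dag$parents)
  indeg <- setNames(integer(length(terms)), terms)
  for (tm in terms) {
    for (p in dag$parents[[tm]]) {
      if (p %in% terms) indeg[[p]] <- indeg[[p]] + 1L
    }
  }
  queue <- terms[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0) {
    tm <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (p in dag$parents[[tm]]) {
      if (!p %in% terms) next
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(terms)) {
    stop_mixtox("Ontology contains a cycle.", "mixtoxsys_dag_error")
  }
  invisible(TRUE)
}

# ancestor closure (strict) for every term, memoised bottom-up
ancestor_closure <- function(dag) {
  memo <- new.env(parent = emptyenv())
  anc <- function(tm) {
    if (!is.null(memo[[tm]])) return(memo[[tm]])
    memo[[tm]] <- character(0) # cycle guard; DAG already validated
    ps <- dag$parents[[tm]]
    ps <- ps[ps %in% names(dag$parents)]
    res <- unique(c(ps, unlist(lapply(ps, anc))))
    memo[[tm]] <- res
    res
  }
  setNames(lapply(names(dag$parents), anc), names(dag$parents))
}

#' Propagate annotations to ancestor terms
#'
#' Annotates every sequence with the union of its terms and all their is_a
#' ancestors, the standard true-path-rule closure that makes term counts
#' DAG-consistent. Idempotent. Terms absent from the DAG are kept as-is
#' (and reported once).
#'
#' @param annot Tibble with columns `seq_id`, `term`.
#' @param dag A `go_dag` object.
#' @return Tibble with columns `seq_id`, `term` (closure, distinct rows).
#' @export
propagate_ancestors <- function(annot, dag) {
  check_columns(annot, c("seq_id", "term"), "annotation")
  stopifnot(inherits(dag, "go_dag"))
  unknown <- setdiff(unique(annot$term), names(dag$parents))
  if (length(unknown) > 0) {
    inform(sprintf("%d annotated term(s) not in the ontology are kept as-is.",
                   length(unknown)))
  }
  anc <- ancestor_closure(dag)
  known <- annot[annot$term %in% names(dag$parents), c("seq_id", "term")]
  closures <- anc[known$term]
  extra <- tibble::tibble(
    seq_id = rep(known$seq_id, lengths(closures)),
    term = unlist(closures, use.names = FALSE) %||% character(0)
  )
  dplyr::bind_rows(annot[c("seq_id", "term")], extra) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$seq_id, .data$term)
}

#' Hypergeometric GO-term over-representation analysis
#'
#' Tests each term for over-representation in a study list relative to the
#' array background by the one-sided hypergeometric (Fisher exact) tail
#' \eqn{p = P(X \ge k)} with k study genes carrying the term, K background
#' genes carrying it, n the study size and N the background size.
#' Annotations are propagated to ancestors first (switchable), and raw
#' p-values are compared with `alpha` by default; Benjamini-Hochberg
#' correction is available and recommended for exploratory scans.
#'
#' @param study Character vector of study sequence ids (must be a subset of
#'   the universe).
#' @param annot Annotation tibble (`seq_id`, `term`).
#' @param dag A `go_dag` (required when `propagate = TRUE`).
#' @param universe Character vector of background ids (default: all
#'   annotated ids).
#' @param alpha Significance level.
#' @param correction `"none"` (default) or `"BH"`.
#' @param propagate Propagate annotations to ancestors first (default TRUE).
#' @param under Also test under-representation (lower tail); default FALSE.
#' @return Tibble with `term`, `name`, `namespace`, `k`, `K`, `n`, `N`,
#'   `p`, `p_adj`, `enriched`, sorted by `p`.
#' @export
enrich <- function(study, annot, dag = NULL, universe = NULL, alpha = 0.05,
                   correction = c("none", "BH"), propagate = TRUE,
                   under = FALSE) {
  correction <- match.arg(correction)
  check_columns(annot, c("seq_id", "term"), "annotation")
  if (length(study) == 0) {
    stop_mixtox("Study list is empty.", "mixtoxsys_usage_error")
  }
  universe <- universe %||% unique(annot$seq_id)
  if (!all(study %in% universe)) {
    stop_mixtox("Study ids must be a subset of the universe.",
                "mixtoxsys_usage_error")
  }
  if (propagate) {
    if (is.null(dag)) {
      stop_mixtox("`dag` is required when propagate = TRUE.",
                  "mixtoxsys_usage_error")
    }
    annot <- propagate_ancestors(annot, dag)
  }
  annot <- annot[annot$seq_id %in% universe, , drop = FALSE]
  N <- length(unique(universe))
  n <- length(unique(study))
  per_term <- annot |>
    dplyr::distinct(.data$seq_id, .data$term) |>
    dplyr::summarise(K = dplyr::n(),
                     k = sum(.data$seq_id %in% study),
                     .by = "term")
  p <- if (under) {
    phyper(per_term$k, per_term$K, N - per_term$K, n)
  } else {
    phyper(per_term$k - 1, per_term$K, N - per_term$K, n, lower.tail = FALSE)
  }
  p_adj <- if (correction == "BH") stats::p.adjust(p, "BH") else p
  info <- function(field, default) {
    vapply(per_term$term, function(tm) {
      v <- if (!is.null(dag)) dag[[field]][[tm]] else NULL
      (v %||% default)[1]
    }, character(1))
  }
  tibble::tibble(
    term = per_term$term,
    name = info("name", NA_character_),
    namespace = info("namespace", NA_character_),
    k = per_term$k, K = per_term$K, n = n, N = N,
    p = p, p_adj = p_adj, enriched = p_adj < alpha
  ) |>
    dplyr::arrange(.data$p)
}

#' Lowest significant nodes per ontology branch
#'
#' Reduces a set of significant terms to the antichain of terms having no
#' significant descendant — the most specific node in each branch, the set
#' used to draw multi-level summary charts. Every removed term is an
#' ancestor of some returned term, so the ancestor closure of the result
#' covers the input.
#'
#' @param sig_terms Character vector of significant term ids (must be in
#'   the DAG).
#' @param dag A `go_dag` object.
#' @return Character vector of lowest nodes.
#' @export
lowest_nodes <- function(sig_terms, dag) {
  stopifnot(inherits(dag, "go_dag"))
  sig_terms <- unique(sig_terms)
  if (!all(sig_terms %in% names(dag$parents))) {
    stop_mixtox("All significant terms must be present in the DAG.",
                "mixtoxsys_usage_error")
  }
  anc <- ancestor_closure(dag)
  covered <- unique(unlist(anc[sig_terms], use.names = FALSE))
  setdiff(sig_terms, covered)
}
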