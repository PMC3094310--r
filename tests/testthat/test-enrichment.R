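chain_dag <- function() go_dag(list(a = character(0), b = "a", c = "b"))

test_that("the OBO subset reader keeps id, name, namespace and is_a", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: root process",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: child process",
    "namespace: biological_process",
    "is_a: GO:0000001 ! root process",
    "relationship: part_of GO:0000001",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: gone",
    "is_obsolete: true",
    "",
    "[Typedef]",
    "id: part_of"
  ), obo)
  dag <- read_obo(obo)
  expect_setequal(names(dag$parents), c("GO:0000001", "GO:0000002"))
  expect_equal(dag$parents[["GO:0000002"]], "GO:0000001")
  expect_equal(dag$parents[["GO:0000001"]], character(0))
  expect_equal(dag$name[["GO:0000002"]], "child process")
  expect_equal(dag$namespace[["GO:0000002"]], "biological_process")
})

test_that("cyclic ontologies are rejected", {
  expect_error(go_dag(list(a = "b", b = "a")), class = "mixtoxsys_dag_error")
})

test_that("ancestor propagation closes annotation sets and is idempotent", {
  dag <- chain_dag()
  ann <- tibble::tibble(seq_id = "s1", term = "c")
  out <- propagate_ancestors(ann, dag)
  expect_setequal(out$term, c("a", "b", "c"))
  expect_equal(propagate_ancestors(out, dag), out)

  root_only <- tibble::tibble(seq_id = "s1", term = "a")
  expect_equal(propagate_ancestors(root_only, dag), root_only)

  withr::with_seed(57, {
    for (i in 1:10) {
      ge <- gen_annotation(universe_size = 60, dag_depth = 3, n_terms = 12,
                           study_size = 10, seed = i)
      once <- propagate_ancestors(ge$annotation, ge$dag)
      expect_equal(propagate_ancestors(once, ge$dag), once)
      # DAG consistency: a parent can never be rarer than its child
      counts <- table(once$term)
      for (tm in names(ge$dag$parents)) {
        for (p in ge$dag$parents[[tm]]) {
          k_child <- counts[tm]; k_par <- counts[p]
          if (!is.na(k_child) && !is.na(k_par)) {
            expect_gte(as.integer(k_par), as.integer(k_child))
          }
        }
      }
    }
  })
})

test_that("hypergeometric p-values match the combinatorial tail oracle", {
  # frozen worked example: N = 100, K = 5, n = 10, k = 3
  expect_equal(hyper_tail_oracle(3, 5, 10, 100), 0.006637913,
               tolerance = 1e-6)
  expect_equal(phyper(2, 5, 95, 10, lower.tail = FALSE),
               hyper_tail_oracle(3, 5, 10, 100), tolerance = 1e-12)

  withr::with_seed(63, {
    for (i in 1:100) {
      N <- sample(5:60, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   hyper_tail_oracle(k, K, n, N), tolerance = 1e-12)
    }
  })
})

test_that("enrichment flags spiked terms and respects trivial cases", {
  ge <- gen_annotation(universe_size = 300, n_terms = 20, study_size = 50,
                       spike_odds = 10, seed = 2)
  res <- enrich(ge$study, ge$annotation, ge$dag, universe = ge$universe)
  expect_true(ge$spiked_term %in% res$term[res$enriched])
  expect_true(!is.unsorted(res$p))
  expect_true(all(res$k <= res$K & res$K <= res$N & res$k <= res$n))

  # a term with the same frequency in study and background is not enriched:
  # K/N = 25/100 matches k/n = 5/20
  ann <- tibble::tibble(seq_id = paste0("s", c(1:5, 21:40)),
                        term = "GO:0000001")
  uni <- paste0("s", 1:100)
  res2 <- enrich(paste0("s", 1:20), ann,
                 dag = go_dag(list("GO:0000001" = character(0))),
                 universe = uni)
  expect_false(res2$enriched[1])
  expect_gt(res2$p[1], 0.05)

  # study = universe forces p = 1 everywhere
  ge2 <- gen_annotation(universe_size = 50, n_terms = 8, study_size = 10,
                        seed = 3)
  res3 <- enrich(ge2$universe, ge2$annotation, ge2$dag,
                 universe = ge2$universe)
  expect_true(all(res3$p == 1))

  expect_error(enrich(character(0), ann, universe = uni),
               class = "mixtoxsys_usage_error")
  expect_error(enrich("not_in_universe", ann, universe = uni),
               class = "mixtoxsys_usage_error")
})

test_that("BH correction never increases the number of discoveries", {
  ge <- gen_annotation(universe_size = 200, n_terms = 25, study_size = 40,
                       spike_odds = 6, seed = 9)
  raw <- enrich(ge$study, ge$annotation, ge$dag, universe = ge$universe)
  adj <- enrich(ge$study, ge$annotation, ge$dag, universe = ge$universe,
                correction = "BH")
  expect_lte(sum(adj$enriched), sum(raw$enriched))
  expect_true(all(adj$p_adj >= adj$p))
})

test_that("lowest-node reduction returns the significant antichain", {
  dag <- chain_dag()
  expect_equal(lowest_nodes("b", dag), "b")
  expect_equal(lowest_nodes(c("a", "b", "c"), dag), "c")
  expect_error(lowest_nodes("zz", dag), class = "mixtoxsys_usage_error")

  # no returned pair may be ancestor-related; removed terms stay covered
  reaches <- function(dag, from, to) {
    frontier <- from
    while (length(frontier) > 0) {
      if (to %in% frontier) return(TRUE)
      frontier <- unique(unlist(dag$parents[frontier]))
    }
    FALSE
  }
  withr::with_seed(71, {
    for (i in 1:10) {
      ge <- gen_annotation(universe_size = 30, dag_depth = 4, n_terms = 15,
                           study_size = 5, seed = i)
      sig <- sample(names(ge$dag$parents), 6)
      low <- lowest_nodes(sig, ge$dag)
      for (u in low) for (v in low) {
        if (u != v) expect_false(reaches(ge$dag, u, v))
      }
      for (s in setdiff(sig, low)) {
        expect_true(any(vapply(low, function(l) reaches(ge$dag, l, s),
                               logical(1))))
      }
    }
  })
})

test_that("enrichment is invariant to relabeling sequence ids", {
  ge <- gen_annotation(universe_size = 120, n_terms = 15, study_size = 30,
                       spike_odds = 8, seed = 13)
  relabel <- setNames(paste0("x", seq_along(ge$universe)), ge$universe)
  ann2 <- dplyr::mutate(ge$annotation, seq_id = relabel[seq_id])
  r1 <- enrich(ge$study, ge$annotation, ge$dag, universe = ge$universe)
  r2 <- enrich(relabel[ge$study], ann2, ge$dag,
               universe = unname(relabel[ge$universe]))
  expect_equal(r1$p, r2$p)
})
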