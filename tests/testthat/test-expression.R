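deg_fixture <- function() {
  gen_deg_study(
    list_sizes = c(Ni = 135, CHP = 43, Mix = 103),
    exclusive_overlaps = c("Ni/CHP" = 15, "Ni/Mix" = 19, "CHP/Mix" = 15),
    triple = 8,
    trend_split = list("CHP/Mix" = c(same = 11, opposite = 4),
                       "Ni/Mix" = c(same = 5, opposite = 14),
                       "Ni/CHP" = c(same = 5, opposite = 10)),
    seed = 42
  )
}

test_that("DEG calling follows the log-odds threshold and tags trends", {
  tab <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        M = c(1.2, -0.4, 0.8), B = c(-2, -1, -0.5))
  expect_equal(nrow(call_degs(tab)), 0)
  expect_equal(nrow(call_degs(tab, b_threshold = Inf)), 0)

  ni <- dplyr::filter(qpcr_array_comparison(), condition == "Ni", !is.na(B))
  called <- call_degs(ni)
  expect_equal(nrow(called), 7) # positive-B genes in the printed column
  expect_true(all(called$B > 0))
  expect_setequal(unique(called$direction), c("up", "down"))

  zero <- tibble::tibble(gene_id = "g", M = 0, B = 3)
  expect_error(call_degs(zero), class = "mixtoxsys_tie_error")
  expect_warning(out <- call_degs(zero, m_zero = "drop"))
  expect_equal(nrow(out), 0)
  dup <- tibble::tibble(gene_id = c("g", "g"), M = c(1, 2), B = c(1, 2))
  expect_error(call_degs(dup), class = "mixtoxsys_validation_error")
})

test_that("overlap accounting reproduces the published mixture bookkeeping", {
  called <- call_degs(deg_fixture())
  ov <- overlap_accounting(called, focal = "Mix")
  expect_equal(ov$sizes$n[ov$sizes$condition == "Mix"], 103L)
  um <- ov$unique[ov$unique$condition == "Mix", ]
  expect_equal(um$unique, 61L)
  expect_equal(round(um$pct_unique), 59)
  expect_equal(um$unique_including_opposite, 79L)
  expect_equal(round(um$pct_unique_including_opposite), 77)
  pw <- ov$pairwise[ov$pairwise$pair == "CHP/Mix", ]
  expect_equal(pw$count, 15L)
  expect_equal(pw$same_trend, 11L)
  expect_equal(pw$opposite_trend, 4L)
  expect_equal(ov$triple$count, 8L)
})

test_that("disjoint lists have no overlaps and full uniqueness", {
  degs <- tibble::tibble(
    condition = rep(c("A", "B", "C"), times = c(3, 2, 4)),
    gene_id = paste0("g", 1:9),
    M = rnorm(9)
  )
  ov <- overlap_accounting(degs)
  expect_equal(ov$unique$unique, c(3L, 2L, 4L))
  expect_true(all(ov$pairwise$count == 0))
  expect_equal(ov$triple$count, 0L)
})

test_that("the partition identity holds on random synthetic triples", {
  withr::with_seed(99, {
    for (i in 1:50) {
      pool <- paste0("g", 1:40)
      degs <- purrr::map_dfr(c("A", "B", "C"), function(cd) {
        genes <- sample(pool, sample(5:25, 1))
        tibble::tibble(condition = cd, gene_id = genes,
                       M = sample(c(-1, 1), length(genes), replace = TRUE))
      })
      ov <- overlap_accounting(degs)
      for (cd in c("A", "B", "C")) {
        touching <- vapply(strsplit(ov$pairwise$pair, "/"),
                           function(p) cd %in% p, logical(1))
        expect_equal(
          ov$unique$unique[ov$unique$condition == cd] +
            sum(ov$pairwise$count[touching]) + ov$triple$count,
          ov$sizes$n[ov$sizes$condition == cd]
        )
        expect_equal(sum(ov$pairwise$same_trend + ov$pairwise$opposite_trend),
                     sum(ov$pairwise$count))
      }
    }
  })
})

test_that("concordance scoring is order-invariant and sign-symmetric", {
  rows <- dplyr::filter(qpcr_array_comparison(), condition == "Ni")
  base <- concordance(dplyr::select(rows, -condition))
  shuffled <- concordance(dplyr::select(rows[sample(nrow(rows)), ],
                                        -condition))
  expect_equal(base, shuffled)
  flipped <- dplyr::mutate(dplyr::select(rows, -condition),
                           qpcr_value = -qpcr_value, M = -M)
  expect_equal(concordance(flipped), base)

  all_quiet <- tibble::tibble(gene_id = paste0("g", 1:5),
                              qpcr_value = rnorm(5),
                              qpcr_significant = FALSE,
                              M = rnorm(5), B = runif(5, -8, -1))
  res <- concordance(all_quiet)
  expect_equal(res$matches, res$total)

  empty <- tibble::tibble(gene_id = "g", qpcr_value = 1,
                          qpcr_significant = TRUE,
                          M = NA_real_, B = NA_real_)
  expect_error(concordance(empty),
               class = "mixtoxsys_empty_comparison_error")
})

ct_fixture <- function(d_tgt = 3, d_r1 = 0, d_r2 = 0, n = 4, sd = 0,
                       seed = 1) {
  withr::with_seed(seed, {
    mk <- function(gene, base, delta) {
      tibble::tibble(
        gene_id = gene,
        group = rep(c("control", "exposed"), each = n),
        replicate = rep(seq_len(n), 2),
        ct = c(rnorm(n, base, sd), rnorm(n, base - delta, sd))
      )
    }
    dplyr::bind_rows(mk("tgt", 30, d_tgt), mk("r1", 20, d_r1),
                     mk("r2", 22, d_r2))
  })
}

eff_all2 <- tibble::tibble(gene_id = c("tgt", "r1", "r2"),
                           efficiency = c(2, 2, 2))

test_that("relative expression is efficiency-corrected and normalised", {
  expect_equal(relative_expression(ct_fixture(0, 0, 0), "tgt",
                                   c("r1", "r2"), eff_all2)$ratio, 1)
  expect_equal(relative_expression(ct_fixture(3, 0, 0), "tgt",
                                   c("r1", "r2"), eff_all2)$ratio, 8)
  # mixed efficiencies: 1.9^2 / geomean(2^1, 2^-1) = 3.61
  eff_mix <- tibble::tibble(gene_id = c("tgt", "r1", "r2"),
                            efficiency = c(1.9, 2, 2))
  r <- relative_expression(ct_fixture(2, 1, -1), "tgt", c("r1", "r2"),
                           eff_mix)
  expect_equal(r$ratio, 1.9^2, tolerance = 1e-12)
  expect_error(relative_expression(ct_fixture(), "tgt", character(0),
                                   eff_all2),
               class = "mixtoxsys_validation_error")
  bad_eff <- tibble::tibble(gene_id = c("tgt", "r1", "r2"),
                            efficiency = c(2.4, 2, 2))
  expect_error(relative_expression(ct_fixture(), "tgt", c("r1", "r2"),
                                   bad_eff),
               class = "mixtoxsys_validation_error")
})

test_that("all-efficiency-2 reduces to the ddCt method on random data", {
  withr::with_seed(31, {
    for (i in 1:10) {
      ct <- ct_fixture(runif(1, -2, 4), runif(1, -1, 1), runif(1, -1, 1),
                       sd = 0.3, seed = i)
      r <- relative_expression(ct, "tgt", c("r1", "r2"), eff_all2)
      agg <- dplyr::summarise(ct, d = mean(ct[group == "control"]) -
                                mean(ct[group == "exposed"]),
                              .by = "gene_id")
      ddct <- agg$d[agg$gene_id == "tgt"] -
        mean(agg$d[agg$gene_id != "tgt"])
      expect_equal(r$log2_ratio, ddct, tolerance = 1e-12)
    }
  })
})

test_that("the reallocation test is exact for small designs and seeded", {
  ct0 <- ct_fixture(0, 0, 0, n = 3, sd = 0.2, seed = 6)
  res0 <- randomization_test(ct0, "tgt", c("r1", "r2"), eff_all2)
  expect_equal(res0$mode, "exhaustive")
  expect_equal(res0$n_perm, 20L) # C(6, 3) splits
  expect_gte(res0$p, 0.1)

  strong <- ct_fixture(5, 0, 0, n = 4, sd = 0.1, seed = 2)
  res <- randomization_test(strong, "tgt", c("r1", "r2"), eff_all2)
  expect_lte(res$p, 0.05)

  big <- ct_fixture(1, 0, 0, n = 8, sd = 0.5, seed = 3)
  r1 <- randomization_test(big, "tgt", c("r1", "r2"), eff_all2,
                           n_perm = 500, seed = 11)
  r2 <- randomization_test(big, "tgt", c("r1", "r2"), eff_all2,
                           n_perm = 500, seed = 11)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$mode, "sampled")
  expect_warning(randomization_test(big, "tgt", c("r1", "r2"), eff_all2,
                                    n_perm = 50, seed = 1),
                 class = "mixtoxsys_validation_warning")
})

test_that("identical groups give a null reallocation p-value", {
  ct <- ct_fixture(0, 0, 0, n = 3, sd = 0, seed = 1)
  ct$ct <- rep(c(30, 31, 29, 30, 31, 29), 3) # mirrored groups
  res <- randomization_test(ct, "tgt", c("r1", "r2"), eff_all2)
  expect_gte(res$p, 0.9)
})
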