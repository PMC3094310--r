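#' Call differentially expressed genes from moderated statistics
#'
#' A probe is called differentially expressed when its log-odds of
#' differential expression (B statistic) exceeds the threshold; the trend
#' (up/down) is the sign of its log2 ratio M. Probes with missing M or B are
#' dropped.
#'
#' @param table Data frame with columns `gene_id`, `M`, `B` (optionally
#'   `condition`).
#' @param b_threshold Log-odds threshold (default 0, i.e. odds > 1).
#' @param m_zero How to handle called probes with M exactly 0 (no trend):
#'   `"error"` (default) or `"drop"` with a warning.
#' @return Tibble of called genes with `gene_id`, `direction` (`"up"`/
#'   `"down"`), `M`, `B` (and `condition` if present).
#' @export
call_degs <- function(table, b_threshold = 0, m_zero = c("error", "drop")) {
  m_zero <- match.arg(m_zero)
  check_columns(table, c("gene_id", "M", "B"), "DEG table")
  if ("condition" %in% names(table)) {
    dup <- table |>
      dplyr::count(.data$condition, .data$gene_id) |>
      dplyr::filter(.data$n > 1)
  } else {
    dup <- table |> dplyr::count(.data$gene_id) |> dplyr::filter(.data$n > 1)
  }
  if (nrow(dup) > 0) {
    stop_mixtox("Duplicate gene ids within a condition.",
                "mixtoxsys_validation_error")
  }
  called <- table |>
    dplyr::filter(!is.na(.data$M), !is.na(.data$B), .data$B > b_threshold)
  zero <- called$M == 0
  if (any(zero)) {
    if (m_zero == "error") {
      stop_mixtox("Called gene(s) with M = 0 have no trend; set m_zero = 'drop' to exclude them.",
                  "mixtoxsys_tie_error")
    }
    warn(sprintf("Dropping %d called gene(s) with M = 0 (no trend).",
                 sum(zero)))
    called <- called[!zero, , drop = FALSE]
  }
  called |>
    dplyr::mutate(direction = ifelse(.data$M > 0, "up", "down"),
                  .after = "gene_id") |>
    tibble::as_tibble()
}

canonical_pair <- function(a, b, order) {
  paste(order[sort(match(c(a, b), order))], collapse = "/")
}

#' Exclusive overlap accounting of three trend-tagged DEG lists
#'
#' Partitions the union of three DEG lists into unique genes, exclusive
#' pairwise overlaps (genes shared by exactly two lists) and the triple
#' intersection, so that for every condition
#' `unique + its exclusive pairwise overlaps + triple = list size`.
#' Pairwise overlaps are split by trend agreement (sign of M in the two
#' conditions). A condition's "unique including opposite" count adds, to
#' its unique genes, the genes it shares with exactly one other list but
#' with the opposite trend — functionally original responses.
#'
#' Percentages are relative to the `focal` condition's list size for rows
#' involving the focal condition, and to the union of all three lists
#' otherwise.
#'
#' @param degs Tibble of called DEGs with columns `condition`, `gene_id`,
#'   `M` (e.g. from [call_degs()] on each condition, row-bound). Exactly 3
#'   conditions are required.
#' @param focal Optional condition name (e.g. the mixture) used as the
#'   percentage denominator for its rows and for the
#'   `unique_including_opposite` summary.
#' @return A `mixtox_overlap` object with tibbles `sizes`, `pairwise`,
#'   `triple`, `unique`.
#' @export
overlap_accounting <- function(degs, focal = NULL) {
  check_columns(degs, c("condition", "gene_id", "M"), "DEG lists")
  conds <- unique(degs$condition)
  if (length(conds) != 3) {
    stop_mixtox("Exactly three conditions are required.",
                "mixtoxsys_validation_error")
  }
  if (!is.null(focal) && !focal %in% conds) {
    stop_mixtox("`focal` must be one of the conditions.",
                "mixtoxsys_validation_error")
  }
  if (anyDuplicated(degs[c("condition", "gene_id")]) > 0) {
    stop_mixtox("Duplicate gene within a list.", "mixtoxsys_validation_error")
  }

  sets <- split(degs$gene_id, factor(degs$condition, levels = conds))
  signs <- lapply(split(degs, factor(degs$condition, levels = conds)),
                  function(d) setNames(sign(d$M), d$gene_id))
  sizes <- tibble::tibble(condition = conds,
                          n = unname(vapply(sets, length, integer(1))))
  union_all <- unique(degs$gene_id)
  n_union <- length(union_all)
  triple_genes <- Reduce(intersect, sets)

  pairs <- combn(conds, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    genes <- setdiff(intersect(sets[[pr[1]]], sets[[pr[2]]]), triple_genes)
    same <- sum(signs[[pr[1]]][genes] == signs[[pr[2]]][genes])
    denom <- if (!is.null(focal) && focal %in% pr) {
      sizes$n[sizes$condition == focal]
    } else n_union
    tibble::tibble(
      pair = canonical_pair(pr[1], pr[2], conds),
      count = length(genes), same_trend = same,
      opposite_trend = length(genes) - same,
      pct = 100 * length(genes) / denom
    )
  })

  uniq <- purrr::map_dfr(conds, function(cd) {
    others <- setdiff(conds, cd)
    u <- setdiff(sets[[cd]], union(sets[[others[1]]], sets[[others[2]]]))
    opp <- sum(pairwise$opposite_trend[
      vapply(pairs, function(pr) cd %in% pr, logical(1))])
    tibble::tibble(
      condition = cd, unique = length(u),
      unique_including_opposite = length(u) + opp,
      pct_unique = 100 * length(u) / sizes$n[sizes$condition == cd],
      pct_unique_including_opposite =
        100 * (length(u) + opp) / sizes$n[sizes$condition == cd]
    )
  })

  structure(
    list(sizes = sizes,
         pairwise = pairwise,
         triple = tibble::tibble(count = length(triple_genes),
                                 pct = 100 * length(triple_genes) / n_union),
         unique = uniq,
         n_union = n_union, focal = focal),
    class = "mixtox_overlap"
  )
}

#' @export
print.mixtox_overlap <- function(x, ...) {
  cat(sprintf("DEG overlap accounting (union of %d genes)\n", x$n_union))
  cat("List sizes:\n"); print(x$sizes)
  cat("Exclusive pairwise overlaps:\n"); print(x$pairwise)
  cat(sprintf("Triple intersection: %d\n", x$triple$count))
  cat("Unique genes:\n"); print(x$unique)
  invisible(x)
}

#' Microarray / qPCR concordance scoring
#'
#' A gene's two platform read-outs are concordant when either (i) the array
#' calls it differentially expressed (B > 0), the qPCR change is
#' significant, and the two point the same way (sign of M equals sign of
#' the qPCR relative-expression value), or (ii) the array does not call it
#' (B <= 0) and the qPCR change is not significant. Rows with missing array
#' values are excluded from the totals.
#'
#' @param rows Tibble with columns `gene_id`, `qpcr_value` (signed relative
#'   expression), `qpcr_significant` (logical), `M`, `B`; optionally
#'   `condition`, in which case per-condition counts are also returned.
#' @return A tibble with `matches`, `total` and `fraction` (rounded to 2
#'   decimals); one row per condition plus an `"overall"` row when a
#'   `condition` column is present.
#' @export
concordance <- function(rows) {
  check_columns(rows, c("gene_id", "qpcr_value", "qpcr_significant", "M", "B"),
                "concordance rows")
  usable <- rows |> dplyr::filter(!is.na(.data$M), !is.na(.data$B))
  if (nrow(usable) == 0) {
    stop_mixtox("No rows with array values to compare.",
                "mixtoxsys_empty_comparison_error")
  }
  usable <- usable |>
    dplyr::mutate(match = (.data$B > 0 & .data$qpcr_significant &
                             sign(.data$M) == sign(.data$qpcr_value)) |
                    (.data$B <= 0 & !.data$qpcr_significant))
  summarise_match <- function(d) {
    tibble::tibble(matches = sum(d$match), total = nrow(d),
                   fraction = round(sum(d$match) / nrow(d), 2))
  }
  if ("condition" %in% names(rows)) {
    per <- usable |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_modify(~ summarise_match(.x)) |>
      dplyr::ungroup()
    dplyr::bind_rows(per, dplyr::bind_cols(condition = "overall",
                                           summarise_match(usable)))
  } else {
    summarise_match(usable)
  }
}

# ---- qPCR ------------------------------------------------------------------

mean_delta_ct <- function(ct, gene) {
  d <- ct[ct$gene_id == gene, , drop = FALSE]
  ctrl <- d$ct[d$group == "control"]
  expo <- d$ct[d$group == "exposed"]
  if (length(ctrl) == 0 || length(expo) == 0) {
    stop_mixtox(sprintf("Gene '%s' is missing from one group.", gene),
                "mixtoxsys_normalization_error")
  }
  mean(ctrl) - mean(expo)
}

rel_expr_one <- function(ct, target, references, eff) {
  r_t <- eff[[target]]^mean_delta_ct(ct, target)
  r_refs <- vapply(references, function(g) eff[[g]]^mean_delta_ct(ct, g),
                   numeric(1))
  r_t / geometric_mean(r_refs)
}

check_ct_table <- function(ct, genes, efficiencies) {
  check_columns(ct, c("gene_id", "group", "replicate", "ct"), "Ct table")
  eff <- setNames(efficiencies$efficiency, efficiencies$gene_id)
  missing <- setdiff(genes, names(eff))
  if (length(missing) > 0) {
    stop_mixtox(sprintf("No amplification efficiency for gene(s): %s",
                        paste(missing, collapse = ", ")),
                "mixtoxsys_validation_error")
  }
  if (any(eff[genes] <= 1 | eff[genes] > 2)) {
    stop_mixtox("Amplification efficiencies must lie in (1, 2].",
                "mixtoxsys_validation_error")
  }
  eff
}

#' Efficiency-corrected relative expression, geometrically normalised
#'
#' Computes, per target gene, the efficiency-corrected expression ratio
#' \deqn{R = \frac{E_t^{\Delta Ct_t}}{\mathrm{geomean}_r\, E_r^{\Delta Ct_r}}}
#' where \eqn{\Delta Ct = \overline{Ct}_{control} - \overline{Ct}_{exposed}}
#' and the denominator geometrically averages over the reference genes
#' (e.g. 18S rRNA and an invariant alkaline phosphatase). With all
#' efficiencies equal to 2 this is exactly the 2^(-ddCt) method.
#'
#' @param ct Tibble with columns `gene_id`, `group` (`"control"`/
#'   `"exposed"`), `replicate`, `ct` (cycles).
#' @param targets Character vector of target gene ids.
#' @param references Character vector of reference gene ids (>= 1).
#' @param efficiencies Tibble with columns `gene_id`, `efficiency`
#'   (in (1, 2]).
#' @return Tibble with `gene_id`, `ratio`, `log2_ratio`.
#' @export
relative_expression <- function(ct, targets, references, efficiencies) {
  if (length(references) < 1) {
    stop_mixtox("At least one reference gene is required.",
                "mixtoxsys_validation_error")
  }
  eff <- check_ct_table(ct, c(targets, references), efficiencies)
  purrr::map_dfr(targets, function(tg) {
    r <- rel_expr_one(ct, tg, references, as.list(eff))
    tibble::tibble(gene_id = tg, ratio = r, log2_ratio = log2(r))
  })
}

#' Randomization test for qPCR relative expression
#'
#' Fixed-reallocation randomization test: replicates (sample units carrying
#' the Ct values of target and reference genes) are reallocated between the
#' control and exposed groups and the null distribution of |log2 ratio| is
#' compared with the observed value. All C(n1+n2, n1) reallocations are
#' enumerated when there are at most 10,000 of them; otherwise `n_perm`
#' random reallocations are drawn from the seeded stream.
#'
#' @inheritParams relative_expression
#' @param target Single target gene id.
#' @param n_perm Number of random reallocations when enumeration is not
#'   feasible (>= 100 recommended; smaller values trigger a warning).
#' @param seed Integer seed for the Monte-Carlo mode.
#' @return One-row tibble with `gene_id`, `ratio`, `log2_ratio`, `p`,
#'   `mode` (`"exhaustive"`/`"sampled"`), `n_perm`.
#' @export
randomization_test <- function(ct, target, references, efficiencies,
                               n_perm = 2000, seed = 1) {
  if (n_perm < 100) {
    warn("Fewer than 100 permutations gives an unstable p-value.",
         class = "mixtoxsys_validation_warning")
  }
  eff <- as.list(check_ct_table(ct, c(target, references), efficiencies))
  randomization_test_impl(ct, target, references, eff, n_perm, seed)
}

randomization_test_impl <- function(ct, target, references, eff, n_perm, seed) {
  genes <- c(target, references)
  ct <- ct[ct$gene_id %in% genes, , drop = FALSE]
  units <- unique(ct[c("group", "replicate")])
  n1 <- sum(units$group == "control")
  n2 <- sum(units$group == "exposed")
  if (n1 == 0 || n2 == 0) {
    stop_mixtox("Both groups need replicates.", "mixtoxsys_validation_error")
  }
  unit_id <- paste(units$group, units$replicate, sep = ".")
  ct$unit <- paste(ct$group, ct$replicate, sep = ".")

  stat_for <- function(ctrl_units) {
    relab <- ct
    relab$group <- ifelse(relab$unit %in% ctrl_units, "control", "exposed")
    abs(log2(rel_expr_one(relab, target, references, eff)))
  }
  observed <- stat_for(unit_id[units$group == "control"])

  n_comb <- choose(n1 + n2, n1)
  if (n_comb <= 10000) {
    splits <- combn(unit_id, n1, simplify = FALSE)
    stats <- vapply(splits, stat_for, numeric(1))
    p <- mean(stats >= observed - 1e-12)
    mode <- "exhaustive"; n_used <- length(splits)
  } else {
    stats <- with_gen_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat_for(sample(unit_id, n1)),
             numeric(1))
    })
    p <- (1 + sum(stats >= observed - 1e-12)) / (n_perm + 1)
    mode <- "sampled"; n_used <- n_perm
  }
  r <- rel_expr_one(ct, target, references, eff)
  tibble::tibble(gene_id = target, ratio = r, log2_ratio = log2(r),
                 p = p, mode = mode, n_perm = n_used)
}
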