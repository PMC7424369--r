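# Population-level DEG detection from concordant/reversal REOs: each gene is
# tested for whether its ordering against stable partner genes differs
# between groups (Fisher exact), with iterative removal of already-flagged
# genes from the partner background.

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Counts fill the table row-wise: `a`, `b` on the first row, `c`, `d` on the
#' second. The two-sided p-value sums all tables with the same margins whose
#' point probability does not exceed that of the observed table, the
#' convention shared by mainstream statistics environments. Vectorised over
#' the four arguments.
#'
#' @param a,b,c,d nonnegative integer counts
#' @return numeric vector of two-sided p-values
#' @examples
#' fisher_exact_2x2(31, 18, 33, 11)  # 0.266 to 3 d.p.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  if (any(counts < 0)) abort("counts must be nonnegative")
  if (any(rowSums(counts) == 0)) abort("at least one count must be positive")
  vapply(seq_len(nrow(counts)), function(r) {
    fisher.test(matrix(counts[r, ], nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
}

# Long partner table from a reo_comparison: one row per (gene, partner)
# incidence with logical columns g1_gt / g2_gt ("gene above partner" under
# each group's stable direction).
comparison_to_partner_table <- function(comp) {
  tb <- as_tibble(comp)
  bind_rows(
    tibble(gene = tb$gene_a, partner = tb$gene_b,
           g1_gt = tb$direction_1 == "a_gt_b",
           g2_gt = tb$direction_2 == "a_gt_b"),
    tibble(gene = tb$gene_b, partner = tb$gene_a,
           g1_gt = tb$direction_1 == "a_lt_b",
           g2_gt = tb$direction_2 == "a_lt_b")
  )
}

tabulate_gene_counts <- function(partners) {
  partners |>
    group_by(.data$gene) |>
    summarise(
      n_partners = dplyr::n(),
      g1_gt = sum(.data$g1_gt),
      g2_gt = sum(.data$g2_gt),
      .groups = "drop"
    ) |>
    mutate(
      g1_lt = .data$n_partners - .data$g1_gt,
      g2_lt = .data$n_partners - .data$g2_gt
    ) |>
    select("gene", "g1_gt", "g1_lt", "g2_gt", "g2_lt")
}

#' RankCompV2-style differential expression calling
#'
#' Builds each group's significantly stable pair set, intersects them, and
#' asks per gene whether the split of its common stable partners into
#' "gene above partner" versus "gene below partner" differs between the two
#' groups (two-sided Fisher exact test, BH-adjusted across genes with at
#' least one partner). Because a strongly shifted gene contaminates the
#' partner background of every gene it pairs with, the test is iterated:
#' at each round the previously flagged genes are removed from all partner
#' sets and the remaining genes are re-tested, until the flagged set is
#' stable or `max_iter` is reached.
#'
#' @param expr expression table or matrix
#' @param group1_samples,group2_samples character vectors of sample ids
#' @param alpha FDR threshold for DEG calling, default 0.05
#' @param stable_alpha FDR threshold for per-group stable pairs, default 0.05
#' @param max_iter maximum filter iterations, default 10
#' @param block_size pair block size passed to [stable_pairs()]
#' @param stable_sets optional precomputed list of two `reo_stable_pairs`
#'   objects (group 1 then group 2); when supplied, `expr` and the sample
#'   vectors are not touched for pair building
#' @return a `reo_deg` tibble with one row per gene having at least one
#'   common stable partner: `gene_id`, `g1_gt`, `g1_lt`, `g2_gt`, `g2_lt`
#'   (final-iteration partner counts), `fisher_p`, `fdr`, `direction`
#'   (`"up_in_group2"`, `"down_in_group2"` or `"none"`), `flagged` and
#'   `flagged_iteration`; attributes record `iterations_run`, `converged`,
#'   both alphas and the underlying comparison's summary
#' @export
rankcomp_v2 <- function(expr = NULL, group1_samples = NULL, group2_samples = NULL,
                        alpha = 0.05, stable_alpha = 0.05, max_iter = 10,
                        block_size = 1e6, stable_sets = NULL) {
  if (max_iter < 1) abort("max_iter must be a positive integer")
  if (is.null(stable_sets)) {
    if (is.null(expr)) abort("supply either expr + sample groups or stable_sets")
    set1 <- stable_pairs(expr, group1_samples, alpha = stable_alpha,
                         block_size = block_size, group = "group1")
    set2 <- stable_pairs(expr, group2_samples, alpha = stable_alpha,
                         block_size = block_size, group = "group2")
  } else {
    set1 <- stable_sets[[1]]
    set2 <- stable_sets[[2]]
  }
  comp <- compare_stable_pairs(set1, set2)
  if (attr(comp, "m") == 0) {
    abort("no common stable pairs between the groups; RankCompV2 cannot proceed")
  }
  partners <- comparison_to_partner_table(comp)

  test_round <- function(flagged_prev) {
    active <- partners[!partners$partner %in% flagged_prev, ]
    counts <- tabulate_gene_counts(active)
    if (nrow(counts) == 0) return(list(counts = counts, flagged = character(0)))
    counts$fisher_p <- fisher_exact_2x2(counts$g1_gt, counts$g1_lt,
                                        counts$g2_gt, counts$g2_lt)
    counts$fdr <- p.adjust(counts$fisher_p, method = "BH")
    p1 <- counts$g1_gt / (counts$g1_gt + counts$g1_lt)
    p2 <- counts$g2_gt / (counts$g2_gt + counts$g2_lt)
    counts$direction <- dplyr::case_when(
      counts$fdr < alpha & p2 > p1 ~ "up_in_group2",
      counts$fdr < alpha & p2 < p1 ~ "down_in_group2",
      TRUE ~ "none"
    )
    list(counts = counts, flagged = counts$gene[counts$direction != "none"])
  }

  flagged_prev <- character(0)
  first_flagged <- c()
  converged <- FALSE
  iterations <- 0L
  round <- NULL
  for (t in seq_len(max_iter)) {
    round <- test_round(flagged_prev)
    iterations <- t
    newly <- setdiff(round$flagged, names(first_flagged))
    if (length(newly)) {
      first_flagged <- c(first_flagged,
                         stats::setNames(rep(t - 1L, length(newly)), newly))
    }
    if (setequal(round$flagged, flagged_prev)) {
      converged <- TRUE
      break
    }
    flagged_prev <- round$flagged
  }
  counts <- round$counts
  counts$flagged <- counts$direction != "none"
  counts$flagged_iteration <- ifelse(
    counts$flagged, unname(first_flagged[counts$gene]), NA_integer_)
  out <- counts |>
    rename(gene_id = "gene") |>
    arrange(.data$gene_id)
  new_reopair_tbl(out, "reo_deg",
    alpha = alpha, stable_alpha = stable_alpha,
    iterations_run = iterations, converged = converged,
    m = attr(comp, "m"), k_reversal = attr(comp, "k_reversal"),
    reversal_ratio = attr(comp, "reversal_ratio"),
    groups = attr(comp, "groups")
  )
}

#' @export
print.reo_deg <- function(x, ...) {
  cat(sprintf(
    "RankCompV2 DEG table: %d genes tested, %d flagged (FDR < %g, %d iteration(s), %s)\n",
    nrow(x), sum(x$flagged), attr(x, "alpha"), attr(x, "iterations_run"),
    if (attr(x, "converged")) "converged" else "not converged"
  ))
  NextMethod()
}
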