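# Core REO machinery: within-sample pair orderings, the binomial stability
# test, BH selection of stable pairs, and concordant/reversal comparison of
# two groups' stable-pair sets.

#' One-tailed binomial stability p-value for a gene pair
#'
#' A pair's relative ordering is consistent in `k` of `n` informative samples
#' (samples where the two values differ). Under the null that either ordering
#' is equally likely in each sample (probability `p0`), the p-value is the
#' upper tail P(X >= k) for X ~ Binomial(n, p0). The test is one-tailed with
#' `k` the majority count; no two-sided doubling is applied.
#'
#' @param k consistent-sample count (vectorised)
#' @param n informative-sample count (vectorised)
#' @param p0 null probability of one ordering per sample, default 0.5
#' @return numeric vector of upper-tail p-values
#' @examples
#' binomial_stability_p(10, 10)  # 2^-10
#' binomial_stability_p(0, 10)   # 1
#' @export
binomial_stability_p <- function(k, n, p0 = 0.5) {
  if (any(n < 1)) abort("n must be >= 1")
  if (any(k < 0) || any(k > n)) abort("k must satisfy 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie in (0, 1)")
  p <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  # exact endpoints: the empty sum and the single surviving term
  k <- rep_len(k, length(p))
  n <- rep_len(n, length(p))
  p[k == 0] <- 1
  sel <- k == n
  p[sel] <- p0^n[sel]
  p
}

# Iterate over canonical pairs of a gene-sorted matrix in fixed-size blocks,
# calling fn(gene_a, gene_b, n_gt, n_lt, n_tie) per block. Peak memory is
# O(block_size x samples) regardless of the total pair count.
iterate_pair_blocks <- function(m, block_size, fn) {
  G <- nrow(m)
  idx <- pair_indices(G)
  total <- length(idx$i)
  genes <- rownames(m)
  start <- 1L
  while (start <= total) {
    end <- min(start + as.integer(block_size) - 1L, total)
    bi <- idx$i[start:end]
    bj <- idx$j[start:end]
    A <- m[bi, , drop = FALSE]
    B <- m[bj, , drop = FALSE]
    n_gt <- as.integer(rowSums(A > B))
    n_lt <- as.integer(rowSums(A < B))
    n_tie <- ncol(m) - n_gt - n_lt
    fn(genes[bi], genes[bj], n_gt, n_lt, n_tie)
    start <- end + 1L
  }
  invisible(total)
}

#' Summarise within-sample orderings for every gene pair
#'
#' For each of the C(G, 2) canonical pairs (gene_a < gene_b lexicographically)
#' counts the samples where gene_a exceeds gene_b (`n_gt`), where it is below
#' (`n_lt`), and ties (`n_tie`). `n = n_gt + n_lt` is the informative sample
#' count and `k = max(n_gt, n_lt)` the majority count, the two quantities the
#' binomial stability test consumes. Pairs are processed in fixed-size blocks
#' so memory scales with the block, not the full pair space.
#'
#' @param expr expression table or matrix
#' @param samples optional character vector restricting to a sample subset
#' @param block_size pairs per block, default 1e6
#' @return tibble with columns `gene_a`, `gene_b`, `n_gt`, `n_lt`, `n_tie`,
#'   `n`, `k`
#' @export
summarize_pairs <- function(expr, samples = NULL, block_size = 1e6) {
  m <- subset_samples(as_expr_matrix(expr), samples)
  if (nrow(m) < 2) abort("need at least 2 genes")
  if (ncol(m) < 2) abort("need at least 2 samples")
  m <- m[order(rownames(m)), , drop = FALSE]
  acc <- vector("list", 0)
  iterate_pair_blocks(m, block_size, function(ga, gb, n_gt, n_lt, n_tie) {
    acc[[length(acc) + 1L]] <<- tibble(
      gene_a = ga, gene_b = gb,
      n_gt = n_gt, n_lt = n_lt, n_tie = n_tie,
      n = n_gt + n_lt, k = pmax(n_gt, n_lt)
    )
  })
  dplyr::bind_rows(acc)
}

# Benjamini-Hochberg over a discrete p-value distribution given as distinct
# values with multiplicities. Returns adjusted p per distinct value,
# bit-identical to p.adjust(rep(p, w), "BH") evaluated at those values.
bh_adjust_weighted <- function(p, weights) {
  m <- sum(weights)
  ord <- order(p)
  p_s <- p[ord]
  cum <- cumsum(weights[ord])
  cand <- m / cum * p_s
  adj <- pmin(1, rev(cummin(rev(cand))))
  adj[order(ord)]
}

#' Identify significantly stable gene pairs in a sample group
#'
#' Runs the one-tailed binomial stability test on every canonical gene pair
#' and applies Benjamini-Hochberg correction across all C(G, 2) tests
#' (including uninformative pairs, which count toward the multiplicity).
#' Because the p-value depends only on (k, n), the adjustment is computed
#' over the multiset of distinct (k, n) values weighted by their pair counts
#' and mapped back — identical to naive BH on the full p-vector. Pairs with
#' adjusted p below `alpha` and a strict majority direction are retained.
#'
#' @inheritParams summarize_pairs
#' @param alpha FDR threshold, default 0.05
#' @param p0 per-sample null ordering probability, default 0.5
#' @param group optional group label recorded on the result
#' @return a `reo_stable_pairs` tibble with columns `gene_a`, `gene_b`,
#'   `direction` (`"a_gt_b"` or `"a_lt_b"`), `k`, `n`, `p_value`, `fdr`;
#'   attributes record the gene universe, total pair count, sample count and
#'   `alpha`
#' @export
stable_pairs <- function(expr, samples = NULL, alpha = 0.05, p0 = 0.5,
                         block_size = 1e6, group = NULL) {
  m <- subset_samples(as_expr_matrix(expr), samples)
  if (nrow(m) < 2) abort("need at least 2 genes")
  if (ncol(m) < 2) abort("need at least 2 samples")
  m <- m[order(rownames(m)), , drop = FALSE]

  # Pass 1: tally distinct (k, n) combinations over all pairs.
  tallies <- new.env(parent = emptyenv())
  iterate_pair_blocks(m, block_size, function(ga, gb, n_gt, n_lt, n_tie) {
    key <- paste(pmax(n_gt, n_lt), n_gt + n_lt)
    for (tb in split(seq_along(key), key)) {
      kk <- key[tb[1]]
      tallies[[kk]] <- (tallies[[kk]] %||% 0L) + length(tb)
    }
  })
  keys <- ls(tallies)
  kn <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  k_vals <- as.integer(kn[, 1])
  n_vals <- as.integer(kn[, 2])
  w <- vapply(keys, function(kk) tallies[[kk]], integer(1))
  p_vals <- rep(1, length(k_vals))
  inf <- n_vals > 0
  p_vals[inf] <- binomial_stability_p(k_vals[inf], n_vals[inf], p0)
  fdr_vals <- bh_adjust_weighted(p_vals, w)
  keep <- fdr_vals < alpha & n_vals > 0 & 2L * k_vals > n_vals
  lookup_fdr <- stats::setNames(fdr_vals, keys)
  keep_keys <- keys[keep]

  # Pass 2: re-enumerate and retain pairs whose (k, n) combination survived.
  acc <- vector("list", 0)
  iterate_pair_blocks(m, block_size, function(ga, gb, n_gt, n_lt, n_tie) {
    key <- paste(pmax(n_gt, n_lt), n_gt + n_lt)
    sel <- key %in% keep_keys
    if (!any(sel)) return(invisible(NULL))
    k <- pmax(n_gt, n_lt)[sel]
    n <- (n_gt + n_lt)[sel]
    acc[[length(acc) + 1L]] <<- tibble(
      gene_a = ga[sel], gene_b = gb[sel],
      direction = ifelse(n_gt[sel] > n_lt[sel], "a_gt_b", "a_lt_b"),
      k = k, n = n,
      p_value = binomial_stability_p(k, n, p0),
      fdr = unname(lookup_fdr[key[sel]])
    )
  })
  out <- if (length(acc)) dplyr::bind_rows(acc) else tibble(
    gene_a = character(), gene_b = character(), direction = character(),
    k = integer(), n = integer(), p_value = numeric(), fdr = numeric()
  )
  new_reopair_tbl(out, "reo_stable_pairs",
    genes = rownames(m),
    n_pairs_total = choose(nrow(m), 2),
    n_samples = ncol(m),
    alpha = alpha, p0 = p0,
    group = group %||% NA_character_
  )
}

#' Classify the overlap of two stable-pair sets
#'
#' Intersects two groups' stable-pair sets by pair identity. A common pair
#' whose majority directions agree is concordant; one whose directions are
#' opposite is a reversal pair. The reversal ratio k/m (reversal pairs over
#' common pairs) is the headline measure of how strongly a factor perturbs
#' the ordering structure.
#'
#' @param set1,set2 `reo_stable_pairs` objects built over the same gene
#'   universe
#' @return a `reo_comparison` tibble of the common pairs with columns
#'   `gene_a`, `gene_b`, `direction_1`, `direction_2`, `status`
#'   (`"concordant"`/`"reversal"`); attributes `m`, `k_reversal`,
#'   `reversal_ratio` (NA when m = 0) and the two group labels
#' @export
compare_stable_pairs <- function(set1, set2) {
  if (!inherits(set1, "reo_stable_pairs") || !inherits(set2, "reo_stable_pairs")) {
    abort("compare_stable_pairs expects two reo_stable_pairs objects")
  }
  if (!identical(attr(set1, "genes"), attr(set2, "genes"))) {
    abort("stable-pair sets were built over different gene universes")
  }
  common <- inner_join(
    as_tibble(set1)[, c("gene_a", "gene_b", "direction")],
    as_tibble(set2)[, c("gene_a", "gene_b", "direction")],
    by = c("gene_a", "gene_b"), suffix = c("_1", "_2")
  )
  common$status <- ifelse(common$direction_1 == common$direction_2,
                          "concordant", "reversal")
  m <- nrow(common)
  k_rev <- sum(common$status == "reversal")
  new_reopair_tbl(common, "reo_comparison",
    m = m, k_reversal = k_rev,
    reversal_ratio = if (m > 0) k_rev / m else NA_real_,
    groups = c(attr(set1, "group"), attr(set2, "group")),
    genes = attr(set1, "genes")
  )
}

#' @export
print.reo_stable_pairs <- function(x, ...) {
  cat(sprintf(
    "Stable REO pairs: %d of %s pairs (G = %d genes, %d samples, FDR < %g)%s\n",
    nrow(x), format(attr(x, "n_pairs_total"), big.mark = ","),
    length(attr(x, "genes")), attr(x, "n_samples"), attr(x, "alpha"),
    if (!is.na(attr(x, "group"))) paste0(" [group: ", attr(x, "group"), "]") else ""
  ))
  NextMethod()
}

#' @export
print.reo_comparison <- function(x, ...) {
  cat(sprintf(
    "REO comparison: m = %d common stable pairs, %d reversal (ratio %s)\n",
    attr(x, "m"), attr(x, "k_reversal"),
    if (is.na(attr(x, "reversal_ratio"))) "undefined"
    else format(attr(x, "reversal_ratio"), digits = 4)
  ))
  NextMethod()
}
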