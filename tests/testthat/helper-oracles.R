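# Independent brute-force oracles and small fixture builders. Each oracle is
# a direct transcription of a definition (term-by-term sums, exhaustive
# enumeration, naive double loops) and never shares code with the package
# paths it checks.

# Upper-tail binomial P(X >= k) by explicit term-by-term summation.
brute_binom_upper <- function(k, n, p0 = 0.5) {
  if (k > n) return(0)
  i <- k:n
  sum(choose(n, i) * p0^i * (1 - p0)^(n - i))
}

# Two-sided Fisher exact p by exhaustive enumeration of all 2x2 tables with
# the observed margins, summing point probabilities <= that of the observed
# table (with the standard 1e-7 relative slack for float comparison).
brute_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  x_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(x_range, c1, n - c1, r1)
  obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric P(X >= x) by direct combinatorial summation.
brute_hyper_upper <- function(x, N, K, q) {
  xs <- x:min(K, q)
  sum(exp(lchoose(K, xs) + lchoose(N - K, q - xs) - lchoose(N, q)))
}

# Naive per-pair ordering summary: explicit double loop over genes in
# lexicographic order and over samples.
naive_pair_summary <- function(m) {
  m <- m[order(rownames(m)), , drop = FALSE]
  genes <- rownames(m)
  G <- nrow(m)
  rows <- list()
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      n_gt <- 0L; n_lt <- 0L; n_tie <- 0L
      for (s in seq_len(ncol(m))) {
        if (m[i, s] > m[j, s]) n_gt <- n_gt + 1L
        else if (m[i, s] < m[j, s]) n_lt <- n_lt + 1L
        else n_tie <- n_tie + 1L
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene_a = genes[i], gene_b = genes[j],
        n_gt = n_gt, n_lt = n_lt, n_tie = n_tie,
        n = n_gt + n_lt, k = max(n_gt, n_lt)
      )
    }
  }
  do.call(rbind, rows)
}

# Naive stable-pair selection: binomial p for every pair, p.adjust("BH")
# over the full p-vector (uninformative pairs included with p = 1), keep
# fdr < alpha with a strict majority.
naive_stable_pairs <- function(m, alpha = 0.05, p0 = 0.5) {
  sm <- naive_pair_summary(m)
  p <- ifelse(sm$n == 0, 1, mapply(brute_binom_upper, sm$k, sm$n, p0))
  fdr <- p.adjust(p, method = "BH")
  keep <- fdr < alpha & sm$n > 0 & 2 * sm$k > sm$n
  out <- sm[keep, ]
  out$direction <- ifelse(out$n_gt > out$n_lt, "a_gt_b", "a_lt_b")
  out$p_value <- p[keep]
  out$fdr <- fdr[keep]
  rownames(out) <- NULL
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
# Feasible only for small sizes (choose(n1 + n2, n1) assignments).
enum_mwu_two_sided <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# A random expression matrix with lexicographically sortable gene ids.
random_expr_matrix <- function(G, S, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rlnorm(G * S, meanlog = 5, sdlog = 1), G, S)
    rownames(m) <- sprintf("g%03d", seq_len(G))
    colnames(m) <- sprintf("s%03d", seq_len(S))
    m
  })
}

# A matrix in which every sample shares one strict total order of the genes.
total_order_matrix <- function(G, S) {
  m <- matrix(rep(seq_len(G), S), G, S)
  rownames(m) <- sprintf("g%03d", seq_len(G))
  colnames(m) <- sprintf("s%03d", seq_len(S))
  m
}

# Forge a reo_stable_pairs object directly from a pair table (unit-test
# constructor for compare/rankcomp stages).
forge_stable_set <- function(df, genes, group = NA_character_, alpha = 0.05) {
  tb <- tibble::as_tibble(df)
  if (!"k" %in% names(tb)) tb$k <- 20L
  if (!"n" %in% names(tb)) tb$n <- 20L
  if (!"p_value" %in% names(tb)) tb$p_value <- 2^-20
  if (!"fdr" %in% names(tb)) tb$fdr <- 1e-4
  structure(tb,
    genes = genes, n_pairs_total = choose(length(genes), 2),
    n_samples = 20L, alpha = alpha, p0 = 0.5, group = group,
    class = c("reo_stable_pairs", class(tb))
  )
}

# Canonical pair table (gene_a < gene_b) for a gene vector.
all_pairs_of <- function(genes) {
  genes <- sort(genes)
  G <- length(genes)
  i <- rep.int(seq_len(G - 1L), times = (G - 1L):1L)
  j <- sequence((G - 1L):1L) + i
  tibble::tibble(gene_a = genes[i], gene_b = genes[j])
}
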