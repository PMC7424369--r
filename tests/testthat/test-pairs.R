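test_that("binomial stability p matches closed forms and brute-force sums", {
  expect_identical(binomial_stability_p(10, 10), 0.5^10)
  expect_identical(binomial_stability_p(0, 10), 1)
  expect_equal(binomial_stability_p(5, 10), 638 / 1024)

  for (n in 1:20) {
    k <- 0:n
    expect_equal(binomial_stability_p(k, n),
                 vapply(k, brute_binom_upper, numeric(1), n = n),
                 tolerance = 1e-12, info = paste("n =", n))
  }
  # asymmetric null probability
  expect_equal(binomial_stability_p(7, 9, p0 = 0.3),
               brute_binom_upper(7, 9, p0 = 0.3))

  expect_error(binomial_stability_p(5, 0), "n must")
  expect_error(binomial_stability_p(11, 10), "k must")
})

test_that("binomial stability p is monotone non-increasing in k and stable at large n", {
  for (n in c(10, 1000, 10000)) {
    p <- binomial_stability_p(0:n, n)
    expect_true(all(diff(p) <= 0))
    expect_true(all(is.finite(p)) && all(p >= 0 & p <= 1))
  }
  # deep-tail accuracy at n = 10000 against a log-space term sum
  log_terms <- lchoose(10000, 5300:10000) - 10000 * log(2)
  mx <- max(log_terms)
  brute <- exp(mx) * sum(exp(log_terms - mx))
  expect_equal(binomial_stability_p(5300, 10000), brute, tolerance = 1e-9)
})

test_that("pair summaries count orderings and ties per sample", {
  m <- rbind(gA = c(5, 4, 3), gB = c(1, 2, 3))
  colnames(m) <- c("s1", "s2", "s3")
  sm <- summarize_pairs(m)
  expect_equal(nrow(sm), 1)
  expect_equal(sm$n_gt, 2L)
  expect_equal(sm$n_lt, 0L)
  expect_equal(sm$n_tie, 1L)   # tied sample excluded from n
  expect_equal(sm$n, 2L)
  expect_equal(sm$k, 2L)

  m4 <- random_expr_matrix(4, 5, seed = 3)
  expect_equal(nrow(summarize_pairs(m4)), 6)  # C(4,2)

  expect_error(summarize_pairs(m[1, , drop = FALSE]), "2 genes")
  expect_error(summarize_pairs(m[, 1, drop = FALSE]), "2 samples")
})

test_that("blocked pair enumeration equals the naive double loop", {
  for (seed in 1:3) {
    m <- random_expr_matrix(50, 10, seed = seed)
    got <- summarize_pairs(m, block_size = 97)  # force many partial blocks
    ref <- naive_pair_summary(m)
    expect_equal(as.data.frame(got), ref, info = paste("seed", seed))
  }
  # with planted ties
  m <- random_expr_matrix(20, 8, seed = 9)
  m[3, ] <- m[7, ]
  expect_equal(as.data.frame(summarize_pairs(m, block_size = 11)),
               naive_pair_summary(m))
})

test_that("a shared strict total order makes every pair stable", {
  m <- total_order_matrix(30, 20)
  sp <- stable_pairs(m, alpha = 0.05)
  expect_equal(nrow(sp), choose(30, 2))
  expect_true(all(sp$k == 20 & sp$n == 20))
  expect_equal(unique(sp$p_value), 2^-20)
  # direction must match the shared order: gene ids sorted == value order
  expect_true(all(sp$direction == "a_lt_b"))
})

test_that("discrete-BH stable pair selection equals naive BH on the full p-vector", {
  for (seed in c(2, 5, 11)) {
    m <- random_expr_matrix(15, 12, seed = seed)
    # mix of strong and null structure: overwrite half the genes with a total order
    m[1:8, ] <- total_order_matrix(8, 12) * 1000
    rownames(m) <- sprintf("g%03d", 1:15)
    got <- stable_pairs(m, alpha = 0.05)
    ref <- naive_stable_pairs(m, alpha = 0.05)
    expect_equal(got$gene_a, ref$gene_a)
    expect_equal(got$gene_b, ref$gene_b)
    expect_equal(got$direction, ref$direction)
    expect_equal(got$p_value, ref$p_value, tolerance = 1e-12)
    expect_equal(got$fdr, ref$fdr, tolerance = 1e-12)
  }
})

test_that("a weakly consistent pair is excluded among strongly stable ones", {
  # 46 genes in a strict shared order give 1035 strongly stable pairs;
  # one extra gene pair at k = 6 of n = 10 has raw p above any BH cutoff.
  m <- total_order_matrix(46, 10) * 10
  extra <- rbind(
    zza = c(2, 2, 2, 2, 1, 1, 1, 1, 1, 1) * 0.1,
    zzb = c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2) * 0.1
  )  # zza vs zzb: n_gt = 4, n_lt = 6 -> k = 6, n = 10
  colnames(extra) <- colnames(m)
  mm <- rbind(m, extra)
  sp <- stable_pairs(mm, alpha = 0.05)
  expect_false(any(sp$gene_a == "zza" & sp$gene_b == "zzb"))
  expect_gte(brute_binom_upper(6, 10), 0.05)  # raw p already non-significant
  # the strongly ordered pairs all survive
  expect_gte(nrow(sp), choose(46, 2))
})

test_that("stable pairs are invariant under strictly monotone transforms", {
  m <- random_expr_matrix(25, 14, seed = 21)
  base <- stable_pairs(m)
  expect_identical(tidy(stable_pairs(log(m))), tidy(base))
  expect_identical(tidy(stable_pairs(m^3)), tidy(base))
  expect_identical(tidy(stable_pairs(2.5 * m + 7)), tidy(base))
})

test_that("comparison classifies concordant and reversal pairs", {
  genes <- sprintf("g%03d", 1:60)
  pairs <- all_pairs_of(genes)[1:1000, ]
  pairs$direction <- rep(c("a_gt_b", "a_lt_b"), length.out = 1000)
  set1 <- forge_stable_set(pairs, genes, group = "grp1")
  pairs2 <- pairs
  pairs2$direction[c(10, 500)] <- ifelse(pairs$direction[c(10, 500)] == "a_gt_b",
                                         "a_lt_b", "a_gt_b")
  set2 <- forge_stable_set(pairs2, genes, group = "grp2")

  cmp <- compare_stable_pairs(set1, set2)
  expect_equal(attr(cmp, "m"), 1000)
  expect_equal(attr(cmp, "k_reversal"), 2)
  expect_equal(attr(cmp, "reversal_ratio"), 0.002)
  expect_equal(sum(cmp$status == "concordant") + sum(cmp$status == "reversal"), 1000)

  # identity comparison: ratio 0
  cmp0 <- compare_stable_pairs(set1, set1)
  expect_equal(attr(cmp0, "reversal_ratio"), 0)

  # symmetry: m and k_reversal unchanged when arguments swap
  cmp_swap <- compare_stable_pairs(set2, set1)
  expect_equal(attr(cmp_swap, "m"), attr(cmp, "m"))
  expect_equal(attr(cmp_swap, "k_reversal"), attr(cmp, "k_reversal"))
})

test_that("comparison handles empty overlap and mismatched universes", {
  genes <- sprintf("g%03d", 1:10)
  pairs <- all_pairs_of(genes)
  pairs$direction <- "a_gt_b"
  s1 <- forge_stable_set(pairs[1:5, ], genes)
  s2 <- forge_stable_set(pairs[6:10, ], genes)
  cmp <- compare_stable_pairs(s1, s2)
  expect_equal(attr(cmp, "m"), 0)
  expect_true(is.na(attr(cmp, "reversal_ratio")))  # undefined, not an error

  s3 <- forge_stable_set(pairs[1:5, ], c(genes, "g999"))
  expect_error(compare_stable_pairs(s1, s3), "universe")
})

test_that("measured reversal ratio matches an exhaustive scan on generated data", {
  sim <- simulate_reo_data(reo_generator_config(
    n_genes = 80, samples_per_group = c(25, 25), noise_sigma = 0.02,
    n_deg = 4, rank_shift = 25, seed = 55
  ))
  md <- sim$metadata
  s1 <- stable_pairs(sim$expression, md$sample_id[md$group == "group1"])
  s2 <- stable_pairs(sim$expression, md$sample_id[md$group == "group2"])
  cmp <- compare_stable_pairs(s1, s2)

  # brute-force scan of every common pair against the noiseless templates
  r1 <- sim$truth$template_rank_group1
  r2 <- sim$truth$template_rank_group2
  expected_rev <- sum((r1[cmp$gene_a] - r1[cmp$gene_b]) *
                      (r2[cmp$gene_a] - r2[cmp$gene_b]) < 0)
  expect_equal(attr(cmp, "k_reversal"), expected_rev)
  expect_equal(attr(cmp, "reversal_ratio"), expected_rev / attr(cmp, "m"))
})
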