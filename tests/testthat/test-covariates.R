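test_that("identical ages yield p = 1 everywhere and no flags", {
  m <- random_expr_matrix(10, 16, seed = 4)
  ages <- stats::setNames(rep(50, 16), colnames(m))
  res <- age_association(m, ages, min_group = 3)
  expect_true(all(res$p_value == 1))
  expect_false(any(res$flagged))
})

test_that("complete age separation gives the exact Mann-Whitney tail probability", {
  # one pair whose ordering is determined by age > 50: 15 vs 15 samples,
  # disjoint age ranges. Closed form for complete separation: 2 / C(30, 15).
  S <- 30
  ages <- stats::setNames(c(seq(30, 44, length.out = 15),
                            seq(56, 70, length.out = 15)), sprintf("s%03d", 1:S))
  old <- ages > 50
  m <- matrix(rlnorm(2 * S), 2, S, dimnames = list(c("gA", "gB"), names(ages)))
  m["gA", ] <- ifelse(old, 10, 1)
  m["gB", ] <- 5
  res <- age_association(m, ages, min_group = 5)
  row <- res[res$gene_a == "gA" & res$gene_b == "gB", ]
  expect_equal(row$n_gt, 15L)
  expect_equal(row$n_lt, 15L)
  expect_equal(row$p_value, 2 / choose(30, 15), tolerance = 1e-12)
})

test_that("exact small-sample Mann-Whitney p agrees with full permutation enumeration", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      ages <- stats::setNames(sample(20:80, 13), sprintf("s%03d", 1:13))
      side <- c(rep(TRUE, 7), rep(FALSE, 6))
      m <- matrix(0, 2, 13, dimnames = list(c("gA", "gB"), names(ages)))
      m["gA", ] <- ifelse(side, 2, 1)
      m["gB", ] <- 1.5
      res <- age_association(m, ages, min_group = 3)
      expect_equal(res$p_value[1], enum_mwu_two_sided(ages[side], ages[!side]),
                   tolerance = 1e-10)
    }
  })
})

test_that("age association is invariant to monotone expression and affine age transforms", {
  sim <- simulate_reo_data(reo_generator_config(
    n_genes = 12, samples_per_group = c(10, 10), n_deg = 0, seed = 6
  ))
  ages <- stats::setNames(sim$metadata$age, sim$metadata$sample_id)
  m <- as.matrix(tibble::column_to_rownames(as.data.frame(sim$expression), "gene_id"))
  base <- age_association(m, ages, min_group = 4)
  expect_identical(tidy(age_association(log(m), ages, min_group = 4)), tidy(base))
  expect_identical(tidy(age_association(m, 2 * ages + 3, min_group = 4)), tidy(base))
})

test_that("pairs with a thin side are skipped and excluded from the multiplicity", {
  m <- rbind(gA = c(10, 9, 8, 7, 6, 5, 4, 3, 2, 0.1),
             gB = rep(1, 10),
             gC = rep(0.5, 10))
  colnames(m) <- sprintf("s%03d", 1:10)
  ages <- stats::setNames(30:39, colnames(m))
  # gA vs gB: 9 above / 1 below -> skipped at min_group = 2? no: 1 < 2 -> skipped
  res <- age_association(m, ages, min_group = 2)
  expect_false(any(res$gene_a == "gA" & res$gene_b == "gB"))
  expect_equal(attr(res, "n_pairs_total"), 3)
  expect_lt(attr(res, "n_pairs_tested"), 3)
})

test_that("null ages produce no pair at FDR < 0.2", {
  sim <- simulate_reo_data(reo_scenarios()$age_null)
  ages <- stats::setNames(sim$metadata$age, sim$metadata$sample_id)
  res <- age_association(sim$expression, ages, alpha = 0.2, min_group = 5)
  expect_gt(attr(res, "n_pairs_tested"), 0)
  expect_equal(sum(res$fdr < 0.2), 0)
})

test_that("balance tests reproduce the published cohort p-values", {
  md_counts <- function(n11, n12, n21, n22, f1, l1, f2, l2) {
    tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n11 + n12 + n21 + n22)),
      group = "all", age = NA_real_,
      !!f1 := c(rep(l1[1], n11 + n12), rep(l1[2], n21 + n22)),
      !!f2 := c(rep(l2[1], n11), rep(l2[2], n12), rep(l2[1], n21), rep(l2[2], n22))
    )
  }
  md <- md_counts(31, 18, 33, 11, "smoking", c("smoker", "nonsmoker"),
                  "sex", c("male", "female"))
  res <- balance_test(md, "smoking", "sex")
  expect_equal(sprintf("%.3f", res$fisher_p), "0.266")

  md2 <- md_counts(14, 35, 20, 24, "smoking", c("smoker", "nonsmoker"),
                   "race", c("white", "black"))
  expect_equal(sprintf("%.3f", balance_test(md2, "smoking", "race")$fisher_p), "0.131")

  md3 <- md_counts(25, 9, 39, 20, "sex", c("male", "female"),
                   "race", c("white", "black"))
  expect_equal(sprintf("%.3f", balance_test(md3, "sex", "race")$fisher_p), "0.495")

  # transpose symmetry
  expect_equal(balance_test(md, "sex", "smoking")$fisher_p,
               balance_test(md, "smoking", "sex")$fisher_p)

  # perfectly balanced table
  md4 <- md_counts(10, 10, 10, 10, "smoking", c("smoker", "nonsmoker"),
                   "sex", c("male", "female"))
  expect_equal(balance_test(md4, "smoking", "sex")$fisher_p, 1.0)
})

test_that("balance test drops unknowns and demands binary factors", {
  md <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:6), group = "g",
    smoking = c("smoker", "smoker", "nonsmoker", "nonsmoker", "unknown", "smoker"),
    sex = c("male", "female", "male", "female", "male", "unknown"),
    race = "white", age = NA_real_
  )
  res <- balance_test(md, "smoking", "sex")
  expect_equal(res$n11 + res$n12 + res$n21 + res$n22, 4L)  # unknowns dropped
  expect_error(balance_test(md, "smoking", "race"), "1 observed level")
})
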