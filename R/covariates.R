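# Confounder handling: per-pair age association via the Mann-Whitney U test
# and Fisher-exact balance checks of categorical factors.

# Mann-Whitney two-sided p for two age vectors. Exact when both sides are
# small (<= exact_max) and there are no ties; otherwise normal approximation
# with tie and continuity correction. Degenerate comparisons (zero rank
# variance, i.e. all values equal) carry no evidence: p = 1.
mwu_test <- function(x, y, exact_max = 25) {
  r <- rank(c(x, y))
  if (max(r) == min(r)) {
    return(list(u = length(x) * length(y) / 2, p = 1))
  }
  ties <- any(duplicated(c(x, y)))
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact, correct = TRUE)
  )
  p <- ht$p.value
  if (is.na(p)) p <- 1
  list(u = unname(ht$statistic), p = min(p, 1))
}

#' Per-pair association between REO direction and age
#'
#' For each canonical gene pair, samples with known age are partitioned by
#' their within-sample ordering of the pair (ties excluded); the two sides'
#' age distributions are then compared with a two-sided Mann-Whitney U test.
#' Pairs where either side has fewer than `min_group` samples are skipped and
#' excluded from the BH multiplicity. A pair whose adjusted p falls below
#' `alpha` is flagged as age-associated.
#'
#' @param expr expression table or matrix
#' @param ages per-sample ages: a named numeric vector (names = sample ids)
#'   or a data frame with `sample_id` and `age` columns; samples with unknown
#'   (NA) age are dropped for this analysis only
#' @param alpha FDR threshold for flagging, default 0.05
#' @param min_group minimum per-side sample count, default 5
#' @param exact_max largest per-side size at which the exact Mann-Whitney
#'   distribution is used (given no ties), default 25
#' @return a `reo_age_assoc` tibble of tested pairs: `gene_a`, `gene_b`,
#'   `n_gt`, `n_lt` (side sizes), `u_statistic`, `p_value`, `fdr`, `flagged`
#' @export
age_association <- function(expr, ages, alpha = 0.05, min_group = 5,
                            exact_max = 25) {
  m <- as_expr_matrix(expr)
  if (is.data.frame(ages)) {
    if (!all(c("sample_id", "age") %in% names(ages))) {
      abort("ages data frame needs sample_id and age columns")
    }
    ages <- stats::setNames(as.numeric(ages$age), ages$sample_id)
  }
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0) abort("no sample has a known age")
  known <- intersect(colnames(m), names(ages))
  if (length(known) < 2 * min_group) {
    abort(sprintf("need at least %d samples with known age, have %d",
                  2 * min_group, length(known)))
  }
  m <- m[order(rownames(m)), known, drop = FALSE]
  if (nrow(m) < 2) abort("need at least 2 genes")
  age_vec <- ages[known]

  idx <- pair_indices(nrow(m))
  genes <- rownames(m)
  rows <- vector("list", length(idx$i))
  kept <- 0L
  for (p in seq_along(idx$i)) {
    a <- m[idx$i[p], ]
    b <- m[idx$j[p], ]
    gt <- a > b
    lt <- a < b
    if (sum(gt) < min_group || sum(lt) < min_group) next
    ht <- mwu_test(age_vec[gt], age_vec[lt], exact_max = exact_max)
    kept <- kept + 1L
    rows[[kept]] <- tibble(
      gene_a = genes[idx$i[p]], gene_b = genes[idx$j[p]],
      n_gt = sum(gt), n_lt = sum(lt),
      u_statistic = ht$u, p_value = ht$p
    )
  }
  out <- if (kept) dplyr::bind_rows(rows[seq_len(kept)]) else tibble(
    gene_a = character(), gene_b = character(), n_gt = integer(),
    n_lt = integer(), u_statistic = numeric(), p_value = numeric()
  )
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$flagged <- out$fdr < alpha
  new_reopair_tbl(out, "reo_age_assoc",
    alpha = alpha, min_group = min_group,
    n_samples = length(known),
    n_pairs_total = length(idx$i), n_pairs_tested = kept
  )
}

#' Fisher-exact balance test between two binary factors
#'
#' Checks whether a second confounding factor is distributed differently
#' between the two groups defined by a split factor — e.g. whether sex is
#' balanced between smokers and nonsmokers. Samples with `"unknown"` in
#' either factor are dropped; both factors must then have exactly two
#' observed levels.
#'
#' @param metadata sample metadata tibble (see [read_metadata()])
#' @param split_factor,test_factor column names of the two factors
#' @return a one-row `reo_balance` tibble: the factor names and levels, the
#'   four cell counts `n11`, `n12`, `n21`, `n22` (split levels as rows, test
#'   levels as columns, levels sorted), and `fisher_p`; the `table` attribute
#'   holds the labelled 2x2 matrix
#' @examples
#' md <- tibble::tibble(
#'   sample_id = paste0("s", 1:8),
#'   group = "g", race = "unknown", age = NA_real_,
#'   smoking = rep(c("smoker", "nonsmoker"), each = 4),
#'   sex = c("male", "male", "female", "male", "female", "male", "female", "female")
#' )
#' balance_test(md, "smoking", "sex")
#' @export
balance_test <- function(metadata, split_factor, test_factor) {
  for (f in c(split_factor, test_factor)) {
    if (!f %in% names(metadata)) abort(paste0("metadata has no column ", f))
  }
  s <- as.character(metadata[[split_factor]])
  t_ <- as.character(metadata[[test_factor]])
  ok <- !is.na(s) & !is.na(t_) & s != "unknown" & t_ != "unknown"
  s <- s[ok]; t_ <- t_[ok]
  s_lev <- sort(unique(s)); t_lev <- sort(unique(t_))
  if (length(s_lev) != 2) {
    abort(sprintf("split factor %s has %d observed level(s), need 2",
                  split_factor, length(s_lev)))
  }
  if (length(t_lev) != 2) {
    abort(sprintf("test factor %s has %d observed level(s), need 2",
                  test_factor, length(t_lev)))
  }
  tab <- table(factor(s, s_lev), factor(t_, t_lev))
  p <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  out <- tibble(
    split_factor = split_factor, test_factor = test_factor,
    split_levels = paste(s_lev, collapse = "/"),
    test_levels = paste(t_lev, collapse = "/"),
    n11 = tab[1, 1], n12 = tab[1, 2], n21 = tab[2, 1], n22 = tab[2, 2],
    fisher_p = p
  )
  new_reopair_tbl(out, "reo_balance", table = unclass(tab))
}
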