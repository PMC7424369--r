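# Hypergeometric over-representation analysis of DEG lists in gene sets.

#' Hypergeometric gene-set enrichment
#'
#' Tests each gene set for over-representation of a query gene list within a
#' stated universe. With `N` universe genes of which `K` belong to the set
#' and a query of `q` genes overlapping the set in `x`, the p-value is the
#' upper tail P(X >= x) of the hypergeometric distribution. BH correction is
#' applied across all tested sets. Up- and downregulated DEG lists should be
#' tested in separate calls.
#'
#' @param query character vector of query gene ids (e.g. upregulated DEGs);
#'   genes outside the universe are dropped with a warning
#' @param collection named list of gene sets (see [read_gmt()])
#' @param universe character vector of background gene ids; enrichment
#'   p-values depend strongly on this choice, so it is always explicit —
#'   typically all genes present in the expression matrix after collapsing
#' @param alpha FDR threshold for flagging, default 0.05
#' @param min_set_size sets smaller than this after intersection with the
#'   universe are skipped and excluded from the BH multiplicity, default 2
#' @return a `reo_enrichment` tibble sorted by p-value (ties by set name):
#'   `set_name`, `set_size` (K), `universe_size` (N), `query_size` (q),
#'   `overlap` (x), `p_value`, `fdr`, `flagged`
#' @export
hypergeom_enrich <- function(query, collection, universe, alpha = 0.05,
                             min_set_size = 2) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("universe is empty")
  query <- unique(as.character(query))
  if (length(query) == 0) abort("query gene list is empty")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    query <- setdiff(query, outside)
    if (length(query) == 0) abort("no query gene lies in the universe")
  }
  N <- length(universe)
  q <- length(query)
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  keep <- lengths(sets) >= min_set_size
  sets <- sets[keep]
  if (length(sets) == 0) {
    return(new_reopair_tbl(
      tibble(set_name = character(), set_size = integer(),
             universe_size = integer(), query_size = integer(),
             overlap = integer(), p_value = numeric(), fdr = numeric(),
             flagged = logical()),
      "reo_enrichment", alpha = alpha
    ))
  }
  K <- lengths(sets)
  x <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  p <- phyper(x - 1, K, N - K, q, lower.tail = FALSE)
  out <- tibble(
    set_name = names(sets), set_size = unname(K),
    universe_size = N, query_size = q, overlap = unname(x),
    p_value = unname(p), fdr = p.adjust(unname(p), method = "BH")
  )
  out$flagged <- out$fdr < alpha
  out <- arrange(out, .data$p_value, .data$set_name)
  new_reopair_tbl(out, "reo_enrichment", alpha = alpha)
}
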