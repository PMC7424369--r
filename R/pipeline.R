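# End-to-end orchestration: balance tests -> per-group stable pairs ->
# comparison -> RankCompV2 -> enrichment -> chromosome tally, with every
# stage's result collected in a manifest. Orchestrated results are identical
# to standalone stage calls on the same inputs: there is no hidden state.

#' Tally DEGs by chromosome class and direction
#'
#' Classifies each gene as X, Y or autosomal from its cytoband and
#' cross-tabulates against the supplied direction labels. Used to ask
#' whether sex-biased genes concentrate on the sex chromosomes.
#'
#' @param degs data frame with columns `gene_id` and `direction`
#' @param cytobands data frame with columns `gene_id`, `cytoband`; every DEG
#'   must be annotated
#' @return a `reo_tally` tibble with one row per direction x chromosome
#'   class (`"X"`, `"Y"`, `"autosome"`) and an `n` count column; attribute
#'   `totals` holds the overall class counts
#' @export
tally_chromosomes <- function(degs, cytobands) {
  if (!all(c("gene_id", "direction") %in% names(degs))) {
    abort("degs needs gene_id and direction columns")
  }
  unannotated <- setdiff(degs$gene_id, cytobands$gene_id)
  if (length(unannotated)) {
    abort(paste0("unannotated gene(s): ", paste(unannotated, collapse = ", ")))
  }
  joined <- left_join(as_tibble(degs[, c("gene_id", "direction")]),
                      as_tibble(cytobands[, c("gene_id", "cytoband")]),
                      by = "gene_id")
  chrom <- chromosome_of(joined$cytoband)
  joined$chromosome_class <- ifelse(chrom %in% c("X", "Y"), chrom, "autosome")
  out <- joined |>
    count(.data$direction, .data$chromosome_class, name = "n") |>
    arrange(.data$direction, .data$chromosome_class)
  totals <- joined |> count(.data$chromosome_class, name = "n")
  new_reopair_tbl(out, "reo_tally",
    totals = totals,
    n_sex_chromosomal = sum(chrom %in% c("X", "Y")),
    n_autosomal = sum(!chrom %in% c("X", "Y"))
  )
}

#' Run the full REO confounder pipeline for one binary factor
#'
#' Executes, in order: balance tests of the other categorical confounders
#' between the two groups, per-group stable-pair detection, concordant/
#' reversal comparison with the reversal ratio, RankCompV2 DEG calling,
#' optional hypergeometric enrichment of the up- and downregulated DEG lists,
#' and an optional chromosome tally of the flagged genes.
#'
#' @param expr expression table or matrix
#' @param metadata sample metadata (see [read_metadata()])
#' @param split_factor metadata column defining the two groups (e.g.
#'   `"smoking"`); only samples with the two chosen levels are analysed
#' @param group1,group2 the two factor levels to compare; defaults to the
#'   sorted observed levels
#' @param gene_sets optional named list of gene sets for enrichment
#' @param cytobands optional cytoband annotation for the DEG tally
#' @param stable_alpha,deg_alpha,enrich_alpha FDR thresholds for stable-pair
#'   detection, DEG calling and enrichment
#' @param max_iter RankCompV2 iteration cap
#' @param gene_cap optional maximum gene count; when set, the `gene_cap`
#'   highest-variance genes (ties broken by gene id) are kept so the pair
#'   space stays desk-sized
#' @param block_size pair block size for the stable-pair stage
#' @return a `reo_manifest` list with elements `balance`, `stable_group1`,
#'   `stable_group2`, `comparison`, `deg`, `enrichment_up`,
#'   `enrichment_down`, `tally` (stages not run are NULL), plus `summary`
#'   (one-row tibble of headline numbers) and `config` (the echoed call
#'   parameters)
#' @export
run_reo_pipeline <- function(expr, metadata, split_factor,
                             group1 = NULL, group2 = NULL,
                             gene_sets = NULL, cytobands = NULL,
                             stable_alpha = 0.05, deg_alpha = 0.05,
                             enrich_alpha = 0.05, max_iter = 10,
                             gene_cap = NULL, block_size = 1e6) {
  if (!split_factor %in% names(metadata)) {
    abort(paste0("metadata has no column ", split_factor))
  }
  fac <- as.character(metadata[[split_factor]])
  levels_obs <- sort(setdiff(unique(fac), c(NA, "unknown")))
  group1 <- group1 %||% levels_obs[1]
  group2 <- group2 %||% levels_obs[2]
  if (is.na(group1) || is.na(group2)) abort("split factor needs two observed levels")
  g1_samples <- metadata$sample_id[fac == group1 & !is.na(fac)]
  g2_samples <- metadata$sample_id[fac == group2 & !is.na(fac)]
  m <- as_expr_matrix(expr)
  g1_samples <- intersect(g1_samples, colnames(m))
  g2_samples <- intersect(g2_samples, colnames(m))
  if (length(g1_samples) < 2 || length(g2_samples) < 2) {
    abort("each group needs at least 2 samples present in the expression matrix")
  }

  if (!is.null(gene_cap) && gene_cap < nrow(m)) {
    v <- apply(m[, c(g1_samples, g2_samples), drop = FALSE], 1, var)
    keep <- rownames(m)[order(-v, rownames(m))][seq_len(gene_cap)]
    m <- m[rownames(m) %in% keep, , drop = FALSE]
  }

  # Balance of the remaining categorical confounders between the two groups.
  md_sub <- metadata[metadata$sample_id %in% c(g1_samples, g2_samples), ]
  md_sub$.split <- ifelse(md_sub$sample_id %in% g1_samples, group1, group2)
  balance <- list()
  for (f in setdiff(intersect(c("sex", "race", "smoking"), names(metadata)),
                    split_factor)) {
    res <- tryCatch(balance_test(md_sub, ".split", f), error = function(e) NULL)
    if (!is.null(res)) {
      res$split_factor <- split_factor
      balance[[f]] <- res
    }
  }
  balance <- if (length(balance)) dplyr::bind_rows(balance) else NULL

  set1 <- stable_pairs(m, g1_samples, alpha = stable_alpha,
                       block_size = block_size, group = group1)
  set2 <- stable_pairs(m, g2_samples, alpha = stable_alpha,
                       block_size = block_size, group = group2)
  comparison <- compare_stable_pairs(set1, set2)
  deg <- rankcomp_v2(m, g1_samples, g2_samples, alpha = deg_alpha,
                     stable_alpha = stable_alpha, max_iter = max_iter,
                     stable_sets = list(set1, set2))

  enrichment_up <- enrichment_down <- NULL
  if (!is.null(gene_sets)) {
    universe <- rownames(m)
    up <- deg$gene_id[deg$direction == "up_in_group2"]
    down <- deg$gene_id[deg$direction == "down_in_group2"]
    if (length(up)) {
      enrichment_up <- hypergeom_enrich(up, gene_sets, universe, alpha = enrich_alpha)
    }
    if (length(down)) {
      enrichment_down <- hypergeom_enrich(down, gene_sets, universe, alpha = enrich_alpha)
    }
  }

  tally <- NULL
  flagged <- deg[deg$flagged, c("gene_id", "direction")]
  if (!is.null(cytobands) && nrow(flagged)) {
    tally <- tally_chromosomes(flagged, cytobands)
  }

  summary <- tibble(
    split_factor = split_factor, group1 = group1, group2 = group2,
    n_group1 = length(g1_samples), n_group2 = length(g2_samples),
    n_genes = nrow(m),
    stable_group1 = nrow(set1), stable_group2 = nrow(set2),
    m_common = attr(comparison, "m"),
    k_reversal = attr(comparison, "k_reversal"),
    reversal_ratio = attr(comparison, "reversal_ratio"),
    n_deg = sum(deg$flagged),
    n_deg_up = sum(deg$direction == "up_in_group2"),
    n_deg_down = sum(deg$direction == "down_in_group2"),
    rankcomp_converged = attr(deg, "converged")
  )

  structure(
    list(
      balance = balance,
      stable_group1 = set1, stable_group2 = set2,
      comparison = comparison, deg = deg,
      enrichment_up = enrichment_up, enrichment_down = enrichment_down,
      tally = tally, summary = summary,
      config = list(
        split_factor = split_factor, group1 = group1, group2 = group2,
        stable_alpha = stable_alpha, deg_alpha = deg_alpha,
        enrich_alpha = enrich_alpha, max_iter = max_iter,
        gene_cap = gene_cap,
        version = as.character(utils::packageVersion("reopair"))
      )
    ),
    class = "reo_manifest"
  )
}

#' Write every stage of a pipeline manifest to TSV files
#'
#' @param manifest a `reo_manifest` from [run_reo_pipeline()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_manifest <- function(manifest, dir) {
  stopifnot(inherits(manifest, "reo_manifest"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dump <- function(x, name) {
    if (!is.null(x) && nrow(x)) {
      readr::write_tsv(as_tibble(x), file.path(dir, paste0(name, ".tsv")),
                       progress = FALSE)
    }
  }
  dump(manifest$balance, "balance")
  dump(manifest$stable_group1, "stable_pairs_group1")
  dump(manifest$stable_group2, "stable_pairs_group2")
  dump(manifest$comparison, "pair_comparison")
  dump(manifest$deg, "deg_table")
  dump(manifest$enrichment_up, "enrichment_up")
  dump(manifest$enrichment_down, "enrichment_down")
  dump(manifest$tally, "chromosome_tally")
  dump(manifest$summary, "summary")
  yaml::write_yaml(manifest$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.reo_manifest <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("REO pipeline [%s: %s vs %s]\n",
           "  samples: %d / %d, genes: %d\n",
           "  stable pairs: %d / %d, common m = %d, reversal k = %d (ratio %s)\n",
           "  DEGs: %d (%d up, %d down in %s)\n"),
    s$split_factor, s$group1, s$group2, s$n_group1, s$n_group2, s$n_genes,
    s$stable_group1, s$stable_group2, s$m_common, s$k_reversal,
    if (is.na(s$reversal_ratio)) "undefined" else format(s$reversal_ratio, digits = 4),
    s$n_deg, s$n_deg_up, s$n_deg_down, s$group2
  ))
  invisible(x)
}
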