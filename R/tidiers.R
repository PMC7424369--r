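# broom-style tidiers: tidy() returns the per-record table as a plain
# tibble, glance() a one-row summary of the fit/comparison.

strip_reopair_class <- function(x) {
  cls <- class(x)
  class(x) <- cls[!startsWith(cls, "reo_")]
  for (a in c("genes", "n_pairs_total", "n_samples", "alpha", "p0", "group",
              "m", "k_reversal", "reversal_ratio", "groups", "table",
              "iterations_run", "converged", "stable_alpha", "min_group",
              "n_pairs_tested", "totals", "n_sex_chromosomal", "n_autosomal")) {
    attr(x, a) <- NULL
  }
  as_tibble(x)
}

#' @export
tidy.reo_stable_pairs <- function(x, ...) strip_reopair_class(x)

#' @export
tidy.reo_comparison <- function(x, ...) strip_reopair_class(x)

#' @export
tidy.reo_deg <- function(x, ...) strip_reopair_class(x)

#' @export
tidy.reo_age_assoc <- function(x, ...) strip_reopair_class(x)

#' @export
tidy.reo_balance <- function(x, ...) strip_reopair_class(x)

#' @export
tidy.reo_enrichment <- function(x, ...) strip_reopair_class(x)

#' @export
tidy.reo_tally <- function(x, ...) strip_reopair_class(x)

#' @export
glance.reo_stable_pairs <- function(x, ...) {
  tibble(
    group = attr(x, "group"),
    n_genes = length(attr(x, "genes")),
    n_samples = attr(x, "n_samples"),
    n_pairs_total = attr(x, "n_pairs_total"),
    n_stable = nrow(x),
    alpha = attr(x, "alpha")
  )
}

#' @export
glance.reo_comparison <- function(x, ...) {
  tibble(
    group1 = attr(x, "groups")[1], group2 = attr(x, "groups")[2],
    m = attr(x, "m"),
    k_reversal = attr(x, "k_reversal"),
    concordant = attr(x, "m") - attr(x, "k_reversal"),
    reversal_ratio = attr(x, "reversal_ratio")
  )
}

#' @export
glance.reo_deg <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_flagged = sum(x$flagged),
    n_up = sum(x$direction == "up_in_group2"),
    n_down = sum(x$direction == "down_in_group2"),
    iterations_run = attr(x, "iterations_run"),
    converged = attr(x, "converged"),
    alpha = attr(x, "alpha"),
    stable_alpha = attr(x, "stable_alpha"),
    m_common_pairs = attr(x, "m"),
    reversal_ratio = attr(x, "reversal_ratio")
  )
}

#' @export
glance.reo_age_assoc <- function(x, ...) {
  tibble(
    n_pairs_total = attr(x, "n_pairs_total"),
    n_pairs_tested = attr(x, "n_pairs_tested"),
    n_flagged = sum(x$flagged),
    n_samples = attr(x, "n_samples"),
    alpha = attr(x, "alpha"),
    min_group = attr(x, "min_group")
  )
}

#' @export
glance.reo_enrichment <- function(x, ...) {
  tibble(
    n_sets_tested = nrow(x),
    n_flagged = sum(x$flagged),
    alpha = attr(x, "alpha")
  )
}

#' @export
glance.reo_manifest <- function(x, ...) x$summary
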