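# ggplot2 visualisations of each result type.

#' @export
autoplot.reo_stable_pairs <- function(object, ...) {
  df <- tidy(object)
  df$consistency <- df$k / df$n
  ggplot2::ggplot(df, ggplot2::aes(x = .data$consistency)) +
    ggplot2::geom_histogram(binwidth = 0.02, boundary = 1,
                            fill = "grey35", colour = "white") +
    ggplot2::labs(
      x = "REO consistency k / n",
      y = "stable pairs",
      title = sprintf("Stable pair consistency (%d pairs, FDR < %g)",
                      nrow(df), attr(object, "alpha"))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.reo_comparison <- function(object, ...) {
  g <- glance(object)
  df <- tibble(
    status = c("concordant", "reversal"),
    n = c(g$concordant, g$k_reversal)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$n, fill = .data$status)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(concordant = "grey60", reversal = "firebrick")) +
    ggplot2::labs(
      x = NULL, y = "common stable pairs",
      title = sprintf("Reversal ratio %.4g (k = %d of m = %d)",
                      g$reversal_ratio, g$k_reversal, g$m)
    ) +
    ggplot2::theme_minimal()
}

#' Disruption plot: each gene's greater-than fraction in the two groups
#'
#' Genes on the diagonal keep the same ordering profile against their stable
#' partners in both groups; flagged DEGs sit off the diagonal (above: up in
#' group 2; below: down in group 2).
#'
#' @param object a `reo_deg` table
#' @param ... unused
#' @export
autoplot.reo_deg <- function(object, ...) {
  df <- tidy(object)
  df$p1 <- df$g1_gt / (df$g1_gt + df$g1_lt)
  df$p2 <- df$g2_gt / (df$g2_gt + df$g2_lt)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p1, y = .data$p2,
                                   colour = .data$direction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      none = "grey50", up_in_group2 = "firebrick", down_in_group2 = "steelblue"
    )) +
    ggplot2::labs(
      x = "fraction of partners below gene (group 1)",
      y = "fraction of partners below gene (group 2)",
      colour = NULL,
      title = sprintf("RankCompV2 disruption (%d DEGs of %d genes)",
                      sum(df$flagged), nrow(df))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.reo_enrichment <- function(object, ...) {
  df <- tidy(object)
  df$set_name <- factor(df$set_name, levels = rev(df$set_name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value), y = .data$set_name,
                                   size = .data$overlap, colour = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey55")) +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL,
                  colour = sprintf("FDR < %g", attr(object, "alpha")),
                  size = "overlap") +
    ggplot2::theme_minimal()
}
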