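# Internal helpers shared across modules.

#' Coerce an expression table to a numeric gene-by-sample matrix
#'
#' Accepts either a tibble/data.frame whose first column holds gene
#' identifiers (the remaining columns being numeric sample columns), or a
#' numeric matrix with gene identifiers as row names. Validates the
#' expression-matrix invariants: unique gene and sample identifiers and
#' all-finite values.
#'
#' @param x expression data (data frame with a gene-id first column, or a
#'   named numeric matrix)
#' @return numeric matrix, genes in rows (rownames), samples in columns
#' @keywords internal
#' @noRd
as_expr_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("expression matrix must have gene row names and sample column names")
    }
    m <- x
    storage.mode(m) <- "double"
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2) abort("expression table needs a gene-id column plus at least one sample column")
    genes <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(x[-1], is.numeric, logical(1)))[1]
      abort(paste0("non-numeric expression column: ", names(x)[-1][bad]))
    }
    rownames(m) <- genes
  } else {
    abort("expression input must be a data frame or a named numeric matrix")
  }
  dup_g <- rownames(m)[duplicated(rownames(m))]
  if (length(dup_g)) abort(paste0("duplicate gene id: ", dup_g[1]))
  dup_s <- colnames(m)[duplicated(colnames(m))]
  if (length(dup_s)) abort(paste0("duplicate sample id: ", dup_s[1]))
  if (anyNA(m) || any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(paste0(
      "non-finite expression value at gene ", rownames(m)[idx[1]],
      ", sample ", colnames(m)[idx[2]]
    ))
  }
  m
}

# Matrix -> tidy expression tibble (gene_id first column).
expr_as_tibble <- function(m) {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble(gene_id = rownames(m)), out)
}

# Subset columns of an expression matrix by sample ids, erroring on unknowns.
subset_samples <- function(m, samples) {
  if (is.null(samples)) return(m)
  missing <- setdiff(samples, colnames(m))
  if (length(missing)) abort(paste0("sample not in expression matrix: ", missing[1]))
  m[, samples, drop = FALSE]
}

# Canonical pair index table for G genes in lexicographic id order:
# all i < j pairs enumerated row-major (i ascending, then j).
pair_indices <- function(G) {
  i <- rep.int(seq_len(G - 1L), times = (G - 1L):1L)
  j <- sequence((G - 1L):1L) + i
  list(i = i, j = j)
}

new_reopair_tbl <- function(x, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c(class, class(x))
  x
}
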