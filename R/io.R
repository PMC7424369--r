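# Readers and writers for the plain-text formats the pipeline touches:
# expression TSV, sample-metadata TSV, GMT gene sets, cytoband annotation.

#' Read a gene-by-sample expression matrix from TSV
#'
#' The file must have a header row of sample identifiers, gene identifiers in
#' the first column, and numeric values elsewhere. Duplicate gene or sample
#' identifiers and non-numeric or missing cells are load errors: relative
#' expression orderings are defined within complete samples, so silent
#' imputation is never appropriate.
#'
#' @param path path to a tab-separated expression file
#' @return a tibble with a `gene_id` character column followed by one numeric
#'   column per sample, in file order
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_expression(tibble::tibble(gene_id = c("gA", "gB"), s1 = c(2, 1), s2 = c(3, 5)), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]][-1]
  if (anyDuplicated(header)) {
    abort(paste0("duplicate sample id: ", header[duplicated(header)][1]))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         na = character(), show_col_types = FALSE)
  if (ncol(raw) < 2) abort("expression file needs a gene column and at least one sample column")
  names(raw)[1] <- "gene_id"
  raw$gene_id <- as.character(raw$gene_id)
  for (col in names(raw)[-1]) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num)) {
        row <- which(is.na(num))[1]
        abort(paste0("non-numeric expression value at row ", row, " (gene ",
                     raw$gene_id[row], "), column ", col))
      }
      raw[[col]] <- num
    }
  }
  as_expr_matrix(raw)  # invariant check (duplicates, finiteness)
  as_tibble(raw)
}

#' Write an expression matrix to TSV
#'
#' @param expr expression table or matrix (see [read_expression()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_expression <- function(expr, path) {
  m <- as_expr_matrix(expr)
  readr::write_tsv(expr_as_tibble(m), path, progress = FALSE)
  invisible(path)
}

.known_sex <- c("male", "female")
.known_smoking <- c("smoker", "nonsmoker")

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `group`, `sex`, `race`, `smoking`, `age`
#' (extra columns pass through). Empty or unrecognised categorical values are
#' mapped to the explicit level `"unknown"`; unparseable or negative ages
#' become `NA`. Nothing is dropped at load time — filtering on missingness is
#' the job of each analysis stage.
#'
#' @param path path to a tab-separated metadata file
#' @return tibble of per-sample metadata
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  md <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  need <- c("sample_id", "group", "sex", "race", "smoking", "age")
  missing <- setdiff(need, names(md))
  if (length(missing)) abort(paste0("metadata missing column(s): ", paste(missing, collapse = ", ")))
  if (anyDuplicated(md$sample_id)) {
    abort(paste0("duplicate sample_id: ", md$sample_id[duplicated(md$sample_id)][1]))
  }
  norm_cat <- function(x, known = NULL) {
    x <- tolower(trimws(x))
    x[is.na(x) | x == "" | x == "na"] <- "unknown"
    if (!is.null(known)) x[!x %in% c(known, "unknown")] <- "unknown"
    x
  }
  md$group <- {g <- trimws(md$group); g[is.na(g) | g == ""] <- "unknown"; g}
  md$sex <- norm_cat(md$sex, .known_sex)
  md$smoking <- norm_cat(md$smoking, .known_smoking)
  md$race <- norm_cat(md$race)
  suppressWarnings(age <- as.numeric(md$age))
  age[!is.na(age) & age < 0] <- NA_real_
  md$age <- age
  md
}

#' Write sample metadata to TSV
#' @param metadata metadata tibble (see [read_metadata()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member genes. Lines with fewer than three fields are format errors.
#'
#' @param path path to a `.gmt` file
#' @return named list of character vectors (unique member gene ids); the
#'   `description` attribute carries the per-set description strings
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) abort(paste0("malformed GMT line ", bad[1], ": fewer than 3 fields"))
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) abort(paste0("duplicate gene-set name: ", nms[duplicated(nms)][1]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  if (any(lengths(sets) == 0L)) abort("empty gene set in GMT file")
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, character(1), 2L), nms)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors
#' @param path output path
#' @param description optional named character vector of set descriptions
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, description = NULL) {
  description <- description %||% attr(sets, "description") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene cytoband annotation from a two-column TSV
#'
#' @param path TSV with columns `gene_id` and `cytoband` (header optional as
#'   long as the two columns are in that order)
#' @return tibble with `gene_id`, `cytoband` columns
#' @export
read_cytobands <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  if (ncol(cb) < 2) abort("cytoband file needs two columns: gene_id, cytoband")
  names(cb)[1:2] <- c("gene_id", "cytoband")
  if (anyDuplicated(cb$gene_id)) {
    abort(paste0("duplicate gene_id in cytoband file: ", cb$gene_id[duplicated(cb$gene_id)][1]))
  }
  chromosome_of(cb$cytoband)  # validate every band parses
  cb[, c("gene_id", "cytoband")]
}

#' Write gene cytoband annotation
#' @param cytobands tibble with `gene_id`, `cytoband` columns
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cytobands <- function(cytobands, path) {
  readr::write_tsv(cytobands[, c("gene_id", "cytoband")], path, progress = FALSE)
  invisible(path)
}

#' Extract the chromosome token from a cytoband string
#'
#' A cytoband such as `"Yq11.221"` or `"16q24.3"` begins with a chromosome
#' token (1-22, X or Y) followed by an arm designator (`p` or `q`, possibly
#' with band coordinates). Parsing stops at the first arm character.
#'
#' @param cytoband character vector of cytoband strings
#' @return character vector of chromosome tokens (`"1"`-`"22"`, `"X"`, `"Y"`)
#' @examples
#' chromosome_of(c("Yq11.221", "Xp22.32", "19q13.42"))
#' @export
chromosome_of <- function(cytoband) {
  if (length(cytoband) == 0) return(character(0))
  token <- sub("^((?:[0-9]{1,2}|[XY]))[pq].*$", "\\1", cytoband)
  valid <- grepl("^((?:[0-9]{1,2}|[XY]))[pq]", cytoband) &
    (token %in% c(as.character(1:22), "X", "Y"))
  if (any(!valid)) {
    abort(paste0("unparseable cytoband: ", cytoband[!valid][1]))
  }
  token
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes mapping to zero or to multiple genes are discarded; when several
#' surviving probes map to the same gene, the gene's per-sample value is the
#' arithmetic mean of those probes' values. Output genes are sorted
#' lexicographically, the canonical gene order used throughout the pipeline.
#'
#' @param expr probe-level expression table or matrix (probe ids in the
#'   gene-id position)
#' @param annotation data frame with columns `probe_id` and `gene_id`; a probe
#'   mapping to several genes appears on several rows
#' @return gene-level expression tibble (`gene_id` + sample columns)
#' @examples
#' probes <- tibble::tibble(
#'   gene_id = c("p1", "p2", "p3", "p4"),
#'   s1 = c(2, 4, 9, 7)
#' )
#' ann <- tibble::tibble(
#'   probe_id = c("p1", "p2", "p3", "p3"),
#'   gene_id = c("gA", "gA", "gA", "gB")
#' )
#' collapse_probes(probes, ann)  # gA = mean(2, 4) = 3; p3, p4 discarded
#' @export
collapse_probes <- function(expr, annotation) {
  m <- as_expr_matrix(expr)
  if (!all(c("probe_id", "gene_id") %in% names(annotation))) {
    abort("annotation needs columns probe_id and gene_id")
  }
  ann <- dplyr::distinct(as_tibble(annotation[, c("probe_id", "gene_id")]))
  n_targets <- table(ann$probe_id)
  unique_probes <- names(n_targets)[n_targets == 1L]
  ann1 <- ann[ann$probe_id %in% unique_probes, ]
  ann1 <- ann1[ann1$probe_id %in% rownames(m), ]
  if (nrow(ann1) == 0) abort("no probe maps uniquely to a gene; nothing to collapse")
  sub <- m[ann1$probe_id, , drop = FALSE]
  collapsed <- rowsum(sub, group = ann1$gene_id)
  n_probes <- table(ann1$gene_id)
  collapsed <- collapsed / as.vector(n_probes[rownames(collapsed)])
  collapsed <- collapsed[order(rownames(collapsed)), , drop = FALSE]
  expr_as_tibble(collapsed)
}
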