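# Readers and writers for the plain-text interchange formats: tab-separated
# count matrix / sample sheet / annotation, GMT gene sets, STRING-dialect edge
# lists, and the DESeq2-style differential-expression table.

#' Read and write a tab-separated count matrix
#'
#' Genes as rows (first column the gene identifier), samples as header columns.
#'
#' @param path File path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = 1, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (any(m < 0) || any(m != round(m))) {
    abort("count matrix must contain non-negative integers")
  }
  storage.mode(m) <- "integer"
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort("duplicate gene or sample identifiers in count matrix")
  }
  m
}

#' @rdname read_count_matrix
#' @param counts Integer matrix, genes x samples.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the sample sheet
#'
#' Tab-separated with columns `sample_id`, `cohort` and optionally `sex`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cohort") %in% names(df))) {
    abort("sample sheet needs columns sample_id, cohort")
  }
  as_tibble(df)
}

#' @rdname read_sample_sheet
#' @param samples Sample-sheet tibble.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write gene annotation
#'
#' Tab-separated with columns `gene` and `protein_coding` (logical).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_annotation <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene", "protein_coding") %in% names(df))) {
    abort("annotation needs columns gene, protein_coding")
  }
  df$protein_coding <- as.logical(df$protein_coding)
  as_tibble(df)
}

#' @rdname read_annotation
#' @param annotation Annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' member genes. Members are deduplicated on read.
#'
#' @param path File path.
#' @return A `gene_set_collection` (named list of gene vectors with a
#'   `description` attribute).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) abort("GMT lines need at least 3 tab-separated fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  desc <- setNames(vapply(parts, `[[`, character(1), 2), names(sets))
  structure(sets, description = desc, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write STRING-dialect edge lists
#'
#' Whitespace-separated with a header line: `protein1 protein2` followed by
#' named evidence-channel scores (integers 0-1000), e.g. `experiments`,
#' `database`, `textmining`.
#'
#' @param path File path.
#' @return Tibble with the header's columns.
#' @export
read_string_edges <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("protein1", "protein2") %in% names(df))) {
    abort("edge list needs columns protein1, protein2")
  }
  as_tibble(df)
}

#' @rdname read_string_edges
#' @param edges Edge tibble.
#' @export
write_string_edges <- function(edges, path) {
  write.table(edges, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a differential-expression table
#'
#' Tab-separated with the de-facto standard header
#' `gene baseMean log2FoldChange lfcSE stat pvalue padj` for interoperability.
#'
#' @param x A `deg_result` from [deg_test()].
#' @param path File path.
#' @export
write_de_table <- function(x, path) {
  tab <- tidy(x)
  out <- data.frame(
    gene = tab$gene,
    baseMean = tab$base_mean,
    log2FoldChange = tab$log2_fc,
    lfcSE = tab$lfc_se,
    stat = tab$stat,
    pvalue = tab$p_value,
    padj = tab$q_value
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
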