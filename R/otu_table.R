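#' Construct an OTU count table
#'
#' The central data container: a samples x taxa matrix of non-negative
#' integer counts with unique sample and taxon identifiers and an optional
#' taxonomy lineage per taxon (semicolon-delimited ranks, e.g.
#' `"Bacteroidetes;Porphyromonadaceae;Porphyromonas"`).
#'
#' @param counts numeric matrix, samples in rows, taxa in columns; entries
#'   must be non-negative integers (integer-valued doubles accepted).
#' @param sample_ids,taxon_ids character vectors of unique identifiers;
#'   default to the matrix dimnames.
#' @param taxonomy optional named character vector mapping taxon id to a
#'   semicolon-delimited lineage.
#' @return an object of class `otu_table`: a list with elements `counts`
#'   (named integer matrix), and `taxonomy` (named character or `NULL`).
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      taxon_ids = colnames(counts), taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(taxon_ids)) {
    stop("sample and taxon identifiers are required", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (nrow(counts) != length(sample_ids) || ncol(counts) != length(taxon_ids)) {
    stop("count matrix dimensions do not match identifier lengths", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(taxon_ids)) {
    stop("duplicate taxon identifiers: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("counts must be non-negative integers (offending cell: sample '%s', taxon '%s')",
                 sample_ids[bad[1]], taxon_ids[bad[2]]), call. = FALSE)
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(sample_ids, taxon_ids)
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[taxon_ids]
    names(taxonomy) <- taxon_ids
    taxonomy[is.na(taxonomy)] <- "unclassified"
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d taxa%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "" else " (with taxonomy)"))
  cat(sprintf("library sizes: %s .. %s\n",
              format(min(library_sizes(x)), big.mark = ","),
              format(max(library_sizes(x)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Sample identifiers of an OTU table
#' @param table an `otu_table`.
#' @return character vector.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' Taxon identifiers of an OTU table
#' @param table an `otu_table`.
#' @return character vector.
#' @export
taxon_ids <- function(table) colnames(table$counts)

#' Per-sample library sizes (row sums)
#' @param table an `otu_table`.
#' @return named numeric vector of total counts per sample.
#' @export
library_sizes <- function(table) rowSums(table$counts)

#' Subset an OTU table by sample and/or taxon identifiers
#' @param table an `otu_table`.
#' @param samples,taxa identifiers (or logical/integer indices) to keep;
#'   `NULL` keeps all.
#' @return an `otu_table`.
#' @export
subset_otu_table <- function(table, samples = NULL, taxa = NULL) {
  counts <- table$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(taxa)) counts <- counts[, taxa, drop = FALSE]
  otu_table(counts, taxonomy = table$taxonomy[colnames(counts)])
}
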