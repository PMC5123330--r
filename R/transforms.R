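# Count-table transforms shared by every downstream stage: rarefaction,
# taxonomic aggregation, prevalence filtering and winsorization.

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's counts without replacement (hypergeometric
#' subsampling) to a common depth, the standard ecological normalisation
#' before distance calculations. Samples whose library size is below the
#' depth are dropped with a warning.
#'
#' @param table an [otu_table].
#' @param depth target depth; defaults to the minimum library size so no
#'   sample is dropped.
#' @param seed integer seed; rarefaction is reproducible for a fixed seed.
#' @return a rarefied [otu_table]; every retained sample sums to `depth`.
#' @export
rarefy_table <- function(table, depth = min(library_sizes(table)), seed) {
  if (!is.numeric(depth) || depth <= 0 || depth != round(depth)) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  ls <- library_sizes(table)
  keep <- ls >= depth
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) below rarefaction depth %d: %s",
                    sum(!keep), depth,
                    paste(names(ls)[!keep], collapse = ", ")), call. = FALSE)
  }
  if (!any(keep)) stop("no sample reaches the rarefaction depth", call. = FALSE)
  counts <- table$counts[keep, , drop = FALSE]
  rare <- with_seed(seed, quiet_rrarefy(counts, depth))
  otu_table(rare, taxonomy = table$taxonomy)
}

#' Aggregate OTU counts to a taxonomic rank
#'
#' Sums counts over OTUs sharing the lineage prefix down to the requested
#' rank. Lineages are semicolon-delimited with ranks ordered
#' phylum; family; genus. OTUs with no assignment at the rank are pooled
#' into an `"unclassified"` bin. Per-sample totals are conserved exactly.
#'
#' @param table an [otu_table] with taxonomy.
#' @param level `"phylum"`, `"family"` or `"genus"`.
#' @return an [otu_table] with one column per distinct lineage prefix.
#' @export
aggregate_taxa <- function(table, level = c("phylum", "family", "genus")) {
  level <- match.arg(level)
  if (is.null(table$taxonomy)) {
    stop("table has no taxonomy; cannot aggregate", call. = FALSE)
  }
  depth <- c(phylum = 1L, family = 2L, genus = 3L)[[level]]
  prefix <- vapply(strsplit(table$taxonomy, ";", fixed = TRUE), function(ranks) {
    ranks <- trimws(ranks)
    ranks <- ranks[ranks != ""]
    if (length(ranks) < depth || ranks[depth] %in% c("unclassified", "NA")) {
      "unclassified"
    } else {
      paste(ranks[seq_len(depth)], collapse = ";")
    }
  }, character(1))
  agg <- t(rowsum(t(table$counts), group = prefix))
  otu_table(agg)
}

#' Filter taxa by prevalence
#'
#' Prevalence is the fraction of samples in which a taxon has a nonzero
#' count. Taxa with prevalence strictly below the threshold are removed;
#' taxa exactly at the threshold are kept.
#'
#' @param table an [otu_table].
#' @param min_prevalence fraction in (0, 1]; default 0.20.
#' @return filtered [otu_table].
#' @export
filter_by_prevalence <- function(table, min_prevalence = 0.20) {
  if (!is.numeric(min_prevalence) || min_prevalence <= 0 || min_prevalence > 1) {
    stop("`min_prevalence` must be in (0, 1]", call. = FALSE)
  }
  prev <- colMeans(table$counts > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) stop("no taxon passes the prevalence filter", call. = FALSE)
  subset_otu_table(table, taxa = names(prev)[keep])
}

#' Winsorize a count vector at an upper quantile
#'
#' Caps values above the nearest-rank (ceiling) upper-quantile order
#' statistic at that order statistic, limiting outlier leverage on model
#' fits. Values at or below the cap are unchanged.
#'
#' @param counts non-empty vector of non-negative integers.
#' @param upper_quantile fraction in (0, 1]; default 0.97.
#' @return integer vector of the same length.
#' @export
winsorize_taxon_counts <- function(counts, upper_quantile = 0.97) {
  if (!is.numeric(upper_quantile) || upper_quantile <= 0 || upper_quantile > 1) {
    stop("`upper_quantile` must be in (0, 1]", call. = FALSE)
  }
  if (length(counts) == 0) stop("empty count vector", call. = FALSE)
  cap <- sort(counts)[ceiling(upper_quantile * length(counts))]
  pmin(counts, cap)
}
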