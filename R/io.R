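# Readers/writers for the tab-delimited interchange formats: OTU tables
# (classic taxa-by-samples layout with an optional trailing taxonomy
# column), sample metadata sheets, newick trees and square distance
# matrices.

.SITES <- c("vagina", "cervix", "lower_tract", "uterus", "fallopian",
            "ovary", "urine", "peritoneal", "stool")
.COHORTS <- c("benign", "hyperplasia", "cancer")
.METHODS <- c("swab", "scrape", "biopsy", "stool")
.PH_LEVELS <- c("normal", "high", "unknown")

#' Read a tab-delimited OTU count table
#'
#' The classic convention: first column holds taxon identifiers, remaining
#' columns one sample each, with an optional trailing lineage column
#' (semicolon-delimited ranks). Orientation is declared, never guessed:
#' with `samples_as = "rows"` the first column instead holds sample
#' identifiers and columns are taxa.
#'
#' @param path file path.
#' @param samples_as `"columns"` (default, classic layout) or `"rows"`.
#' @param taxonomy_column optional name of the lineage column (commonly
#'   `"taxonomy"`); ignored when absent from the header.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, samples_as = c("columns", "rows"),
                           taxonomy_column = "taxonomy") {
  samples_as <- match.arg(samples_as)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                           colClasses = "character", sep = "\t")
  if (ncol(raw) < 2) stop("malformed table: fewer than two columns", call. = FALSE)
  ids <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  taxonomy <- NULL
  if (!is.null(taxonomy_column) && taxonomy_column %in% colnames(body)) {
    taxonomy <- stats::setNames(body[[taxonomy_column]], ids)
    body <- body[, setdiff(colnames(body), taxonomy_column), drop = FALSE]
  }
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("cell is not a non-negative integer at row '%s', column '%s'",
                 ids[bad[1, 1]], colnames(body)[bad[1, 2]]), call. = FALSE)
  }
  rownames(num) <- ids
  if (samples_as == "columns") {
    otu_table(t(num), taxonomy = taxonomy)
  } else {
    if (!is.null(taxonomy)) {
      stop("a taxonomy column is only meaningful with samples_as = 'columns'",
           call. = FALSE)
    }
    otu_table(num)
  }
}

#' Write an OTU table as tab-delimited text
#'
#' Inverse of [read_otu_table]; classic taxa-by-samples layout with the
#' lineage in a trailing `taxonomy` column when present.
#'
#' @param table an [otu_table].
#' @param path output file path.
#' @param samples_as orientation, as in [read_otu_table].
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, samples_as = c("columns", "rows")) {
  samples_as <- match.arg(samples_as)
  if (samples_as == "columns") {
    out <- data.frame(taxon = taxon_ids(table),
                      t(table$counts), check.names = FALSE)
    if (!is.null(table$taxonomy)) out$taxonomy <- unname(table$taxonomy)
  } else {
    out <- data.frame(sample = sample_ids(table), table$counts,
                      check.names = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata sheet
#'
#' Tab-delimited with header. Required columns: `sample`, `subject`,
#' `cohort`, `site`. Recognised optional columns: `collection_method`,
#' `enrichment_used`, `vaginal_ph` (category: normal/high/unknown),
#' `ph_value`, `age`, `bmi`, `menopausal`, `hypertension`. Categorical
#' levels are validated; subject-level covariates (cohort, pH, demographics)
#' must be constant within subject.
#'
#' @param path file path.
#' @return a `data.frame` with one validated record per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  md <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  validate_metadata(md)
}

#' Validate a metadata data frame
#'
#' @param md data frame with at least `sample`, `subject`, `cohort`, `site`.
#' @return the validated data frame (typed columns, `vaginal_ph` filled with
#'   `"unknown"` where absent).
#' @export
validate_metadata <- function(md) {
  req <- c("sample", "subject", "cohort", "site")
  missing_cols <- setdiff(req, colnames(md))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  md <- as.data.frame(md, stringsAsFactors = FALSE)
  if (anyDuplicated(md$sample)) {
    stop("duplicate sample identifiers in metadata", call. = FALSE)
  }
  check_levels <- function(x, levels, what) {
    bad <- setdiff(unique(stats::na.omit(x)), levels)
    if (length(bad)) {
      stop(sprintf("invalid %s level(s): %s", what, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  check_levels(md$cohort, .COHORTS, "cohort")
  check_levels(md$site, .SITES, "site")
  if ("collection_method" %in% colnames(md)) {
    check_levels(md$collection_method, .METHODS, "collection_method")
  }
  if (!"vaginal_ph" %in% colnames(md)) {
    md$vaginal_ph <- "unknown"
  } else {
    md$vaginal_ph[is.na(md$vaginal_ph) | md$vaginal_ph %in% c("", "NA")] <- "unknown"
    check_levels(md$vaginal_ph, .PH_LEVELS, "vaginal_ph")
  }
  for (col in c("age", "bmi", "ph_value")) {
    if (col %in% colnames(md)) md[[col]] <- as.numeric(md[[col]])
  }
  subject_level <- intersect(
    c("cohort", "vaginal_ph", "age", "bmi", "menopausal", "hypertension"),
    colnames(md))
  for (col in subject_level) {
    per_subj <- tapply(md[[col]], md$subject, function(v) length(unique(v)))
    if (any(per_subj > 1)) {
      stop(sprintf("'%s' varies within subject(s): %s", col,
                   paste(names(per_subj)[per_subj > 1], collapse = ", ")),
           call. = FALSE)
    }
  }
  md
}

#' Write a metadata sheet
#' @param md metadata data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a newick phylogenetic tree
#'
#' Parses a newick file (via ape), validates branch lengths, and
#' midpoint-roots unrooted input so downstream branch enumeration
#' (UniFrac) is well defined.
#'
#' @param path file path to a newick tree with branch lengths.
#' @return a rooted `phylo` object.
#' @export
read_newick_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("unparseable newick file: ", path, call. = FALSE)
  validate_tree(tree)
}

#' Validate (and root) a phylogenetic tree
#' @param tree a `phylo` object.
#' @return a rooted `phylo`, midpoint-rooted if the input was unrooted.
#' @export
validate_tree <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length in tree", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in tree", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tree
}

#' Read / write a square distance matrix
#'
#' Tab-delimited square layout with identifiers in the header row and first
#' column.
#'
#' @param path file path.
#' @return for `read_distance_matrix`, a symmetric zero-diagonal numeric
#'   matrix with identifier dimnames.
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  validate_distance_matrix(m)
  m
}

#' @rdname read_distance_matrix
#' @param d symmetric distance matrix.
#' @export
write_distance_matrix <- function(d, path) {
  out <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
validate_distance_matrix <- function(d) {
  if (nrow(d) != ncol(d)) stop("distance matrix is not square", call. = FALSE)
  if (!isTRUE(all.equal(unname(d), unname(t(d)), tolerance = 1e-10))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal is not zero", call. = FALSE)
  if (any(d < 0)) stop("negative distances", call. = FALSE)
  invisible(d)
}
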