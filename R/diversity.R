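# Alpha diversity (observed richness, Shannon entropy), rarefaction curves,
# and the beta-diversity / dissimilarity matrices consumed by the
# permutation tests: Bray-Curtis, unweighted and weighted UniFrac, and the
# single-taxon presence distance.

#' Observed OTU count of one sample
#'
#' Species richness: the number of taxa with a strictly positive count.
#'
#' @param counts non-negative count vector for one sample.
#' @return integer richness.
#' @export
observed_otu_count <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  sum(counts > 0)
}

#' Shannon diversity index of one sample
#'
#' Entropy of the relative-abundance distribution in nats:
#' H = -sum p_t log p_t over taxa with p_t > 0.
#'
#' @param counts non-negative count vector with positive total.
#' @return Shannon index (natural log).
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("Shannon index undefined for an all-zero sample", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Per-sample alpha-diversity records
#'
#' @param table an [otu_table].
#' @return data frame with columns `sample`, `observed_otus`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  data.frame(
    sample = sample_ids(table),
    observed_otus = apply(table$counts, 1, observed_otu_count),
    shannon = apply(table$counts, 1, shannon_index),
    row.names = NULL
  )
}

#' Rarefaction curves of the alpha-diversity metrics
#'
#' For each sample and depth, the mean over `reps` independent rarefied
#' draws of observed richness and the Shannon index. Depths exceeding a
#' sample's library size are skipped for that sample.
#'
#' @param table an [otu_table].
#' @param depths increasing vector of positive integer depths.
#' @param reps number of rarefied draws per depth.
#' @param seed integer seed.
#' @return data frame `sample`, `depth`, `observed_otus`, `shannon`.
#' @export
rarefaction_curves <- function(table, depths, reps = 10, seed) {
  if (!is.numeric(reps) || reps <= 0) stop("`reps` must be positive", call. = FALSE)
  if (any(depths <= 0 | depths != round(depths))) {
    stop("depths must be positive integers", call. = FALSE)
  }
  ls <- library_sizes(table)
  with_seed(seed, {
    rows <- list()
    for (depth in sort(depths)) {
      keep <- names(ls)[ls >= depth]
      if (!length(keep)) next
      counts <- table$counts[keep, , drop = FALSE]
      obs <- matrix(0, length(keep), reps)
      sha <- matrix(0, length(keep), reps)
      for (r in seq_len(reps)) {
        rare <- quiet_rrarefy(counts, depth)
        obs[, r] <- apply(rare, 1, observed_otu_count)
        sha[, r] <- apply(rare, 1, shannon_index)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = keep, depth = depth,
        observed_otus = rowMeans(obs), shannon = rowMeans(sha),
        row.names = NULL)
    }
    do.call(rbind, rows)
  })
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum |x_t - y_t| / sum (x_t + y_t); computed on the counts as
#' given (rarefy first for the study workflow).
#'
#' @param table an [otu_table] with all library sizes positive.
#' @return symmetric zero-diagonal matrix with values in `[0, 1]`.
#' @export
bray_curtis_matrix <- function(table) {
  ls <- library_sizes(table)
  if (any(ls <= 0)) {
    stop("zero-sum sample(s): ", paste(names(ls)[ls <= 0], collapse = ", "),
         call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(table$counts, method = "bray"))
  diag(d) <- 0
  d
}

#' Drop table taxa absent from a tree
#'
#' Reconciliation step before UniFrac: OTUs present in the table but absent
#' from the tree are dropped with a warning.
#'
#' @param table an [otu_table].
#' @param tree a rooted `phylo`.
#' @return the pruned [otu_table].
#' @export
reconcile_with_tree <- function(table, tree) {
  missing <- setdiff(taxon_ids(table), tree$tip.label)
  if (length(missing)) {
    warning(sprintf("dropping %d taxa absent from the tree: %s",
                    length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")),
            call. = FALSE)
    table <- subset_otu_table(table, taxa = setdiff(taxon_ids(table), missing))
  }
  table
}

# edge x tip incidence: which tips descend from each edge's child node
branch_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  M <- matrix(0, nrow(tree$edge), ntip)
  for (i in seq_along(desc)) M[i, desc[[i]]] <- 1
  colnames(M) <- tree$tip.label
  M
}

#' UniFrac distance matrix
#'
#' Branch-enumeration UniFrac on a rooted tree. Unweighted: for branches
#' with length l and per-sample descendant-presence indicators a, b,
#' d = sum l |a - b| / sum l max(a, b). Weighted (normalized): with
#' descendant abundance proportions p, q,
#' d = sum l |p - q| / sum l (p + q), so both variants live on `[0, 1]`.
#'
#' @param table an [otu_table]; every taxon must be a tree leaf (see
#'   [reconcile_with_tree]); rarefied input is the study convention.
#' @param tree rooted `phylo` with branch lengths.
#' @param weighted logical; `FALSE` for the presence/absence variant.
#' @return symmetric zero-diagonal matrix over samples.
#' @export
unifrac_matrix <- function(table, tree, weighted = FALSE) {
  tree <- validate_tree(tree)
  if (length(setdiff(taxon_ids(table), tree$tip.label))) {
    stop("table contains taxa absent from the tree; reconcile first",
         call. = FALSE)
  }
  ls <- library_sizes(table)
  if (any(ls <= 0)) {
    stop("empty sample(s): ", paste(names(ls)[ls <= 0], collapse = ", "),
         call. = FALSE)
  }
  M <- branch_incidence(tree)
  len <- tree$edge.length
  # samples x tips aligned to tree tip order (absent tips count 0)
  counts <- matrix(0, nrow(table$counts), ncol(M),
                   dimnames = list(sample_ids(table), colnames(M)))
  counts[, taxon_ids(table)] <- table$counts
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  if (weighted) {
    props <- counts / rowSums(counts)
    bp <- M %*% t(props)                      # edge x sample proportions
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      num <- sum(len * abs(bp[, i] - bp[, j]))
      den <- sum(len * (bp[, i] + bp[, j]))
      d[i, j] <- d[j, i] <- num / den
    }
  } else {
    bp <- (M %*% t(counts > 0)) > 0           # edge x sample presence
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      a <- bp[, i]; b <- bp[, j]
      d[i, j] <- d[j, i] <- sum(len * (a != b)) / sum(len * (a | b))
    }
  }
  d
}

#' Single-taxon presence/absence distance matrix
#'
#' Euclidean distance on the one-dimensional presence indicator of one
#' taxon: 0 when two samples agree on presence/absence, 1 otherwise. Used
#' by the shared-taxon permutation test.
#'
#' @param table an [otu_table].
#' @param taxon a taxon identifier present in the table.
#' @return symmetric 0/1 matrix over samples.
#' @export
taxon_presence_distance <- function(table, taxon) {
  if (!taxon %in% taxon_ids(table)) {
    stop("unknown taxon: ", taxon, call. = FALSE)
  }
  ind <- as.numeric(table$counts[, taxon] > 0)
  d <- abs(outer(ind, ind, "-"))
  dimnames(d) <- list(sample_ids(table), sample_ids(table))
  d
}
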