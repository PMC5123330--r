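# Shared helpers: tiny deterministic tables, designs and independent
# oracles used across the test files.

# small otu_table with named dims
tiny_table <- function(counts, samples = NULL, taxa = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- samples %||% paste0("s", seq_len(nrow(counts)))
  colnames(counts) <- taxa %||% paste0("t", seq_len(ncol(counts)))
  gyntract::otu_table(counts, taxonomy = taxonomy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# paired two-site design: one sample per subject per site
paired_design <- function(n_subjects, sites = c("vagina", "uterus")) {
  data.frame(
    sample = as.vector(outer(sites, seq_len(n_subjects),
                             function(s, i) paste0("S", i, "_", s))),
    subject = rep(paste0("S", seq_len(n_subjects)), each = length(sites)),
    cohort = "benign",
    site = rep(sites, n_subjects))
}

# independent naive UniFrac oracle: walks the tree recursively to collect
# descendant tip sets per edge, then applies the branch formulas directly
naive_unifrac <- function(counts, tree, weighted) {
  tips_under <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  props <- counts / rowSums(counts)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    num <- den <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tips <- tips_under(tree$edge[e, 2])
      l <- tree$edge.length[e]
      if (weighted) {
        pa <- sum(props[i, tips]); pb <- sum(props[j, tips])
        num <- num + l * abs(pa - pb)
        den <- den + l * (pa + pb)
      } else {
        a <- any(counts[i, tips] > 0); b <- any(counts[j, tips] > 0)
        num <- num + l * (a != b)
        den <- den + l * (a || b)
      }
    }
    d[i, j] <- d[j, i] <- num / den
  }
  d
}

# random otu_table whose taxa are the tips of a random tree
random_tree_table <- function(n_taxa, n_samples, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, br = function(k) rexp(k, 5))
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  counts <- matrix(rpois(n_samples * n_taxa, 3), n_samples, n_taxa,
                   dimnames = list(paste0("s", seq_len(n_samples)),
                                   tree$tip.label))
  counts[1, ] <- counts[1, ] + 1  # no empty sample
  list(tree = tree, table = tiny_table(counts, taxa = tree$tip.label))
}

# exact two-sided Fisher p by full hypergeometric enumeration (2x2)
enumerate_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  obs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
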