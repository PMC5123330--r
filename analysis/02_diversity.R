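#!/usr/bin/env Rscript
# Alpha diversity (observed richness, Shannon) with the random-intercept
# mixed model for the cohort contrast, then rarefaction and the
# beta-diversity matrices (Bray-Curtis, both UniFrac variants) with a
# principal-coordinates summary.

suppressMessages(library(gyntract))

out <- "results"
table <- read_otu_table("results/study/otu_table.tsv")
metadata <- read_metadata("results/study/metadata.tsv")
tree <- read_newick_tree("results/study/tree.nwk")

alpha <- alpha_diversity(table)
write.table(alpha, file.path(out, "alpha_diversity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

lme_rows <- do.call(rbind, lapply(c("observed_otus", "shannon"), function(m) {
  cbind(metric = m, alpha_diversity_lme(alpha, metadata, metric = m))
}))
write.table(lme_rows, file.path(out, "alpha_lme.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("alpha-diversity cohort contrasts (random intercept per subject):\n")
print(lme_rows, digits = 3)

depth <- min(library_sizes(table))
cat(sprintf("\nrarefying to the minimum library size (%d reads)\n", depth))
rare <- rarefy_table(table, depth, seed = 1L)

bray <- bray_curtis_matrix(rare)
write_distance_matrix(bray, file.path(out, "bray_curtis.tsv"))
rare_tree <- reconcile_with_tree(rare, tree)
for (w in c(FALSE, TRUE)) {
  d <- unifrac_matrix(rare_tree, tree, weighted = w)
  write_distance_matrix(d, file.path(
    out, if (w) "unifrac_weighted.tsv" else "unifrac_unweighted.tsv"))
}

ord <- pcoa_ordination(bray, k = 2)
coords <- data.frame(sample = rownames(ord$coordinates), ord$coordinates)
write.table(coords, file.path(out, "pcoa_bray.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("PCoA axis shares: %.1f%%, %.1f%%\n",
            100 * ord$share[1], 100 * ord$share[2]))
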