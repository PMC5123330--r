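#!/usr/bin/env Rscript
# Block-permutation tests on the distance matrices: the organ-correlation
# matrix over all site pairs (are a subject's organs more alike than
# different subjects' organs?), PERMANOVA for cohort structure, and the
# cohort distance contrast asking whether hyperplasia sits closer to the
# cancer arm than to the benign arm.

suppressMessages(library(gyntract))

metadata <- read_metadata("results/study/metadata.tsv")
bray <- read_distance_matrix("results/bray_curtis.tsv")
unifrac_u <- read_distance_matrix("results/unifrac_unweighted.tsv")
metadata <- metadata[metadata$sample %in% rownames(bray), ]

sites <- sort(unique(metadata$site))
pairs <- combn(sites, 2, simplify = FALSE)
pairs <- Filter(function(p) {
  length(intersect(metadata$subject[metadata$site == p[1]],
                   metadata$subject[metadata$site == p[2]])) >= 2
}, pairs)
organ <- do.call(rbind, lapply(seq_along(pairs), function(i) {
  res <- organ_correlation_test(bray, metadata, pairs[[i]],
                                n_perm = 999, seed = 100L + i)
  data.frame(site_a = pairs[[i]][1], site_b = pairs[[i]][2],
             statistic = res$statistic_observed, p_value = res$p_value)
}))
write.table(organ, "results/organ_correlation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("organ-correlation tests (Bray-Curtis, subject labels permuted within site):\n")
print(organ, digits = 3)

pm <- permanova_block(unifrac_u, metadata, terms = "cohort",
                      n_perm = 999, seed = 200L)
write.table(pm$table, "results/permanova_cohort.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nPERMANOVA for cohort (unweighted UniFrac):\n")
print(pm)

contrast <- cohort_distance_difference_test(
  unifrac_u, metadata, "hyperplasia", "benign", "cancer",
  n_perm = 999, seed = 300L)
cat(sprintf("\nd(hyperplasia, benign) - d(hyperplasia, cancer) = %.4f, p = %.3g\n",
            contrast$statistic_observed, contrast$p_value))
cat("(positive statistic: hyperplasia lies closer to the cancer arm)\n")
write.table(
  data.frame(contrast = "d(hyperplasia,benign) - d(hyperplasia,cancer)",
             statistic = contrast$statistic_observed,
             p_value = contrast$p_value),
  "results/cohort_contrast.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
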