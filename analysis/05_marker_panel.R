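#!/usr/bin/env Rscript
# Marker-panel evaluation, twice: (1) the study's printed per-patient
# panel — detection of the two marker organisms in the lower tract plus
# vaginal pH — reproducing the printed sensitivities/specificities and the
# demographic Fisher tests; (2) the same rules on the synthetic study,
# with ROC/AUC from per-patient median relative abundances.

suppressMessages(library(gyntract))

cat("== printed study panel ==\n")
t5 <- table5_fixture()
rules <- do.call(rbind, lapply(
  c("A", "P", "A_and_P", "A_or_P_plus_highpH"), function(r) {
    res <- evaluate_panel_rule(t5, r)
    data.frame(rule = r,
               sensitivity = res$sensitivity, specificity = res$specificity,
               cases = res$n_cases_evaluable,
               controls = res$n_controls_evaluable)
  }))
print(rules, digits = 3)
write.table(rules, "results/panel_rules_printed.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

t1 <- table1_fixture()
fisher <- data.frame(
  variable = c("vaginal_ph", "menopausal", "hypertension", "diabetes"),
  p_value = vapply(t1[c("vaginal_ph", "menopausal", "hypertension",
                        "diabetes")],
                   function(m) fisher_exact_test(cohort_2x2(m)), numeric(1)))
cat("\ndemographic Fisher tests (benign vs cancer, unknowns excluded):\n")
print(fisher, digits = 3)
write.table(fisher, "results/demographics_fisher.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("\n== synthetic study panel ==\n")
table <- read_otu_table("results/study/otu_table.tsv")
metadata <- read_metadata("results/study/metadata.tsv")
call_A <- patient_detection_calls(table, metadata, "OTU_1")
call_P <- patient_detection_calls(table, metadata, "OTU_2")
panel <- marker_panel_table(metadata, call_A, call_P)
write.table(panel, "results/panel_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
synth_rules <- do.call(rbind, lapply(
  c("A", "P", "A_and_P", "A_or_P_plus_highpH"), function(r) {
    res <- evaluate_panel_rule(panel, r)
    data.frame(rule = r, sensitivity = res$sensitivity,
               specificity = res$specificity)
  }))
print(synth_rules, digits = 3)

sc_A <- marker_median_scores(table, metadata, "OTU_1")
sc_P <- marker_median_scores(table, metadata, "OTU_2")
keep <- names(sc_A)[metadata$cohort[match(names(sc_A), metadata$subject)] %in%
                      c("benign", "cancer")]
labels <- metadata$cohort[match(keep, metadata$subject)] == "cancer"
for (nm in c("A", "P", "combined")) {
  sc <- switch(nm, A = sc_A[keep], P = sc_P[keep],
               combined = pmax(sc_A[keep], sc_P[keep]))
  res <- roc_auc(sc, labels)
  cat(sprintf("AUC (%s, per-patient median relative abundance): %.3f\n",
              nm, res$auc))
  if (nm == "combined") {
    write.table(res$roc, "results/roc_combined.tsv",
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
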