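# Diagnostic marker-panel evaluation: per-patient detection calls from
# replicate samples, the composite presence/pH rules, sensitivity and
# specificity with an evaluable-denominator convention, ROC/AUC from
# per-patient median scores, and the cohort contingency tests.

#' Per-patient detection calls for a marker taxon
#'
#' A patient is called positive when the taxon has a nonzero count in any
#' replicate sample at the requested sites ("detected"), negative when all
#' replicates are zero. Patients with no samples at the sites get `NA` and
#' are excluded downstream.
#'
#' @param table an [otu_table].
#' @param metadata validated metadata.
#' @param taxon taxon identifier.
#' @param sites character vector of sites to pool (e.g. vagina + cervix for
#'   the lower tract).
#' @return named character vector (`"positive"`/`"negative"`/`NA`) over
#'   subjects.
#' @export
patient_detection_calls <- function(table, metadata, taxon,
                                    sites = c("vagina", "cervix", "lower_tract")) {
  if (!taxon %in% taxon_ids(table)) stop("unknown taxon: ", taxon, call. = FALSE)
  md <- metadata[metadata$sample %in% sample_ids(table), , drop = FALSE]
  subjects <- unique(md$subject)
  at_sites <- md[md$site %in% sites, , drop = FALSE]
  calls <- vapply(subjects, function(s) {
    samp <- at_sites$sample[at_sites$subject == s]
    if (!length(samp)) return(NA_character_)
    if (any(table$counts[samp, taxon] > 0)) "positive" else "negative"
  }, character(1))
  stats::setNames(calls, subjects)
}

#' Assemble a marker-panel table from detection calls
#'
#' One row per patient with cohort, vaginal pH category and the two marker
#' calls; the input layout for [evaluate_panel_rule].
#'
#' @param metadata validated metadata (subject-level cohort and
#'   `vaginal_ph`).
#' @param call_A,call_P named call vectors from [patient_detection_calls].
#' @return data frame `patient`, `cohort`, `ph`, `call_A`, `call_P`.
#' @export
marker_panel_table <- function(metadata, call_A, call_P) {
  subj <- unique(metadata$subject)
  first <- match(subj, metadata$subject)
  data.frame(patient = subj,
             cohort = metadata$cohort[first],
             ph = metadata$vaginal_ph[first],
             call_A = unname(call_A[subj]),
             call_P = unname(call_P[subj]),
             row.names = NULL)
}

# composite rule outcome per patient; NA = indeterminate (excluded)
panel_rule_outcome <- function(panel, rule) {
  A <- panel$call_A == "positive"
  P <- panel$call_P == "positive"
  high <- ifelse(panel$ph == "unknown", NA, panel$ph == "high")
  switch(rule,
    A = A,
    P = P,
    A_and_P = A & P,
    A_or_P_plus_highpH = {
      # positive when both markers are present, or when either marker is
      # present together with a high vaginal pH; indeterminate when the
      # outcome hinges on an unknown pH
      out <- (A & P) | ((A | P) & high)
      out[(A & P) & is.na(high)] <- TRUE
      out[!(A | P) & is.na(high)] <- FALSE
      out
    },
    stop("unknown rule: ", rule, call. = FALSE))
}

#' Evaluate a marker-panel rule (benign vs cancer)
#'
#' Computes the rule outcome per patient and summarises sensitivity
#' (rule-positive fraction among cancer patients) and specificity
#' (rule-negative fraction among benign patients). Patients whose outcome
#' is indeterminate — a missing marker call, or an unknown vaginal pH on
#' which the pH-dependent rule hinges — are excluded from the denominators.
#'
#' @param panel marker-panel data frame (`patient`, `cohort`, `ph`,
#'   `call_A`, `call_P`), e.g. from [marker_panel_table] or
#'   [table5_fixture].
#' @param rule `"A"`, `"P"`, `"A_and_P"`, or `"A_or_P_plus_highpH"` (the
#'   combined marker/pH rule: both markers, or either marker with high pH).
#' @return list: `rule`, `sensitivity`, `specificity`,
#'   `n_cases_evaluable`, `n_controls_evaluable`, `n_cases_positive`,
#'   `n_controls_negative`, `excluded` (patient ids).
#' @export
evaluate_panel_rule <- function(panel, rule = c("A", "P", "A_and_P",
                                                "A_or_P_plus_highpH")) {
  rule <- match.arg(rule)
  if (!any(panel$cohort == "cancer") || !any(panel$cohort == "benign")) {
    stop("panel must contain benign and cancer patients", call. = FALSE)
  }
  outcome <- panel_rule_outcome(panel, rule)
  cases <- panel$cohort == "cancer"
  controls <- panel$cohort == "benign"
  ev <- !is.na(outcome)
  if (!any(cases & ev) || !any(controls & ev)) {
    stop("no evaluable patients for rule ", rule, call. = FALSE)
  }
  list(rule = rule,
       sensitivity = mean(outcome[cases & ev]),
       specificity = mean(!outcome[controls & ev]),
       n_cases_evaluable = sum(cases & ev),
       n_controls_evaluable = sum(controls & ev),
       n_cases_positive = sum(outcome[cases & ev]),
       n_controls_negative = sum(!outcome[controls & ev]),
       excluded = panel$patient[(cases | controls) & !ev])
}

#' Per-patient median relative-abundance scores for a marker
#'
#' The ROC score convention: each patient is scored by the median across
#' replicate samples (at the chosen sites) of the marker's relative
#' abundance.
#'
#' @inheritParams patient_detection_calls
#' @return named numeric vector over subjects with samples at the sites.
#' @export
marker_median_scores <- function(table, metadata, taxon,
                                 sites = c("vagina", "cervix", "lower_tract")) {
  if (!taxon %in% taxon_ids(table)) stop("unknown taxon: ", taxon, call. = FALSE)
  md <- metadata[metadata$sample %in% sample_ids(table) &
                   metadata$site %in% sites, , drop = FALSE]
  rel <- table$counts[md$sample, taxon] / library_sizes(table)[md$sample]
  scores <- tapply(rel, md$subject, stats::median)
  stats::setNames(as.numeric(scores), names(scores))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds (score >= threshold =
#' positive call) and integrates the curve by the trapezoid rule, which
#' equals the rank-sum probability U / (n1 n2) with ties counted one half.
#'
#' @param scores numeric per-patient scores (higher = more case-like).
#' @param labels logical or 0/1 vector, `TRUE`/1 = case.
#' @return list: `roc` (data frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels", call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need at least one case and one control", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Two-sided Fisher exact test on a 2-way contingency table
#'
#' Point-probability rule: the p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's.
#'
#' @param table2x2 non-negative integer matrix (2x2 or r x c).
#' @return two-sided p-value.
#' @export
fisher_exact_test <- function(table2x2) {
  m <- as.matrix(table2x2)
  if (any(m < 0) || any(m != round(m))) {
    stop("contingency table must hold non-negative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("empty margin in contingency table", call. = FALSE)
  }
  stats::fisher.test(m)$p.value
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration for small samples without ties (n1 + n2 <= 10),
#' otherwise the normal approximation with tie correction.
#'
#' @param x,y numeric vectors.
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 10) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)$p.value)
  if (is.nan(p)) p <- 1  # every observation tied: no evidence either way
  p
}
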