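# Hard-coded study tables: the per-patient marker/pH panel and the cohort
# demographics contingency counts, entered cell-for-cell from the printed
# study tables so the in-study numbers are testable without any download.

#' Per-patient marker panel of the endometrial-cancer study
#'
#' The 29-patient panel (10 benign, 15 cancer, 4 hyperplasia): vaginal pH
#' category, the Atopobium vaginae (`call_A`) and Porphyromonas sp.
#' (`call_P`) lower-tract detection calls, and the printed composite rule
#' columns — `printed_A_and_P` (both markers) and `printed_A_or_P_pH`
#' (either marker combined with pH; `NA` where the outcome hinges on the
#' one unknown pH measurement, patient EC62).
#'
#' @return data frame with one row per patient.
#' @export
table5_fixture <- function() {
  txt <- "patient cohort ph call_A call_P printed_A_and_P printed_A_or_P_pH
B02 benign normal positive negative negative negative
B04 benign normal negative negative negative negative
B05 benign normal negative negative negative negative
B09 benign normal negative negative negative negative
B24 benign normal negative negative negative negative
B25 benign high positive negative negative positive
B26 benign high negative positive negative positive
B27 benign high positive positive positive positive
B30 benign normal negative negative negative negative
B32 benign high positive negative negative positive
EC06 cancer high positive positive positive positive
EC10 cancer high positive positive positive positive
EC11 cancer high positive positive positive positive
EC12 cancer high positive positive positive positive
EC13 cancer normal positive positive positive positive
EC14 cancer normal positive positive positive positive
EC15 cancer normal positive positive positive positive
EC19 cancer high positive positive positive positive
EC22 cancer normal positive positive positive positive
EC28 cancer high positive positive positive positive
EC31 cancer high positive negative negative positive
EC42 cancer high positive negative negative positive
EC54 cancer high positive positive positive positive
EC62 cancer unknown negative positive negative NA
EC65 cancer high positive negative negative positive
H07 hyperplasia high negative negative negative negative
H08 hyperplasia high negative negative negative negative
H63 hyperplasia normal negative positive negative negative
H72 hyperplasia normal positive negative negative negative"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Cohort demographics contingency counts
#'
#' Categorical benign/cancer (and hyperplasia) counts of the study's
#' demographics table: vaginal pH, menopausal status, hypertension,
#' diabetes and smoking history. Rows are categories, columns cohorts;
#' `unknown` rows are retained and should be dropped before a Fisher test
#' (see [cohort_2x2]).
#'
#' @return named list of integer matrices.
#' @export
table1_fixture <- function() {
  mk <- function(v, rn) {
    matrix(v, nrow = length(rn), ncol = 3, dimnames = list(
      rn, c("benign", "cancer", "hyperplasia")))
  }
  list(
    vaginal_ph = mk(c(6, 4, 0, 1, 15, 1, 2, 2, 0),
                    c("normal", "high", "unknown")),
    menopausal = mk(c(8, 2, 3, 14, 3, 1), c("pre_peri", "post")),
    hypertension = mk(c(1, 8, 1, 10, 7, 0, 1, 3, 0),
                      c("yes", "no", "unknown")),
    diabetes = mk(c(1, 9, 4, 13, 0, 4), c("yes", "no")),
    smoking = mk(c(5, 2, 3, 0, 9, 4, 2, 2, 3, 1, 0, 0),
                 c("never", "previous", "current", "unknown"))
  )
}

#' Benign-vs-cancer table with unknowns excluded
#'
#' @param counts one matrix from [table1_fixture].
#' @return matrix restricted to the benign and cancer columns with any
#'   `unknown` row dropped; input to [fisher_exact_test].
#' @export
cohort_2x2 <- function(counts) {
  counts[setdiff(rownames(counts), "unknown"), c("benign", "cancer"),
         drop = FALSE]
}
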