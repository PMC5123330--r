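# Model layer around the PQL fitter: the linear mixed model for
# alpha-diversity, the Poisson-vs-binomial family rule, the
# differential-abundance scan, and Benjamini-Hochberg FDR.

#' Linear mixed model for alpha diversity
#'
#' Fits `metric ~ cohort (+ covariates)` with a per-subject random
#' intercept by REML (nlme) and reports the Wald test for each non-reference
#' cohort level. When the mixed fit fails or is singular (e.g. one sample
#' per subject), the model falls back to ordinary least squares with a
#' warning.
#'
#' @param alpha data frame from [alpha_diversity] (columns `sample` and the
#'   metric).
#' @param metadata validated metadata.
#' @param metric `"shannon"` or `"observed_otus"`.
#' @param covariates optional character vector of metadata columns to
#'   adjust for.
#' @return data frame: one row per cohort contrast with `coefficient`,
#'   `std_error`, `df`, `t_value`, `p_value`, and the fitting `method`.
#' @export
alpha_diversity_lme <- function(alpha, metadata,
                                metric = c("shannon", "observed_otus"),
                                covariates = NULL) {
  metric <- match.arg(metric)
  dat <- merge(alpha, metadata, by = "sample")
  dat$value <- dat[[metric]]
  dat$cohort <- factor(dat$cohort)
  if (nlevels(dat$cohort) < 2) stop("need >= 2 cohorts", call. = FALSE)
  rhs <- paste(c("cohort", covariates), collapse = " + ")
  form <- stats::as.formula(paste("value ~", rhs))

  fit <- tryCatch(
    nlme::lme(form, random = ~ 1 | subject, data = dat, method = "REML"),
    error = function(e) NULL)
  if (!is.null(fit)) {
    tt <- summary(fit)$tTable
    rows <- grep("^cohort", rownames(tt))
    out <- data.frame(
      term = rownames(tt)[rows],
      coefficient = tt[rows, "Value"],
      std_error = tt[rows, "Std.Error"],
      df = tt[rows, "DF"],
      t_value = tt[rows, "t-value"],
      p_value = tt[rows, "p-value"],
      method = "lme", row.names = NULL)
    return(out)
  }
  warning("mixed model failed (likely singular); falling back to ordinary regression",
          call. = FALSE)
  lmfit <- stats::lm(form, data = dat)
  tt <- summary(lmfit)$coefficients
  rows <- grep("^cohort", rownames(tt))
  data.frame(
    term = rownames(tt)[rows],
    coefficient = tt[rows, "Estimate"],
    std_error = tt[rows, "Std. Error"],
    df = lmfit$df.residual,
    t_value = tt[rows, "t value"],
    p_value = tt[rows, "Pr(>|t|)"],
    method = "lm", row.names = NULL)
}

#' Choose the count-model family for a taxon
#'
#' Overdispersed Poisson on the counts when the zero proportion is below
#' 25%; otherwise the taxon is too sparse for a count model and an
#' overdispersed binomial on presence/absence is used.
#'
#' @param counts taxon count vector across samples.
#' @return `"overdispersed_poisson"` or `"overdispersed_binomial"`.
#' @export
choose_family <- function(counts) {
  if (!length(counts)) stop("empty count vector", call. = FALSE)
  if (mean(counts == 0) < 0.25) "overdispersed_poisson" else "overdispersed_binomial"
}

#' Benjamini-Hochberg q-values
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @return step-up adjusted q-values (monotone, capped at 1).
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential-abundance scan between benign and cancer cohorts
#'
#' The full per-taxon pipeline: aggregate to the requested rank, restrict
#' to the scope's samples and the benign/cancer cohorts (hyperplasia is
#' held out of the primary contrast), filter taxa below 20% prevalence,
#' winsorize each count vector at the 97% upper quantile, pick the family
#' per taxon ([choose_family]), fit the PQL random-intercept model
#' ([fit_overdispersed_glmm]) with the site covariate in the pooled scope,
#' and report Benjamini-Hochberg q-values over the scanned taxa, sorted by
#' p-value.
#'
#' @param table an [otu_table] (unrarefied counts; library sizes enter the
#'   models as offsets/covariates).
#' @param metadata validated metadata.
#' @param level `"otu"`, or a rank for [aggregate_taxa].
#' @param scope `"pooled"` (uterus + lower tract, site covariate),
#'   `"uterus_only"` or `"lower_tract_only"`.
#' @param min_prevalence,winsor_quantile filtering/capping parameters.
#' @param cohorts length-2 character: reference and test cohort.
#' @return data frame with one row per scanned taxon: `taxon`, `test`
#'   (`"Counts"` / `"Presence/absence"`), `coefficient`, `std_error`, `df`,
#'   `t_value`, `p_value`, `q_value`, `converged`.
#' @export
differential_abundance_scan <- function(table, metadata,
                                        level = c("genus", "phylum", "family", "otu"),
                                        scope = c("pooled", "uterus_only",
                                                  "lower_tract_only"),
                                        min_prevalence = 0.20,
                                        winsor_quantile = 0.97,
                                        cohorts = c("benign", "cancer")) {
  level <- match.arg(level)
  scope <- match.arg(scope)
  lower_sites <- c("vagina", "cervix", "lower_tract")
  sites <- switch(scope,
                  pooled = c("uterus", lower_sites),
                  uterus_only = "uterus",
                  lower_tract_only = lower_sites)
  md <- metadata[metadata$cohort %in% cohorts & metadata$site %in% sites, ,
                 drop = FALSE]
  md <- md[md$sample %in% sample_ids(table), , drop = FALSE]
  if (length(unique(md$cohort)) < 2) {
    stop("both cohorts must be present in the scope", call. = FALSE)
  }
  if (level != "otu") table <- aggregate_taxa(table, level)
  tab <- subset_otu_table(table, samples = md$sample)
  libsize <- library_sizes(tab)
  tab <- filter_by_prevalence(tab, min_prevalence)
  if (ncol(tab$counts) < 2) {
    stop("fewer than two taxa survive the prevalence filter", call. = FALSE)
  }
  cohort <- factor(md$cohort, levels = cohorts)
  site_cov <- if (scope == "pooled") {
    factor(ifelse(md$site == "uterus", "uterus", "lower_tract"))
  } else NULL

  rows <- lapply(taxon_ids(tab), function(tx) {
    v <- tab$counts[, tx]
    fam <- choose_family(v)
    y <- if (fam == "overdispersed_poisson") {
      winsorize_taxon_counts(v, winsor_quantile)
    } else {
      as.numeric(v > 0)
    }
    fit <- suppressWarnings(
      fit_overdispersed_glmm(y, family = fam, cohort = cohort,
                             site = site_cov, subject = md$subject,
                             libsize = libsize))
    data.frame(taxon = tx,
               test = if (fam == "overdispersed_poisson") "Counts" else "Presence/absence",
               coefficient = fit$coefficient, std_error = fit$std_error,
               df = fit$df, t_value = fit$t_value, p_value = fit$p_value,
               converged = fit$converged, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value), c("taxon", "test", "coefficient", "std_error",
                                   "df", "t_value", "p_value", "q_value",
                                   "converged")]
  rownames(out) <- NULL
  attr(out, "scope") <- scope
  attr(out, "level") <- level
  out
}
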