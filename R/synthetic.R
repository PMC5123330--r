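# Hierarchical synthetic multi-organ microbiome studies. The generator
# emulates the statistical structure the analysis assumes: per-subject,
# per-taxon log-abundance intercepts (host selection), site shifts,
# cohort-enriched taxa, gamma-Poisson (negative-binomial-type)
# overdispersed counts scaled to log-normal library sizes, and a
# presence/absence two-marker panel with a vaginal-pH model layered on top
# of the compositional background.

#' Parameters of a synthetic multi-organ study
#'
#' Defaults reproduce the study conditions: 10 benign / 4 hyperplasia / 17
#' cancer subjects, body-site sampling probabilities matching the reported
#' amplification success per site, library sizes log-normal on the
#' reported 1.7e4-8.3e5 read range, twelve cancer-enriched taxa, and a
#' two-marker presence/pH model with per-cohort detection rates matching
#' the printed panel margins.
#'
#' @param n_benign,n_hyperplasia,n_cancer subject counts per cohort.
#' @param sites named vector of per-site sampling probabilities.
#' @param n_taxa number of taxa (including the two marker taxa).
#' @param subject_effect_sd SD of per-subject, per-taxon log-abundance
#'   intercepts (host-correlation strength).
#' @param site_effect_sd SD of per-site, per-taxon log shifts.
#' @param base_log_sd SD of baseline per-taxon log abundances.
#' @param enriched_taxa integer indices of cohort-enriched taxa.
#' @param enriched_logfold log-fold enrichment in the cancer cohort.
#' @param enriched_base_shift centre of the baseline log abundance of
#'   enriched taxa (default -1.5, with a tight 0.5 SD): the
#'   cancer-associated organisms this emulates are low-abundance community
#'   members, so their baseline share is kept small enough not to displace
#'   the rest of the composition yet prevalent enough to pass the 20%
#'   prevalence filter.
#' @param hyperplasia_fraction fraction of the cancer effect applied to
#'   hyperplasia subjects (the precursor state sits near the cancer arm).
#' @param dispersion gamma-Poisson overdispersion (0 = pure Poisson).
#' @param libsize_log_mean,libsize_log_sd log-normal library-size model.
#' @param marker_model list of per-cohort probabilities: `detect_A`,
#'   `detect_P` (lower-tract marker detection), `high_ph`, `unknown_ph`.
#' @param seed integer seed.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(n_benign = 10, n_hyperplasia = 4, n_cancer = 17,
                         sites = c(vagina = 0.94, cervix = 0.94,
                                   uterus = 0.87, fallopian = 0.50,
                                   ovary = 0.61),
                         n_taxa = 120,
                         subject_effect_sd = 1,
                         site_effect_sd = 0.5,
                         base_log_sd = 1.5,
                         enriched_taxa = 3:14,
                         enriched_logfold = 1.5,
                         enriched_base_shift = -1.5,
                         hyperplasia_fraction = 1.0,
                         dispersion = 0.25,
                         libsize_log_mean = 11.8,
                         libsize_log_sd = 0.9,
                         marker_model = list(
                           detect_A = c(benign = 0.40, hyperplasia = 0.25,
                                        cancer = 14 / 15),
                           detect_P = c(benign = 0.20, hyperplasia = 0.25,
                                        cancer = 12 / 15),
                           high_ph = c(benign = 0.40, hyperplasia = 0.50,
                                       cancer = 10 / 14),
                           unknown_ph = c(benign = 0, hyperplasia = 0,
                                          cancer = 1 / 15)),
                         seed = 1L) {
  stopifnot(n_benign >= 0, n_hyperplasia >= 0, n_cancer >= 0,
            subject_effect_sd >= 0, site_effect_sd >= 0, dispersion >= 0,
            all(sites >= 0 & sites <= 1), n_taxa >= 4,
            all(enriched_taxa <= n_taxa))
  for (pr in marker_model) stopifnot(all(pr >= 0 & pr <= 1))
  structure(as.list(environment()), class = "synth_params")
}

#' Generate a random phylogenetic tree for the synthetic taxa
#'
#' Random bifurcating rooted topology with independent exponential branch
#' lengths (mean `mean_branch`); deterministic for a fixed seed.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed.
#' @param mean_branch mean branch length.
#' @param labels optional leaf labels (defaults to `OTU_1..OTU_n`).
#' @return a rooted `phylo`.
#' @export
generate_tree <- function(n_taxa, seed, mean_branch = 0.1, labels = NULL) {
  if (n_taxa < 2) stop("need at least two taxa", call. = FALSE)
  with_seed(seed, {
    tree <- ape::rtree(n_taxa,
                       br = function(k) stats::rexp(k, rate = 1 / mean_branch))
    tree$tip.label <- labels %||% paste0("OTU_", seq_len(n_taxa))
    tree
  })
}

#' Generate a synthetic multi-organ, multi-cohort study
#'
#' Draws subjects in three cohorts, a per-subject set of body-site samples
#' (each site included with its sampling probability; every subject keeps
#' at least a vaginal sample), and counts from a gamma-Poisson model over
#' per-sample relative abundances built from baseline + subject + site +
#' cohort log effects. Taxa 1 and 2 are the marker taxa, injected as
#' presence/absence in the lower-tract samples from per-cohort detection
#' probabilities, decoupled from the abundance background. Subject-level
#' vaginal pH and demographics are drawn per cohort.
#'
#' @param params a [synth_params] object.
#' @return list: `table` ([otu_table]), `metadata` (validated data frame),
#'   `tree` (`phylo`), and `truth` (enriched taxa ids, per-subject injected
#'   marker states).
#' @export
generate_study <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  with_seed(p$seed, {
    taxa <- paste0("OTU_", seq_len(p$n_taxa))
    marker_ids <- taxa[1:2]
    genus <- c("Atopobium", "Porphyromonas",
               paste0("G", ceiling(seq(3, p$n_taxa) / 2) - 1))
    phyla <- paste0("P", (seq_len(p$n_taxa) %% 4) + 1)
    taxonomy <- stats::setNames(
      paste(phyla, paste0("F", ceiling(seq_len(p$n_taxa) / 6)), genus, sep = ";"),
      taxa)

    subjects <- c(sprintf("B%02d", seq_len(p$n_benign)),
                  sprintf("H%02d", seq_len(p$n_hyperplasia)),
                  sprintf("EC%02d", seq_len(p$n_cancer)))
    cohorts <- rep(c("benign", "hyperplasia", "cancer"),
                   c(p$n_benign, p$n_hyperplasia, p$n_cancer))
    names(cohorts) <- subjects

    base <- stats::rnorm(p$n_taxa, 0, p$base_log_sd)
    base[p$enriched_taxa] <- stats::rnorm(length(p$enriched_taxa),
                                          p$enriched_base_shift, 0.5)
    site_names <- names(p$sites)
    site_shift <- matrix(stats::rnorm(length(site_names) * p$n_taxa,
                                      0, p$site_effect_sd),
                         nrow = length(site_names),
                         dimnames = list(site_names, taxa))
    # vagina and cervix form one lower-tract community stratum, matching
    # how the analysis pools them
    lower_present <- intersect(c("vagina", "cervix", "lower_tract"), site_names)
    if (length(lower_present) > 1) {
      for (s in lower_present[-1]) site_shift[s, ] <- site_shift[lower_present[1], ]
    }
    cohort_eff <- rep(0, p$n_taxa)
    cohort_eff[p$enriched_taxa] <- p$enriched_logfold

    method_of <- c(vagina = "swab", cervix = "swab", lower_tract = "swab",
                   uterus = "swab", fallopian = "biopsy", ovary = "biopsy",
                   urine = "swab", peritoneal = "biopsy", stool = "stool")
    lower_sites <- c("vagina", "cervix", "lower_tract")
    background <- setdiff(taxa, marker_ids)

    meta_rows <- list()
    count_rows <- list()
    truth_rows <- list()
    for (s in subjects) {
      co <- cohorts[[s]]
      a_st <- stats::rnorm(p$n_taxa, 0, p$subject_effect_sd)
      present <- site_names[stats::runif(length(site_names)) < p$sites]
      if (!length(present)) present <- "vagina"
      detect_A <- stats::runif(1) < p$marker_model$detect_A[[co]]
      detect_P <- stats::runif(1) < p$marker_model$detect_P[[co]]
      ph <- if (stats::runif(1) < p$marker_model$unknown_ph[[co]]) {
        "unknown"
      } else if (stats::runif(1) < p$marker_model$high_ph[[co]]) "high" else "normal"
      age <- round(switch(co, benign = stats::rnorm(1, 46, 6),
                          hyperplasia = stats::rnorm(1, 55, 6),
                          cancer = stats::rnorm(1, 64, 7)))
      bmi <- round(switch(co, benign = stats::rnorm(1, 28, 5),
                          hyperplasia = stats::rnorm(1, 33, 7),
                          cancer = stats::rnorm(1, 33, 6)), 1)
      hyp_pr <- switch(co, benign = 0.1, hyperplasia = 0.25, cancer = 0.59)
      hypertension <- if (stats::runif(1) < hyp_pr) "yes" else "no"
      truth_rows[[s]] <- data.frame(subject = s, cohort = co,
                                    detect_A = detect_A, detect_P = detect_P,
                                    row.names = NULL)
      for (site in present) {
        mult <- switch(co, benign = 0, hyperplasia = p$hyperplasia_fraction,
                       cancer = 1)
        lograte <- base + a_st + site_shift[site, ] + mult * cohort_eff
        rel <- exp(lograte)
        rel[match(marker_ids, taxa)] <- 0
        rel <- rel / sum(rel)
        N <- stats::rlnorm(1, p$libsize_log_mean, p$libsize_log_sd)
        gam <- if (p$dispersion > 0) {
          stats::rgamma(p$n_taxa, shape = 1 / p$dispersion, scale = p$dispersion)
        } else rep(1, p$n_taxa)
        counts <- stats::rpois(p$n_taxa, rel * N * gam)
        if (site %in% lower_sites) {
          rel_A <- stats::rlnorm(1, log(0.01), 0.8)
          rel_P <- stats::rlnorm(1, log(0.01), 0.8)
          counts[1] <- if (detect_A) max(1, stats::rpois(1, rel_A * N)) else 0
          counts[2] <- if (detect_P) max(1, stats::rpois(1, rel_P * N)) else 0
        } else {
          counts[1:2] <- 0
        }
        samp <- paste(s, site, sep = "_")
        count_rows[[samp]] <- counts
        meta_rows[[samp]] <- data.frame(
          sample = samp, subject = s, cohort = co, site = site,
          collection_method = method_of[[site]],
          enrichment_used = site %in% c("fallopian", "ovary"),
          vaginal_ph = ph, age = age, bmi = bmi,
          menopausal = if (age >= 51) "post" else "pre_peri",
          hypertension = hypertension,
          row.names = NULL)
      }
    }
    counts <- do.call(rbind, count_rows)
    colnames(counts) <- taxa
    table <- otu_table(counts, taxonomy = taxonomy)
    metadata <- validate_metadata(do.call(rbind, meta_rows))
    tree <- generate_tree(p$n_taxa, seed = child_seed(p$seed, 1L),
                          labels = taxa)
    list(table = table, metadata = metadata, tree = tree,
         truth = list(enriched_taxa = taxa[p$enriched_taxa],
                      markers = do.call(rbind, truth_rows)))
  })
}
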