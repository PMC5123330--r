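# End-to-end orchestration: simulate-or-load, rarefy, diversity, block
# permutation tests, differential abundance, marker panel; every stochastic
# stage draws its own child seed from the run seed and the manifest records
# enough to re-run bit-identically.

#' Build an analysis configuration
#'
#' @param simulation a [synth_params] object, used when no input paths are
#'   given.
#' @param otu_path,metadata_path,tree_path optional input files (tree may
#'   be `NULL`, disabling UniFrac).
#' @param rarefy_depth rarefaction depth; `NULL` = minimum library size.
#' @param n_perm permutations per test.
#' @param distance `"bray"`, `"unifrac-u"` or `"unifrac-w"` for the
#'   cohort-level tests.
#' @param site_pairs list of site pairs for the organ-correlation tests;
#'   `NULL` picks all pairs with at least two shared subjects.
#' @param diffabund_level,scope differential-abundance settings.
#' @param q_threshold FDR threshold used in the report.
#' @param marker_taxa named length-2 character (`A`, `P`) of marker taxon
#'   ids.
#' @param output_dir optional directory for TSV outputs.
#' @param seed master run seed; each stage derives a deterministic child
#'   seed.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(simulation = synth_params(),
                            otu_path = NULL, metadata_path = NULL,
                            tree_path = NULL,
                            rarefy_depth = NULL, n_perm = 999,
                            distance = c("bray", "unifrac-u", "unifrac-w"),
                            site_pairs = NULL,
                            diffabund_level = "genus",
                            scope = "pooled",
                            q_threshold = 0.10,
                            marker_taxa = c(A = "OTU_1", P = "OTU_2"),
                            output_dir = NULL,
                            seed = 1L) {
  distance <- match.arg(distance)
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full multi-site microbiome analysis
#'
#' Stage order: load/simulate -> alpha diversity + mixed model -> rarefy ->
#' distance matrices -> organ-correlation tests -> block PERMANOVA ->
#' cohort distance contrast -> differential-abundance scan -> marker panel.
#' Identical configurations (including the seed) give identical numeric
#' outputs.
#'
#' @param config an [analysis_config].
#' @return report bundle (list) with all stage results and a `manifest`;
#'   written as TSVs under `config$output_dir` when set.
#' @export
run_full_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- config$seed

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$otu_path)) {
    table <- read_otu_table(config$otu_path)
    metadata <- read_metadata(config$metadata_path)
    tree <- if (!is.null(config$tree_path)) read_newick_tree(config$tree_path)
  } else {
    sim <- config$simulation
    sim$seed <- child_seed(seed, 10L)
    study <- generate_study(sim)
    table <- study$table
    metadata <- study$metadata
    tree <- study$tree
  }
  metadata <- metadata[metadata$sample %in% sample_ids(table), , drop = FALSE]

  # --- alpha diversity ------------------------------------------------
  alpha <- alpha_diversity(table)
  alpha_lme <- do.call(rbind, lapply(c("observed_otus", "shannon"), function(m) {
    cbind(metric = m, alpha_diversity_lme(alpha, metadata, metric = m))
  }))

  # --- distances on rarefied counts ------------------------------------
  depth <- config$rarefy_depth %||% min(library_sizes(table))
  rare <- rarefy_table(table, depth, seed = child_seed(seed, 20L))
  md_rare <- metadata[metadata$sample %in% sample_ids(rare), , drop = FALSE]
  bray <- bray_curtis_matrix(rare)
  dist_main <- switch(config$distance,
    bray = bray,
    `unifrac-u` = unifrac_matrix(reconcile_with_tree(rare, tree), tree, FALSE),
    `unifrac-w` = unifrac_matrix(reconcile_with_tree(rare, tree), tree, TRUE))

  # --- organ correlation ----------------------------------------------
  pairs <- config$site_pairs
  if (is.null(pairs)) {
    sites <- unique(md_rare$site)
    pairs <- list()
    if (length(sites) >= 2) {
      for (combo in utils::combn(sort(sites), 2, simplify = FALSE)) {
        shared <- intersect(md_rare$subject[md_rare$site == combo[1]],
                            md_rare$subject[md_rare$site == combo[2]])
        if (length(shared) >= 2) pairs[[length(pairs) + 1L]] <- combo
      }
    }
  }
  organ <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    res <- organ_correlation_test(bray, md_rare, pairs[[i]],
                                  n_perm = config$n_perm,
                                  seed = child_seed(seed, 30L + i))
    data.frame(site_a = pairs[[i]][1], site_b = pairs[[i]][2],
               statistic = res$statistic_observed, p_value = res$p_value,
               n_perm = res$n_perm, row.names = NULL)
  }))

  # --- cohort structure -----------------------------------------------
  permanova <- permanova_block(dist_main, md_rare, terms = "cohort",
                               n_perm = config$n_perm,
                               seed = child_seed(seed, 40L))
  cohort_contrast <- NULL
  if (all(c("benign", "hyperplasia", "cancer") %in% md_rare$cohort)) {
    res <- cohort_distance_difference_test(
      dist_main, md_rare, "hyperplasia", "benign", "cancer",
      n_perm = config$n_perm, seed = child_seed(seed, 41L))
    cohort_contrast <- data.frame(
      contrast = "d(hyperplasia, benign) - d(hyperplasia, cancer)",
      statistic = res$statistic_observed, p_value = res$p_value,
      n_perm = res$n_perm, row.names = NULL)
  }
  ordination <- pcoa_ordination(dist_main, k = 2)

  # --- differential abundance -----------------------------------------
  diffabund <- differential_abundance_scan(
    table, metadata, level = config$diffabund_level, scope = config$scope)

  # --- marker panel ----------------------------------------------------
  panel <- rules <- roc <- NULL
  if (all(config$marker_taxa %in% taxon_ids(table))) {
    call_A <- patient_detection_calls(table, metadata, config$marker_taxa[["A"]])
    call_P <- patient_detection_calls(table, metadata, config$marker_taxa[["P"]])
    panel <- marker_panel_table(metadata, call_A, call_P)
    rules <- do.call(rbind, lapply(
      c("A", "P", "A_and_P", "A_or_P_plus_highpH"), function(r) {
        res <- evaluate_panel_rule(panel, r)
        data.frame(rule = r, sensitivity = res$sensitivity,
                   specificity = res$specificity,
                   n_cases = res$n_cases_evaluable,
                   n_controls = res$n_controls_evaluable, row.names = NULL)
      }))
    sc_A <- marker_median_scores(table, metadata, config$marker_taxa[["A"]])
    sc_P <- marker_median_scores(table, metadata, config$marker_taxa[["P"]])
    subj <- intersect(names(sc_A),
                      unique(metadata$subject[metadata$cohort %in%
                                                c("benign", "cancer")]))
    labels <- stats::setNames(
      metadata$cohort[match(subj, metadata$subject)] == "cancer", subj)
    roc <- list(
      A = roc_auc(sc_A[subj], labels),
      P = roc_auc(sc_P[subj], labels),
      combined = roc_auc(pmax(sc_A[subj], sc_P[subj]), labels))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gyntract")),
    seed = seed, rarefy_depth = depth, n_perm = config$n_perm,
    distance = config$distance,
    stage_order = c("load/simulate", "alpha+lme", "rarefy", "distances",
                    "organ-correlation", "permanova", "cohort-contrast",
                    "diffabund(aggregate>filter>winsorize>fit)", "panel"),
    stage_seeds = c(simulate = child_seed(seed, 10L),
                    rarefy = child_seed(seed, 20L),
                    permanova = child_seed(seed, 40L)))

  bundle <- list(table = table, metadata = metadata, tree = tree,
                 alpha = alpha, alpha_lme = alpha_lme,
                 rarefied = rare, bray = bray, distance = dist_main,
                 organ_correlation = organ, permanova = permanova,
                 cohort_contrast = cohort_contrast, ordination = ordination,
                 diffabund = diffabund, panel = panel, panel_rules = rules,
                 roc = roc, manifest = manifest)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) utils::write.table(
      x, file.path(config$output_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    w(alpha, "alpha_diversity.tsv")
    w(alpha_lme, "alpha_lme.tsv")
    write_distance_matrix(bray, file.path(config$output_dir, "bray_curtis.tsv"))
    if (!is.null(organ)) w(organ, "organ_correlation.tsv")
    w(permanova$table, "permanova.tsv")
    if (!is.null(cohort_contrast)) w(cohort_contrast, "cohort_contrast.tsv")
    w(diffabund, "differential_abundance.tsv")
    if (!is.null(rules)) w(rules, "panel_rules.tsv")
    writeLines(paste(names(unlist(manifest)), unlist(manifest), sep = "\t"),
               file.path(config$output_dir, "manifest.tsv"))
  }
  bundle
}
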