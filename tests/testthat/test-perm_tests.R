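test_that("block permutation moves whole subjects and respects strata", {
  md <- paired_design(2)
  seen <- vapply(1:20, function(s) {
    perm <- block_permutation(md, seed = s)
    # both samples of a subject always share a label
    expect_equal(unname(perm[paste0("S1_", c("vagina", "uterus"))][1]),
                 unname(perm[paste0("S1_", c("vagina", "uterus"))][2]))
    unname(perm["S1_vagina"])
  }, character(1))
  expect_setequal(unique(seen), c("S1", "S2"))  # identity or full swap only

  md4 <- paired_design(4)
  perms <- unique(vapply(1:500, function(s) {
    paste(block_permutation(md4, seed = s)[md4$sample[md4$site == "vagina"]],
          collapse = ",")
  }, character(1)))
  expect_equal(length(perms), factorial(4))  # exactly 4! distinct block maps

  for (s in 1:10) {
    strat <- block_permutation(md4, stratum = "site", seed = s)
    # a stratified permutation relabels within site; samples never change site
    for (site in c("vagina", "uterus")) {
      idx <- md4$sample[md4$site == site]
      expect_setequal(unname(strat[idx]), unique(md4$subject))
    }
  }
  expect_error(block_permutation(paired_design(1), seed = 1), "two subjects")
})

test_that("perfectly correlated organs give the minimal attainable p", {
  md <- paired_design(8)
  set.seed(5)
  pts <- rnorm(8, sd = 10)
  D <- as.matrix(dist(rep(pts, each = 2)))
  dimnames(D) <- list(md$sample, md$sample)
  res <- organ_correlation_test(D, md, c("vagina", "uterus"),
                                n_perm = 99, seed = 3)
  expect_gt(res$statistic_observed, 0)
  expect_equal(res$p_value, 1 / (99 + 1))
  expect_equal(length(res$null_statistics), 99)
})

test_that("sampled permutation p agrees with exhaustive enumeration", {
  md <- paired_design(5)
  set.seed(9)
  coords <- rnorm(10) + rep(rnorm(5, sd = 1.2), each = 2)
  D <- as.matrix(dist(coords)); dimnames(D) <- list(md$sample, md$sample)

  exact <- organ_correlation_test(D, md, c("vagina", "uterus"),
                                  n_perm = 999, seed = 1)
  expect_true(exact$exhaustive)
  expect_equal(exact$n_perm, factorial(5))

  sampled <- organ_correlation_test(D, md, c("vagina", "uterus"),
                                    n_perm = 99, seed = 7)
  mc_se <- sqrt(exact$p_value * (1 - exact$p_value) / 99)
  expect_lt(abs(sampled$p_value - exact$p_value), 2 * mc_se + 2 / 100)
})

test_that("permutation p-values are reproducible and bounded below", {
  md <- paired_design(8)
  set.seed(2)
  D <- as.matrix(dist(rnorm(16))); dimnames(D) <- list(md$sample, md$sample)
  a <- organ_correlation_test(D, md, c("vagina", "uterus"), n_perm = 99, seed = 5)
  b <- organ_correlation_test(D, md, c("vagina", "uterus"), n_perm = 99, seed = 5)
  expect_identical(a$p_value, b$p_value)
  expect_gte(a$p_value, 1 / 100)
})

test_that("shared-taxon test flags degenerate presence patterns", {
  md <- paired_design(4)
  counts <- matrix(5, 8, 2, dimnames = list(md$sample, c("tA", "tB")))
  tab <- otu_table(counts)
  expect_error(shared_taxon_test(tab, md, "tA", c("vagina", "uterus"),
                                 n_perm = 99, seed = 1),
               "degenerate.*present")

  # co-presence/co-absence within subjects, mixed across subjects
  counts[, "tB"] <- rep(c(1, 0, 1, 0), each = 2)
  tab <- otu_table(counts)
  res <- shared_taxon_test(tab, md, "tB", c("vagina", "uterus"),
                           n_perm = 999, seed = 2)
  expect_gt(res$statistic_observed, 0)
  expect_true(res$exhaustive)
  # exhaustive result equals brute-force enumeration over 4! relabellings
  subj <- md$subject[md$site == "uterus"]
  Dab <- taxon_presence_distance(tab, "tB")[md$sample[md$site == "vagina"],
                                            md$sample[md$site == "uterus"]]
  stats <- vapply(gyntract:::all_permutations(unique(subj)), function(p) {
    relab <- setNames(p, unique(subj))
    same <- outer(md$subject[md$site == "vagina"], relab[subj], "==")
    mean(Dab[!same]) - mean(Dab[same])
  }, numeric(1))
  expect_equal(res$p_value, mean(stats >= res$statistic_observed))
})

test_that("cohort distance contrast is antisymmetric in the compared cohorts", {
  md <- data.frame(sample = paste0("x", 1:9),
                   subject = paste0("x", 1:9),
                   cohort = rep(c("hyperplasia", "benign", "cancer"), each = 3),
                   site = "uterus")
  set.seed(4)
  D <- as.matrix(dist(rnorm(9))); dimnames(D) <- list(md$sample, md$sample)
  ab <- cohort_distance_difference_test(D, md, "hyperplasia", "benign",
                                        "cancer", n_perm = 99, seed = 1)
  ba <- cohort_distance_difference_test(D, md, "hyperplasia", "cancer",
                                        "benign", n_perm = 99, seed = 1)
  expect_equal(ab$statistic_observed, -ba$statistic_observed)
  expect_error(cohort_distance_difference_test(D, md, "hyperplasia",
                                               "benign", "stool",
                                               n_perm = 9, seed = 1),
               "empty cohort")
})

test_that("a displaced cohort is detected at moderate effect size", {
  set.seed(31)
  md <- data.frame(sample = paste0("x", 1:24),
                   subject = paste0("x", 1:24),
                   cohort = rep(c("benign", "hyperplasia", "cancer"), each = 8),
                   site = "uterus")
  coords <- c(rnorm(8, 3), rnorm(8, 0), rnorm(8, 0))  # benign displaced
  D <- as.matrix(dist(coords)); dimnames(D) <- list(md$sample, md$sample)
  res <- cohort_distance_difference_test(D, md, "hyperplasia", "benign",
                                         "cancer", n_perm = 999, seed = 2)
  expect_gt(res$statistic_observed, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("block PERMANOVA equals classical ANOVA F on 1-D Euclidean data", {
  set.seed(12)
  x <- c(rnorm(4, 0), rnorm(4, 1.5))
  md <- data.frame(sample = paste0("u", 1:8), subject = paste0("u", 1:8),
                   cohort = rep(c("benign", "cancer"), each = 4),
                   site = "uterus")
  D <- as.matrix(dist(x)); dimnames(D) <- list(md$sample, md$sample)
  res <- permanova_block(D, md, "cohort", n_perm = 99, seed = 1)
  f_classic <- summary(stats::aov(x ~ md$cohort))[[1]]$`F value`[1]
  expect_equal(res$table$pseudo_F[1], f_classic, tolerance = 1e-10)
  expect_equal(sum(res$table$R2[res$table$term != "total"]), 1)
  expect_gte(res$table$p_value[1], 1 / 100)

  # independent cross-check against vegan's PERMANOVA statistic
  ad <- vegan::adonis2(stats::as.dist(D) ~ cohort, data = md, permutations = 2)
  expect_equal(res$table$pseudo_F[1], ad$F[1], tolerance = 1e-10)
  expect_equal(res$table$R2[1], ad$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA sequential decomposition handles two terms and aliasing", {
  set.seed(14)
  md <- paired_design(6)
  md$cohort <- rep(c("benign", "cancer"), each = 6)
  coords <- rnorm(12) + ifelse(md$cohort == "cancer", 1, 0) +
    ifelse(md$site == "uterus", 0.5, 0)
  D <- as.matrix(dist(coords)); dimnames(D) <- list(md$sample, md$sample)
  res <- permanova_block(D, md, c("site", "cohort"), n_perm = 49, seed = 2)
  expect_equal(res$table$term[1:2], c("site", "cohort"))
  expect_equal(sum(res$table$R2[1:3]), 1)
  md$copy <- md$cohort  # aliased with cohort
  expect_error(permanova_block(D, md, c("cohort", "copy"), n_perm = 9, seed = 1),
               "rank-deficient")
})

test_that("principal coordinates recover line geometry and report eigenvalues", {
  x <- c(0, 1, 3, 7, 12)
  D <- as.matrix(dist(x)); dimnames(D) <- list(paste0("p", 1:5), paste0("p", 1:5))
  ord <- pcoa_ordination(D, k = 1)
  rec <- as.matrix(dist(ord$coordinates[, 1]))
  expect_equal(unname(rec), unname(D), tolerance = 1e-9)
  expect_lte(sum(ord$share[ord$share > 0]), 1 + 1e-12)

  Did <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(ord0 <- pcoa_ordination(Did, k = 2), "positive eigenvalue")
  expect_equal(ncol(ord0$coordinates), 0)
})
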