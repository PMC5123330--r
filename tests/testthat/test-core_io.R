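test_that("otu_table validates counts and identifiers", {
  tab <- tiny_table(matrix(c(1, 3, 2, 4), 2))
  expect_equal(unname(library_sizes(tab)), c(3, 7))
  expect_error(tiny_table(matrix(c(1, -2, 3, 4), 2)), "non-negative")
  expect_error(tiny_table(matrix(c(1, 2.5, 3, 4), 2)), "non-negative")
  expect_error(tiny_table(matrix(1:4, 2), samples = c("a", "a")), "duplicate sample")
  expect_error(tiny_table(matrix(1:4, 2), taxa = c("x", "x")), "duplicate taxon")
})

test_that("otu table file round-trip preserves random tables in both orientations", {
  for (seed in 1:5) {
    set.seed(seed)
    tab <- tiny_table(matrix(rpois(40, 4), 5, 8),
                      taxonomy = setNames(paste0("P1;F1;G", 1:8), paste0("t", 1:8)))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_otu_table(tab, path)
    back <- read_otu_table(path)
    expect_equal(back$counts, tab$counts)
    expect_equal(back$taxonomy, tab$taxonomy)
    write_otu_table(tab, path, samples_as = "rows")
    back2 <- read_otu_table(path, samples_as = "rows")
    expect_equal(back2$counts, tab$counts)
  }
})

test_that("malformed otu table cells raise parse errors naming the cell", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\ts1\ts2", "t1\t3\t-2", "t2\t1\t4"), path)
  expect_error(read_otu_table(path), "t1.*s2")
})

test_that("metadata reader validates schema, levels and subject constancy", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tsubject\tcohort\tsite",
               "a\tS1\tbenign\tvagina", "b\tS1\tbenign\tuterus"), path)
  md <- read_metadata(path)
  expect_equal(nrow(md), 2)
  expect_equal(unique(md$subject), "S1")
  expect_true(all(md$vaginal_ph == "unknown"))

  writeLines(c("sample\tsubject\tcohort\tsite",
               "a\tS1\tbenign\tvagina", "b\tS1\tcancer\tuterus"), path)
  expect_error(read_metadata(path), "cohort.*varies within")

  writeLines(c("sample\tsubject\tsite", "a\tS1\tvagina"), path)
  expect_error(read_metadata(path), "missing required column")

  writeLines(c("sample\tsubject\tcohort\tsite",
               "a\tS1\tbenign\tmoon"), path)
  expect_error(read_metadata(path), "invalid site")
})

test_that("the panel metadata sheet loads with 29 subjects and one unknown pH", {
  md <- read_metadata(system.file("extdata", "table5_metadata.tsv",
                                  package = "gyntract"))
  expect_equal(length(unique(md$subject)), 29)
  expect_equal(sum(md$cohort == "benign"), 10)
  expect_equal(md$vaginal_ph[md$subject == "EC62"], "unknown")
})

test_that("newick reading validates, roots, and round-trips", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tree <- read_newick_tree(path)
  expect_equal(sort(tree$tip.label), c("A", "B", "C"))
  expect_equal(sum(tree$edge.length), 5)

  writeLines("(A:1,B:1,C:1,D:1);", path)
  star <- read_newick_tree(path)
  expect_true(ape::is.rooted(star))
  expect_equal(sum(star$edge.length), 4)

  writeLines("(A:1,B:-1);", path)
  expect_error(read_newick_tree(path), "negative branch")

  set.seed(9)
  rt <- ape::rtree(12)
  ape::write.tree(rt, path)
  back <- read_newick_tree(path)
  expect_equal(sort(back$tip.label), sort(rt$tip.label))
  expect_equal(sum(back$edge.length), sum(rt$edge.length), tolerance = 1e-9)
})

test_that("rarefaction hits the exact depth and never inflates counts", {
  tab <- tiny_table(matrix(c(5, 1000, 5, 0), 2))
  r <- rarefy_table(tab, 10, seed = 1)  # sample 1 keeps all 10 reads
  expect_equal(unname(r$counts["s1", ]), c(5, 5))
  expect_warning(r2 <- rarefy_table(tab, 100, seed = 1), "dropping 1 sample")
  expect_equal(unname(r2$counts["s2", ]), c(100, 0))

  set.seed(4)
  big <- tiny_table(matrix(rpois(60, 30), 5, 12))
  r3 <- rarefy_table(big, 100, seed = 2)
  expect_true(all(rowSums(r3$counts) == 100))
  expect_true(all(r3$counts <= big$counts))
  expect_equal(rarefy_table(big, 100, seed = 2)$counts, r3$counts)
  expect_error(rarefy_table(big, 0, seed = 1), "positive integer")
})

test_that("rarefied draws match hypergeometric moments", {
  tab <- tiny_table(matrix(c(500, 500), 1))
  draws <- vapply(1:2000, function(i) {
    rarefy_table(tab, 100, seed = i)$counts[1, 1]
  }, numeric(1))
  hyper_sd <- sqrt(100 * 0.5 * 0.5 * (1000 - 100) / (1000 - 1))
  expect_lt(abs(mean(draws) - 50), 3 * hyper_sd / sqrt(length(draws)))
})

test_that("taxonomic aggregation sums lineages and conserves totals", {
  tax <- setNames(c("P1;F1;G1", "P1;F1;G1", "P1;F2;G2", "P2"), paste0("t", 1:4))
  tab <- tiny_table(matrix(c(3, 1, 4, 2, 5, 3, 6, 4), 2), taxonomy = tax)
  gen <- aggregate_taxa(tab, "genus")
  expect_equal(unname(gen$counts[1, "P1;F1;G1"]), 7)
  expect_true("unclassified" %in% taxon_ids(gen))  # t4 lacks a genus
  expect_equal(unname(library_sizes(gen)), unname(library_sizes(tab)))

  distinct <- tiny_table(matrix(rpois(12, 5), 3, 4),
                         taxonomy = setNames(paste0("P1;F1;G", 1:4),
                                             paste0("t", 1:4)))
  agg <- aggregate_taxa(distinct, "genus")
  expect_equal(ncol(agg$counts), 4)
  expect_equal(unname(library_sizes(agg)), unname(library_sizes(distinct)))
  expect_error(aggregate_taxa(tiny_table(matrix(1:4, 2)), "genus"), "taxonomy")
})

test_that("prevalence filter keeps the boundary and is idempotent", {
  m <- matrix(0, 25, 2)
  m[1:5, 1] <- 1          # exactly 20% prevalence -> kept
  m[1:4, 2] <- 1          # 16% -> removed
  m[, 1] <- m[, 1] + 0    # keep integer
  tab <- tiny_table(cbind(m, rep(1, 25)))
  filt <- filter_by_prevalence(tab, 0.20)
  expect_true("t1" %in% taxon_ids(filt))
  expect_false("t2" %in% taxon_ids(filt))
  again <- filter_by_prevalence(filt, 0.20)
  expect_equal(again$counts, filt$counts)

  set.seed(11)
  rnd <- tiny_table(matrix(rbinom(200, 1, 0.3) * rpois(200, 4), 20, 10))
  out <- filter_by_prevalence(rnd, 0.2)
  expect_true(all(colMeans(out$counts > 0) >= 0.2))
})

test_that("winsorization caps at the nearest-rank order statistic", {
  expect_equal(winsorize_taxon_counts(rep(7, 10)), rep(7, 10))
  expect_equal(winsorize_taxon_counts(1:100), c(1:97, 97, 97, 97))
  expect_equal(winsorize_taxon_counts(c(0, 0, 0, 0, 50)), c(0, 0, 0, 0, 50))
  set.seed(3)
  v <- rpois(40, 10)
  w <- winsorize_taxon_counts(v)
  expect_length(w, length(v))
  expect_true(all(w <= v))
  cap <- sort(v)[ceiling(0.97 * 40)]
  expect_equal(w[v <= cap], v[v <= cap])
  expect_error(winsorize_taxon_counts(1:5, 1.2), "\\(0, 1\\]")
})
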