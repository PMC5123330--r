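# Block-permutation machinery for repeated-measures microbiome designs and
# the distance-based tests built on it: organ correlation, shared-taxon,
# cohort distance contrast, and PERMANOVA with subject-level label
# permutation. Subjects are the exchangeable units; all samples of a
# subject always move together under the null.

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- vector("list", 0L)
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

new_permutation_result <- function(statistic, null_stats, n_perm, scheme, seed,
                                   exhaustive = FALSE, alternative = "greater") {
  # permutations where the statistic is undefined (no within-subject pair
  # under the relabelling) carry no evidence either way and are dropped
  null_stats <- null_stats[!is.na(null_stats)]
  extreme <- if (alternative == "greater") {
    null_stats >= statistic
  } else {
    abs(null_stats) >= abs(statistic)
  }
  p <- if (exhaustive) mean(extreme) else (1 + sum(extreme)) / (1 + length(null_stats))
  structure(list(
    statistic_observed = statistic,
    null_statistics = null_stats,
    p_value = p,
    n_perm = length(null_stats),
    scheme = scheme,
    seed = seed,
    exhaustive = exhaustive,
    alternative = alternative
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Block-permutation test (%s)\n", x$scheme))
  cat(sprintf("  statistic = %.6g, p = %.4g (%s%d permutations, %s)\n",
              x$statistic_observed, x$p_value,
              if (x$exhaustive) "exhaustive " else "", x$n_perm, x$alternative))
  invisible(x)
}

#' Block permutation of subject labels
#'
#' Permutes subject identities as whole blocks so within-subject correlation
#' is preserved under the null. Without a stratum, one permutation of the
#' subjects relabels every sample; with `stratum = "site"`, subject labels
#' are permuted independently within each body-site stratum, so a sample
#' never changes site.
#'
#' @param metadata validated metadata data frame.
#' @param unit exchangeable unit; only `"subject"` is supported.
#' @param stratum optional stratifying column (e.g. `"site"`).
#' @param seed integer seed.
#' @return character vector of permuted subject labels, named by sample.
#' @export
block_permutation <- function(metadata, unit = "subject", stratum = NULL, seed) {
  stopifnot(identical(unit, "subject"))
  if (length(unique(metadata$subject)) < 2) {
    stop("need at least two subjects to permute", call. = FALSE)
  }
  with_seed(seed, {
    out <- metadata$subject
    names(out) <- metadata$sample
    strata <- if (is.null(stratum)) rep("all", nrow(metadata)) else metadata[[stratum]]
    for (s in unique(strata)) {
      idx <- strata == s
      subj <- unique(metadata$subject[idx])
      perm <- stats::setNames(sample(subj), subj)
      out[idx] <- perm[metadata$subject[idx]]
    }
    out
  })
}

# mean cross-subject minus mean within-subject distance between two sites,
# given the subject labels of the site-B samples
organ_stat <- function(Dab, subjA, subjB) {
  same <- outer(subjA, subjB, "==")
  if (!any(same) || all(same)) return(NA_real_)
  mean(Dab[!same]) - mean(Dab[same])
}

#' Organ-correlation permutation test
#'
#' Tests whether two body sites of the same subject harbour more similar
#' communities than the same sites of different subjects. The statistic is
#' the mean between-subject site-A/site-B distance minus the mean
#' within-subject distance (positive = correlated organs). The null
#' permutes subject labels of the site-B sample blocks (distributionally
#' equivalent to permuting both strata independently); enumeration is
#' exhaustive when the permutation group is no larger than `n_perm`.
#'
#' @param D distance matrix over samples (e.g. Bray-Curtis on rarefied
#'   counts).
#' @param metadata validated metadata covering the rows of `D`.
#' @param site_pair character vector of two sites.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param alternative `"greater"` (directional, default) or `"two_sided"`.
#' @return a `permutation_result`.
#' @export
organ_correlation_test <- function(D, metadata, site_pair, n_perm = 999, seed,
                                   alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(site_pair) == 2)
  a <- metadata[metadata$site == site_pair[1], , drop = FALSE]
  b <- metadata[metadata$site == site_pair[2], , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stop("no samples at one of the sites", call. = FALSE)
  if (length(intersect(a$subject, b$subject)) < 2) {
    stop("need >= 2 subjects sampled at both sites", call. = FALSE)
  }
  Dab <- D[a$sample, b$sample, drop = FALSE]
  obs <- organ_stat(Dab, a$subject, b$subject)
  subjects_b <- unique(b$subject)
  k <- length(subjects_b)
  exhaustive <- factorial(k) <= n_perm
  null_stats <- with_seed(seed, {
    if (exhaustive) {
      vapply(all_permutations(subjects_b), function(perm) {
        relab <- stats::setNames(perm, subjects_b)
        organ_stat(Dab, a$subject, relab[b$subject])
      }, numeric(1))
    } else {
      vapply(seq_len(n_perm), function(i) {
        relab <- stats::setNames(sample(subjects_b), subjects_b)
        organ_stat(Dab, a$subject, relab[b$subject])
      }, numeric(1))
    }
  })
  new_permutation_result(obs, null_stats, n_perm,
                         scheme = sprintf("subject labels permuted within site '%s'",
                                          site_pair[2]),
                         seed = seed, exhaustive = exhaustive,
                         alternative = alternative)
}

#' Shared-taxon permutation test
#'
#' Applies the organ-correlation permutation scheme to the single-taxon
#' presence/absence distance ([taxon_presence_distance]): a positive
#' statistic means the taxon's presence state is shared within subjects
#' across the two sites more than expected between subjects.
#'
#' @inheritParams organ_correlation_test
#' @param table an [otu_table].
#' @param taxon taxon identifier.
#' @return a `permutation_result`.
#' @export
shared_taxon_test <- function(table, metadata, taxon, site_pair, n_perm = 999,
                              seed, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  # the statistic is permutation-invariant whenever the presence indicator
  # is constant within either site (all rows or columns of the cross-site
  # distance block are then identical)
  for (s in site_pair) {
    ind <- table$counts[metadata$sample[metadata$site == s], taxon] > 0
    if (all(ind) || !any(ind)) {
      stop(sprintf("degenerate input: taxon '%s' is %s in every sample at site '%s'",
                   taxon, if (all(ind)) "present" else "absent", s),
           call. = FALSE)
    }
  }
  D <- taxon_presence_distance(table, taxon)
  organ_correlation_test(D, metadata, site_pair, n_perm = n_perm, seed = seed,
                         alternative = alternative)
}

#' Cohort distance-difference permutation test
#'
#' Tests whether cohort A lies farther from cohort B than from cohort C in
#' community space: statistic = mean d(A, B) - mean d(A, C) over sample
#' pairs. The null permutes the B/C cohort labels across the B and C
#' subjects as whole blocks; cohort A is held fixed. Exhaustive enumeration
#' of the label assignments is used when the group is no larger than
#' `n_perm`.
#'
#' @inheritParams organ_correlation_test
#' @param cohortA,cohortB,cohortC cohort labels present in `metadata`.
#' @return a `permutation_result`.
#' @export
cohort_distance_difference_test <- function(D, metadata, cohortA, cohortB,
                                            cohortC, n_perm = 999, seed,
                                            alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  for (co in c(cohortA, cohortB, cohortC)) {
    if (!any(metadata$cohort == co)) stop("empty cohort: ", co, call. = FALSE)
  }
  sampA <- metadata$sample[metadata$cohort == cohortA]
  bc <- metadata[metadata$cohort %in% c(cohortB, cohortC), , drop = FALSE]
  subj_cohort <- tapply(bc$cohort, bc$subject, function(v) v[1])
  subjects <- names(subj_cohort)
  stat_fun <- function(assign) {
    sb <- bc$sample[assign[bc$subject] == cohortB]
    sc <- bc$sample[assign[bc$subject] == cohortC]
    mean(D[sampA, sb]) - mean(D[sampA, sc])
  }
  obs <- stat_fun(subj_cohort)
  n_b <- sum(subj_cohort == cohortB)
  n_group <- choose(length(subjects), n_b)
  exhaustive <- n_group <= n_perm
  null_stats <- with_seed(seed, {
    if (exhaustive) {
      apply(utils::combn(length(subjects), n_b), 2, function(ix) {
        assign <- stats::setNames(rep(cohortC, length(subjects)), subjects)
        assign[ix] <- cohortB
        stat_fun(assign)
      })
    } else {
      vapply(seq_len(n_perm), function(i) {
        assign <- stats::setNames(sample(unname(subj_cohort)), subjects)
        stat_fun(assign)
      }, numeric(1))
    }
  })
  new_permutation_result(obs, null_stats, n_perm,
                         scheme = sprintf("cohort labels of '%s'/'%s' subjects permuted as blocks",
                                          cohortB, cohortC),
                         seed = seed, exhaustive = exhaustive,
                         alternative = alternative)
}

# Gower-centered inner-product matrix of a distance matrix
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

seq_ss <- function(G, designs) {
  # sequential (type-I) sums of squares via cumulative projections
  n <- nrow(G)
  ss <- numeric(length(designs))
  dfs <- integer(length(designs))
  X <- matrix(1, n, 1)
  prev_tr <- 0
  prev_rank <- 1L
  for (i in seq_along(designs)) {
    X <- cbind(X, designs[[i]])
    qx <- qr(X)
    H <- tcrossprod(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE])
    tr <- sum(H * G)
    ss[i] <- tr - prev_tr
    dfs[i] <- qx$rank - prev_rank
    prev_tr <- tr
    prev_rank <- qx$rank
  }
  list(ss = ss, df = dfs, model_rank = prev_rank, model_tr = prev_tr)
}

#' PERMANOVA with subject-level block permutation
#'
#' Distance-based multivariate analysis of variance: the Gower-centered
#' inner-product matrix of `D` is partitioned by sequential (type-I) sums
#' of squares over the model terms, giving a pseudo-F and R-squared per
#' term. Significance comes from permuting the subject-level covariate
#' values across subjects as whole blocks (sample-level terms such as
#' `site` stay attached to their samples), preserving the repeated-measures
#' structure under the null.
#'
#' @param D distance matrix over samples.
#' @param metadata validated metadata covering the rows of `D`.
#' @param terms character vector of metadata columns, in the order they
#'   should enter the sequential decomposition.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return a `permanova_result`: data frame of terms with `df`, `ss`, `R2`,
#'   `pseudo_F`, `p_value`, plus residual and total rows.
#' @export
permanova_block <- function(D, metadata, terms, n_perm = 1000, seed) {
  stopifnot(all(terms %in% colnames(metadata)))
  metadata <- metadata[match(rownames(D), metadata$sample), , drop = FALSE]
  n <- nrow(D)
  G <- gower_center(D)
  ss_total <- sum(diag(G))

  design_of <- function(md) {
    lapply(terms, function(tm) {
      v <- md[[tm]]
      if (is.character(v)) v <- factor(v)
      stats::model.matrix(~v)[, -1, drop = FALSE]
    })
  }
  compute <- function(md) {
    dec <- seq_ss(G, design_of(md))
    ss_res <- ss_total - dec$model_tr
    df_res <- n - dec$model_rank
    F <- (dec$ss / dec$df) / (ss_res / df_res)
    list(F = F, ss = dec$ss, df = dec$df, ss_res = ss_res, df_res = df_res)
  }
  full <- stats::model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = "+"))),
    data = as.data.frame(lapply(metadata[terms], function(v) {
      if (is.character(v)) factor(v) else v
    })))
  qrf <- qr(full)
  if (qrf$rank < ncol(full)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(colnames(full)[qrf$pivot[-seq_len(qrf$rank)]], collapse = ", "),
         call. = FALSE)
  }
  obs <- compute(metadata)

  subj_level <- vapply(terms, function(tm) {
    all(tapply(metadata[[tm]], metadata$subject, function(v) length(unique(v))) == 1)
  }, logical(1))
  subjects <- unique(metadata$subject)
  subj_rows <- match(subjects, metadata$subject)

  perm_F <- with_seed(seed, {
    sapply(seq_len(n_perm), function(i) {
      perm <- stats::setNames(sample(subjects), subjects)
      md <- metadata
      for (tm in terms[subj_level]) {
        subj_val <- stats::setNames(metadata[[tm]][subj_rows], subjects)
        md[[tm]] <- unname(subj_val[perm[metadata$subject]])
      }
      compute(md)$F
    })
  })
  perm_F <- matrix(perm_F, nrow = length(terms))
  p <- vapply(seq_along(terms), function(i) {
    (1 + sum(perm_F[i, ] >= obs$F[i])) / (1 + n_perm)
  }, numeric(1))

  tab <- data.frame(
    term = c(terms, "residual", "total"),
    df = c(obs$df, obs$df_res, n - 1),
    ss = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    pseudo_F = c(obs$F, NA, NA),
    p_value = c(p, NA, NA),
    row.names = NULL
  )
  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 scheme = "subject-level covariates permuted across subjects"),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("Block-permutation PERMANOVA (", x$scheme, ")\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Principal-coordinates ordination
#'
#' Deterministic classical multidimensional scaling of the Gower-centered
#' distance matrix. Negative eigenvalues (non-Euclidean distances) are
#' reported, not dropped; coordinate columns are truncated (with a warning)
#' when fewer than `k` positive eigenvalues exist.
#'
#' @param D distance matrix.
#' @param k number of requested dimensions.
#' @return list with `coordinates` (samples x <= k), `eigenvalues` (all n),
#'   and `share` (eigenvalue / sum of positive eigenvalues).
#' @export
pcoa_ordination <- function(D, k = 2) {
  stopifnot(k >= 1)
  fit <- withCallingHandlers(
    stats::cmdscale(stats::as.dist(D), k = min(k, nrow(D) - 1), eig = TRUE),
    warning = function(w) {
      # cmdscale's own truncation warning; replaced by ours below
      if (grepl("eigenvalues are > 0", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (k > n_pos) {
    warning(sprintf("only %d positive eigenvalue(s); truncating from k = %d",
                    n_pos, k), call. = FALSE)
  }
  coords <- fit$points[, seq_len(min(k, n_pos)), drop = FALSE]
  rownames(coords) <- rownames(D)
  list(coordinates = coords, eigenvalues = eig,
       share = eig / sum(eig[eig > 0]))
}
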