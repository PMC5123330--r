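test_that("alpha-diversity mixed model reduces to the two-sample t-test", {
  set.seed(21)
  md <- data.frame(sample = paste0("s", 1:16), subject = paste0("p", 1:16),
                   cohort = rep(c("benign", "cancer"), each = 8),
                   site = "uterus")
  alpha <- data.frame(sample = md$sample,
                      shannon = rnorm(16, ifelse(md$cohort == "cancer", 2.2, 1.5)),
                      observed_otus = rpois(16, 40))
  res <- suppressWarnings(alpha_diversity_lme(alpha, md, "shannon"))
  dat <- merge(alpha, md, by = "sample")
  tt <- t.test(shannon ~ cohort, data = dat, var.equal = TRUE)
  expect_equal(res$coefficient, unname(diff(tt$estimate)), tolerance = 1e-6)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-6)
})

test_that("alpha-diversity mixed model recovers a subject-level cohort effect", {
  set.seed(22)
  n_subj <- 20
  md <- data.frame(
    sample = paste0("s", 1:(n_subj * 3)),
    subject = rep(paste0("p", 1:n_subj), each = 3),
    cohort = rep(rep(c("benign", "cancer"), each = n_subj / 2 * 3), 1),
    site = "uterus")
  b <- rep(rnorm(n_subj, sd = 1), each = 3)
  alpha <- data.frame(
    sample = md$sample,
    shannon = 1 + 0.8 * (md$cohort == "cancer") + b + rnorm(n_subj * 3),
    observed_otus = 1)
  res <- alpha_diversity_lme(alpha, md, "shannon")
  expect_equal(res$method, "lme")
  expect_equal(res$df, n_subj - 2)
  expect_lt(abs(res$coefficient - 0.8), 3 * res$std_error)
})

test_that("family choice follows the 25% zero-proportion rule", {
  expect_equal(choose_family(c(rep(1, 19), rep(0, 5))), "overdispersed_poisson")
  expect_equal(choose_family(c(rep(1, 18), rep(0, 6))), "overdispersed_binomial")
  expect_equal(choose_family(rep(3, 10)), "overdispersed_poisson")
  expect_error(choose_family(numeric(0)), "empty")
})

test_that("Benjamini-Hochberg q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(30)
  p <- runif(25)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  perm <- sample(25)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_error(bh_fdr(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("PQL with zero subject variance matches ordinary quasi fits", {
  set.seed(33)
  n <- 60
  cohort <- factor(rep(c("benign", "cancer"), each = n / 2))
  subject <- paste0("p", seq_len(n))  # one sample per subject
  libsize <- exp(rnorm(n, 8, 0.3))
  mu <- exp(log(libsize) - 5 + 0.9 * (cohort == "cancer"))
  y <- rpois(n, mu)
  fit <- fit_overdispersed_glmm(y, "overdispersed_poisson", cohort,
                                subject = subject, libsize = libsize,
                                lambda_fix = 0)
  ref <- glm(y ~ cohort + offset(log(libsize)), family = quasipoisson())
  expect_equal(fit$coefficient, unname(coef(ref)["cohortcancer"]),
               tolerance = 1e-4)
  expect_equal(fit$std_error,
               unname(summary(ref)$coefficients["cohortcancer", 2]),
               tolerance = 1e-3)

  yb <- rbinom(n, 1, plogis(-0.3 + 1.0 * (cohort == "cancer")))
  fitb <- fit_overdispersed_glmm(yb, "overdispersed_binomial", cohort,
                                 subject = subject, libsize = libsize,
                                 lambda_fix = 0)
  refb <- glm(yb ~ cohort + log(libsize), family = quasibinomial())
  expect_equal(fitb$coefficient, unname(coef(refb)["cohortcancer"]),
               tolerance = 1e-4)
})

test_that("PQL agrees with the classical PQL reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(34)
  n_subj <- 20
  reps <- 3
  subject <- rep(paste0("p", 1:n_subj), each = reps)
  cohort <- factor(rep(rep(c("benign", "cancer"), each = n_subj / 2), each = reps))
  site <- factor(rep_len(c("lower", "uterus", "lower"), n_subj * reps))
  libsize <- exp(rnorm(n_subj * reps, 9, 0.4))
  b <- rep(rnorm(n_subj, sd = 0.6), each = reps)
  mu <- exp(log(libsize) - 6 + 1.1 * (cohort == "cancer") +
              0.3 * (site == "uterus") + b)
  y <- rnbinom(n_subj * reps, mu = mu, size = 4)
  fit <- fit_overdispersed_glmm(y, "overdispersed_poisson", cohort,
                                site = site, subject = subject,
                                libsize = libsize)
  dat <- data.frame(y = y, cohort = cohort, site = site, subject = subject,
                    off = log(libsize))
  ref <- suppressMessages(MASS::glmmPQL(
    y ~ cohort + site + offset(off), random = ~ 1 | subject,
    family = quasipoisson(), data = dat, verbose = FALSE))
  tt <- summary(ref)$tTable["cohortcancer", ]
  expect_equal(fit$coefficient, unname(tt["Value"]), tolerance = 0.05)
  expect_equal(fit$std_error, unname(tt["Std.Error"]), tolerance = 0.08)
  expect_equal(fit$df, unname(tt["DF"]))
  expect_true(fit$converged)
})

test_that("Wald df depends only on subjects and between-subject parameters", {
  set.seed(35)
  make_fit <- function(n_subj, reps) {
    subject <- rep(paste0("p", 1:n_subj), each = reps)
    cohort <- factor(rep(rep(c("benign", "cancer"),
                             length.out = n_subj), each = reps))
    site <- factor(rep_len(c("lower", "uterus"), n_subj * reps))
    libsize <- exp(rnorm(n_subj * reps, 8, 0.2))
    y <- rpois(n_subj * reps, exp(log(libsize) - 5))
    fit_overdispersed_glmm(y, "overdispersed_poisson", cohort, site = site,
                           subject = subject, libsize = libsize)
  }
  expect_equal(make_fit(27, 2)$df, 25)  # the study's benign+cancer design
  expect_equal(make_fit(27, 4)$df, 25)  # replicate count does not change df
  expect_equal(make_fit(12, 3)$df, 10)
})

test_that("binomial separation is flagged and capped", {
  set.seed(36)
  n_subj <- 16
  subject <- paste0("p", 1:n_subj)
  cohort <- factor(rep(c("benign", "cancer"), each = n_subj / 2))
  y <- as.numeric(cohort == "cancer")  # perfectly separated
  libsize <- exp(rnorm(n_subj, 8, 0.2))
  expect_warning(
    fit <- fit_overdispersed_glmm(y, "overdispersed_binomial", cohort,
                                  subject = subject, libsize = libsize),
    "separation")
  expect_true(fit$separated)
  expect_lte(abs(fit$coefficient), 15)
})

test_that("the differential-abundance scan recovers its pipeline contract", {
  study <- generate_study(synth_params(
    n_benign = 8, n_hyperplasia = 2, n_cancer = 8,
    sites = c(vagina = 1, uterus = 1), n_taxa = 40,
    enriched_taxa = 3:6, enriched_logfold = 2,
    libsize_log_mean = 8.5, libsize_log_sd = 0.4, seed = 77))
  scan <- differential_abundance_scan(study$table, study$metadata,
                                      level = "otu", scope = "pooled")
  expect_true(all(diff(scan$p_value) >= 0))           # sorted by p
  expect_equal(scan$q_value, bh_fdr(scan$p_value)[order(scan$p_value)])
  expect_true(all(scan$test %in% c("Counts", "Presence/absence")))
  expect_true(all(scan$df == length(unique(
    study$metadata$subject[study$metadata$cohort != "hyperplasia"])) - 2))
  # hyperplasia held out: df reflects benign+cancer subjects only
  scan_ut <- differential_abundance_scan(study$table, study$metadata,
                                         level = "otu", scope = "uterus_only")
  expect_true(nrow(scan_ut) >= 2)
})

test_that("the pooled scope adds exactly one site fixed-effect column", {
  set.seed(38)
  n_subj <- 10
  subject <- rep(paste0("p", 1:n_subj), each = 2)
  cohort <- factor(rep(rep(c("benign", "cancer"), each = n_subj / 2), each = 2))
  site <- factor(rep(c("lower", "uterus"), n_subj))
  libsize <- exp(rnorm(n_subj * 2, 8, 0.2))
  y <- rpois(n_subj * 2, exp(log(libsize) - 5))
  with_site <- fit_overdispersed_glmm(y, "overdispersed_poisson", cohort,
                                      site = site, subject = subject,
                                      libsize = libsize)
  without <- fit_overdispersed_glmm(y, "overdispersed_poisson", cohort,
                                    subject = subject, libsize = libsize)
  expect_equal(length(with_site$coefficients),
               length(without$coefficients) + 1)
  expect_equal(with_site$df, without$df)  # site is within-subject
})
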