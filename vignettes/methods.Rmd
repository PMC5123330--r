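---
title: "Methods: repeated-measures microbiome inference across the reproductive tract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeated-measures microbiome inference across the reproductive tract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gyntract)
```

## The inferential problem

Multi-site reproductive-tract microbiome studies sample each patient at
several body sites (vagina, cervix, uterus, Fallopian tubes, ovaries) and
compare a handful of clinical cohorts — here benign gynecologic
conditions, endometrial hyperplasia, and endometrial cancer. Two features
dominate the statistics. First, samples from one subject are strongly
correlated: a patient's vaginal community predicts her uterine community
far better than another patient's does (a host-selection effect).
Treating samples as independent would badly inflate significance, so
every test in this package permutes or models at the *subject* level.
Second, sequencing depth varies by more than an order of magnitude across
samples, so library size enters every abundance model explicitly and all
distance calculations run on rarefied counts.

## Diversity summaries

Alpha diversity uses observed OTU richness (species richness) and the
Shannon index $H = -\sum_t p_t \ln p_t$ in nats (the log base is a
declared convention; it rescales $H$ but no test statistic). The cohort
contrast on an alpha metric is a linear mixed model with a random
intercept per subject, fitted by REML (`nlme::lme`), with a Wald test on
the cohort coefficient. When the mixed fit is singular — for example one
sample per subject — the model falls back to ordinary least squares,
which in the one-sample-per-subject case is exactly the equal-variance
t-test (a tested reduction).

Beta diversity offers three views: Bray-Curtis on counts, unweighted
UniFrac (community membership weighted by shared phylogenetic branch
length), and weighted UniFrac in the normalized form
$d = \sum_b l_b |p_A(b) - p_B(b)| / \sum_b l_b (p_A(b) + p_B(b))$,
which keeps all three distances on $[0,1]$. The normalized weighted
variant is a declared choice (the raw variant is not offered); both
UniFrac variants are validated branch-by-branch against a naive recursive
reference to $10^{-12}$. Trees without a root are midpoint-rooted before
branch enumeration, since UniFrac is root-sensitive. Taxa missing from
the tree are dropped with a warning (`reconcile_with_tree`), never
silently. Rarefaction subsamples without replacement (hypergeometric), to
a configurable depth defaulting to the minimum library size, with a
mandatory seed; samples below the depth are dropped with a warning.

## Block permutation

The exchangeable unit is the subject. For the organ-correlation test of
sites $A$ and $B$ the statistic is

$$T = \underbrace{\text{mean}_{i \ne j}\, d(a_i, b_j)}_{\text{between
subjects}} - \underbrace{\text{mean}_i\, d(a_i, b_i)}_{\text{within
subject}},$$

with all replicate pairs entering the means unweighted. The null permutes
subject labels of the site-$B$ sample blocks only: permuting one member
of each pairing is equivalent in distribution to permuting both strata
independently, and it gives a permutation group of size $S!$ so
exhaustive enumeration (used automatically whenever the group is no
larger than the requested number of permutations) is feasible for small
designs. Sampled p-values use the add-one convention
$p = (1 + \#\{T^* \ge T\})/(1 + B)$, so $p \ge 1/(B+1)$ and a reported
$p = 0.001$ at $B = 999$ means "no permutation reached the observed
statistic". The hypotheses as posed are directional ("greater"), so
one-sided is the default with a two-sided option on $|T|$.

The shared-taxon test plugs the one-dimensional presence/absence distance
of a single taxon into the same machinery. If a taxon is present in every
sample — or absent from every sample — at either site, every row (or
column) of the cross-site distance block is identical, the statistic is
permutation-invariant, and the test refuses to run (degenerate-input
error) rather than return a meaningless $p = 1$.

The cohort distance contrast $T = \bar d(A,B) - \bar d(A,C)$ permutes the
$B$/$C$ cohort labels over the $B \cup C$ subjects as whole blocks,
holding $A$ fixed; swapping $B$ and $C$ negates the statistic exactly.

PERMANOVA partitions the Gower-centred inner-product matrix
$G = -\tfrac12 J D^{(2)} J$ by sequential (type-I) projections of the
model terms, giving per-term pseudo-$F$ and $R^2$ that sum to one with
the residual. The null permutes *subject-level* covariate values across
subjects; sample-level terms such as site stay attached to their samples.
The pseudo-$F$ reduces exactly to the classical one-way ANOVA $F$ when
$D$ is Euclidean distance on one-dimensional data (a tested oracle, also
cross-checked against vegan's implementation).

## Differential abundance

The scan aggregates to the requested rank, restricts to the benign and
cancer cohorts (hyperplasia is a described precursor state and is held
out of the primary contrast, to be examined descriptively), and then per
taxon:

1. prevalence filter: taxa in fewer than 20% of samples are dropped
   (exactly 20% is kept — the rule is "less than");
2. winsorize at the 97% upper quantile, nearest-rank (ceiling) order
   statistic — this caps outlier leverage and is a no-op for 0/1 data;
3. family rule: overdispersed Poisson on counts when the zero proportion
   is below 25%, otherwise overdispersed binomial on presence/absence;
4. PQL fit with a per-subject random intercept; in the pooled scope the
   sampling site (uterus vs lower tract) is a fixed covariate;
5. Benjamini-Hochberg q-values over the scanned taxa.

Library size is the *unrarefied* sample total: rarefaction is a
distance-space normalisation and never feeds the models, where depth is
handled by the offset (Poisson) or covariate (binomial) instead.

The PQL fitter is the package's own: working responses and weights are
refreshed from the current linear predictor and a weighted linear mixed
model $z = X\beta + Zb + e$, $\mathrm{Var}(e) = \phi\,W^{-1}$,
$\mathrm{Var}(b) = \sigma_b^2 I$ is re-solved by REML, profiling the
single variance ratio $\lambda = \sigma_b^2/\phi$ by one-dimensional
optimisation of the restricted likelihood (with an explicit comparison
against the $\lambda = 0$ boundary). Because $Z$ is a subject indicator
matrix, the Woodbury identity reduces every solve to per-subject sums, so
a fit is $O(n)$ per likelihood evaluation. Iteration stops when the
linear predictor moves less than $10^{-6}$ (at most 50 iterations; the
result carries a `converged` flag rather than throwing). Apparent
complete separation in a binomial fit is flagged and the coefficient
capped at $|15|$ with a warning. The dispersion $\phi$ is the REML
residual variance of the working model, equivalent to a weighted Pearson
estimate.

Wald tests use $t = \beta/\mathrm{SE}$ with
$\mathrm{df} = n_{\text{subjects}} - n_{\text{between-subject
parameters}}$: the cohort contrast is a between-subject comparison, so
within-subject terms (site, library size) do not spend subject-level
degrees of freedom, and replicate counts never change df. For the
27-subject benign+cancer design with intercept and cohort this gives
df = 25 regardless of how many samples each subject contributes.

## Marker panel

A patient is "positive" for a marker organism if any replicate sample at
the chosen sites contains it — the aggregation matching
detected/undetected language for multi-swab collections. The combined
rule is *both markers present, or either marker present together with
high vaginal pH*; a patient whose outcome hinges on an unknown pH is
indeterminate and excluded from that rule's denominators (the
evaluable-denominator convention), which is what makes 100% sensitivity
over 14 evaluable cancer patients reproducible from the printed panel.
ROC curves score each patient by the median of replicate relative
abundances and sweep unique scores as thresholds; the trapezoid AUC
equals the rank-sum probability $U/(n_1 n_2)$ with ties counted one half
(a tested identity). Demographic contingency tables use the two-sided
Fisher exact test with unknown categories excluded — the convention that
reproduces the printed p-values to four decimals.

## The synthetic-study generator

`generate_study` emulates the design the analysis assumes, hierarchically:

* subjects in three cohorts (defaults 10 benign / 4 hyperplasia / 17
  cancer), each sampled at body sites with probabilities matching the
  reported per-site amplification success (vagina/cervix 0.94, uterus
  0.87, Fallopian 0.50, ovary 0.61);
* per-taxon baseline log abundances $\sim N(0, 1.5)$; per-subject,
  per-taxon intercepts $\sim N(0, \sigma_{\text{subj}})$ (host
  selection, default SD 1); per-site shifts $\sim N(0, 0.5)$, with the
  lower-tract sites (vagina/cervix) sharing one shift because the
  analysis pools them as a single stratum;
* twelve enriched taxa with a $+1.5$ log-fold cohort effect in cancer
  (hyperplasia gets a configurable fraction of it, default 1.0 — the
  precursor state sits near the cancer arm). Enriched taxa draw their
  baselines from a tight low-abundance distribution ($N(-1.5, 0.5)$ on
  the log scale): the organisms they emulate are minority community
  members, and keeping their baseline share at a few percent of the
  composition prevents their enrichment from mechanically depleting the
  relative abundance of every other taxon — a compositional artifact
  that would otherwise masquerade as false discoveries;
* counts are gamma-Poisson: relative abundances are normalised, scaled
  by a log-normal library size (defaults meanlog 11.8, sdlog 0.9,
  spanning roughly $2\times10^4$–$8\times10^5$ reads), and multiplied by
  a per-count gamma with constant shape $1/\text{dispersion}$
  (negative-binomial-type noise);
* the two marker taxa are injected as presence/absence on top of the
  compositional background, per-cohort detection probabilities
  defaulting to the printed panel margins (e.g. 14/15 for marker A in
  cancer), together with a per-cohort high-pH probability — so panel
  evaluation is decoupled from the abundance model;
* subject-level demographics (age, BMI, menopausal status, hypertension)
  are drawn per cohort at plausible clinical rates.

Everything is driven by one seed and is bit-reproducible.

What the generator does *not* emulate: sequencing reads, chimeras, primer
or extraction bias, contamination, taxonomic mis-assignment, or real
phylogenetic signal in the abundance structure (the tree is random with
exponential branch lengths, mean 0.1). Passing tests on this generator
therefore validate the *statistical machinery* under the assumed
hierarchical model, not robustness to those artefacts.

## Validation design and problem sizes

The suite validates each layer at sizes chosen to keep the full run in a
few minutes:

* *Oracles*: exhaustive permutation enumeration for 4–5-subject designs;
  ANOVA-F equivalence; naive UniFrac reference; hypergeometric moments
  for rarefaction; U-statistic identity for AUC; full hypergeometric
  enumeration for Fisher tests.
* *Calibration*: 200 null replicates per test, 99 permutations each,
  12-subject studies for the continuous-distance tests. The shared-taxon
  statistic lives on 0/1 presence distances, so its permutation
  distribution is much more discrete: calibration uses 24 subjects and
  shallow (~700-read) libraries so presence actually varies; at smaller
  sizes the test is conservative (attained size ~0.01), never
  anti-conservative.
* *Parameter recovery*: 500 replicates at the 27-subject design
  (10 + 17, three samples each), truth 1.1 log-fold, overdispersion in
  the quasi-Poisson form the model assumes ($\mathrm{Var} = \phi\mu$,
  gamma shape $\mu/(\phi-1)$, $\phi = 2$). Under this correctly
  specified variance the coefficient is recovered without detectable
  bias and 95% Wald-t intervals cover at ~0.96. A known limitation,
  documented deliberately: under *quadratic*-variance (NB2) noise —
  constant gamma shape, as the generator's count model uses — PQL shows
  a small systematic attenuation of the cohort coefficient (~3% at this
  design), and the classical reference implementation shows the
  identical attenuation; it is a property of the approximation, not of
  this implementation.
* *End-to-end recovery*: twenty 27-subject studies with 12 enriched taxa
  among 100; the pooled OTU-level scan at q < 0.10 recovers a median of
  8–9 of the 12 with a median of ~1 false positive.

## Numerical conventions and degenerate inputs

Nearest-rank (ceiling) quantiles for winsorization; "less than" filters
keep boundary values; add-one permutation p-values; REML throughout the
mixed solves; `optimize` on $\log\lambda \in [-14, 10]$ with an explicit
zero-variance boundary check; all-zero samples are errors for Shannon and
for every distance; empty permutation strata and single-subject designs
are errors, not warnings. Every stochastic stage takes an explicit seed,
the pipeline derives per-stage child seeds from one run seed, and the run
manifest records them.

## Known limitations

PQL is an approximate likelihood: besides the NB2 attenuation above, its
dispersion estimate is noisy for sparse binomial taxa, and Wald t with
the subject-level df convention is conservative for within-subject
contrasts. The compositional coupling between strongly enriched taxa and
the rest of the community is only partially addressed by keeping enriched
taxa rare; no log-ratio transform is offered because the modelled
workflow uses none. The ROC score combination for the two-marker figure
(maximum of the two relative abundances) is one reasonable choice among
several the source material leaves unspecified.
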