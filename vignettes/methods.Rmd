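---
title: "Quantifying airway microbial community turnover: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying airway microbial community turnover: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwayturnover)
```

This vignette is the package's account of its statistical methods: the
turnover statistics, the longitudinal models, the synthetic cohort
generator that stands in for real sequencing data, and the numerical and
design decisions behind them.

## Setting

The data are serial tracheal aspirates from mechanically ventilated preterm
infants, profiled by 16S amplicon sequencing into a taxon-by-sample count
table, with per-sample metadata (subject, day of age at collection, outcome
group — BPD severity graded mild/moderate/severe — and optionally total
bacterial load from qPCR in log10 copies/reaction). Subjects contribute
between one and four samples; only subjects with at least two enter the
longitudinal analyses. Sequencing depth varies widely between samples
(thousands to hundreds of thousands of reads), so all statistics are either
computed on within-sample proportions or condition on depth explicitly.

## Turnover statistics

### Multi-sample Shannon beta diversity and the effective number of communities

For subject $i$ let $c_{ijk}$ be the count of taxon $k$ in sample $j$, with
`+` denoting summation over an index. With sample weights $w_j =
c_{ij+}/c_{i++}$, within-sample compositions $q_{jk} = c_{ijk}/c_{ij+}$ and
the subject's pooled composition $\bar q_k = c_{i+k}/c_{i++}$,

$$H_{\beta,i} \;=\; \sum_j w_j \sum_k q_{jk}
  \ln\frac{q_{jk}}{\bar q_k}, \qquad 0\ln 0 \equiv 0,$$

in nats. This is the depth-weighted mean Kullback–Leibler divergence of
each sample from the pooled community — equivalently the mutual information
between the sample label and the taxon label, which is how the test suite
verifies it by brute force. Its exponential $\exp(H_{\beta,i})$ is a Hill
number: the *effective number of communities* among the subject's samples.
It equals 1 exactly when all samples share one composition and reaches the
number of samples $j_i$ when the samples are disjoint with equal depths.
Because the attainable maximum depends on $j_i$, subjects with different
sample counts are compared after the normalization

$$H_{n,i} = \frac{\exp(H_{\beta,i}) - 1}{j_i - 1} \in [0, 1],$$

which is undefined (reported as missing, never 0) for single-sample
subjects.

A note on the denominator: the pooled composition is the *subject's* pooled
distribution $c_{i+k}/c_{i++}$, not the cohort-wide one. Only this choice
gives the 1-to-$j_i$ range that makes the Hill number interpretable as an
effective number of that subject's communities; a cohort-wide denominator
would mix between-subject differences into a within-subject statistic.

### Pairwise Morisita–Horn similarity

For two samples with proportions $p$ and $q$,

$$\mathrm{MH}(p, q) = \frac{2\sum_k p_k q_k}{\sum_k p_k^2 + \sum_k q_k^2}
  \in [0, 1],$$

1 iff the compositions are proportional and 0 iff their supports are
disjoint. It is computed on proportions, so it is invariant to sequencing
depth; counts are accepted as input and normalized internally. Every
within-subject pair is reported along with the day interval separating the
two collections, since similarity decays with elapsed time. Lower values
mean more turnover. No metric property is claimed (MH does not satisfy the
triangle inequality); it is used purely as a bounded similarity.

## Group comparisons with repeated measures: log-normal GEE

Morisita–Horn values (several pairs per subject) and bacterial load
(several samples per subject) are compared across outcome groups by
generalized estimating equations on the log scale: a marginal model
$\log y = X\beta$ with subjects as clusters, an exchangeable working
correlation estimated by moments, and cluster-robust (sandwich) standard
errors. The point estimates are consistent even if the working correlation
is wrong; the sandwich variance protects the inference. When a time
covariate is included (load analyses use day/7, so the slope is per week),
its coefficient is reported in the outcome's own log units; load arrives
already log10-transformed and is used as-is (`values_are_log = TRUE`), so
its slope reads directly in log10 copies/reaction per week. Pairwise group
contrasts are Wald tests, unadjusted for multiplicity by default (an
optional Holm adjustment is available). When every cluster has a single
observation the fit reduces to OLS with heteroskedasticity-robust errors
and says so.

The estimating equations are solved in-package (iterated GLS with a moment
update of the common correlation); the degenerate single-observation case
is cross-checked in the tests against `lm()` plus `sandwich::vcovCL()`.

## Taxon trajectories: beta-binomial join-point mixed model

The relative abundance of a focal taxon (count $y_{ij}$ out of depth
$n_{ij}$) over age $t_{ij}$ is modeled as

$$y_{ij} \mid b_i \sim \mathrm{BetaBin}(n_{ij}, \mu_{ij}, \phi_g), \qquad
\mathrm{logit}(\mu_{ij}) = \beta_{0g} + \beta_{1g} t_{ij} +
\beta_{2g} (t_{ij} - \kappa)_+ + b_i, \qquad b_i \sim N(0, \sigma_b^2),$$

with one intercept, pre-knot slope and slope *change* per outcome group
$g$, and group-specific dispersions $\phi_g$. The beta-binomial is
parameterized by its mean and a single positive dispersion with beta shapes
$(\mu/\phi, (1-\mu)/\phi)$, so $\phi \to 0$ recovers the binomial and each
group's extra-binomial variation is one interpretable scalar. The
truncated-line basis $(t - \kappa)_+$ makes the trend continuous at the
knot by construction, with $\beta_{2g}$ the change in slope there. The
subject random intercept lets individual infants sit far from their group's
average curve, which the data demand — single-genus dominance makes
between-subject variation much larger than binomial.

**Estimation.** The marginal likelihood integrates $b_i$ out by *adaptive*
Gauss–Hermite quadrature: per subject, the integrand's mode is found by
damped Newton iterations using analytic first and second derivatives of the
beta-binomial log density with respect to the logit mean, and the rule is
recentred and rescaled there. The default is 21 nodes: verification against
dense trapezoid integration showed 15 nodes leaves up to ~2.6e-6 relative
error in the marginal likelihood for random-intercept SDs around 1–1.5,
while 21 nodes stays below ~5e-8 at modest extra cost, comfortably inside
the 1e-6 agreement the test suite enforces. The optimizer (`nlminb`) gets
an analytic gradient via the Fisher identity — the score is the posterior
expectation, over the quadrature nodes, of the complete-data score — and
starts from a binomial GLM fit of the fixed effects; if it fails to
converge, up to three jittered restarts are attempted and the best
objective kept. Standard errors come from the observed information,
obtained by central differences of the analytic score. Dispersions and the
random-effect SD are optimized on the log scale with box constraints.

**Inference.** Group contrasts of the mean relative abundance at requested
days (day 14 by default) are reported two ways: on the logit scale, where
the contrast is an exact linear combination of coefficients, and on the RA
scale, where the population-average curve $E_b[\mathrm{logit}^{-1}(\eta_g(t)
+ b)]$ is integrated by quadrature and the delta method supplies the
standard error. Both carry Wald p-values. Fitted population curves are
exported on a half-day grid.

**Knot placement.** The default knot is day 10. Alternatively
`select_knot()` follows the classical device of fitting a cubic polynomial
in day to the empirical logit of the pooled per-day relative abundance
(weighted by per-day depth), setting its first derivative to zero, and
solving the quadratic: the real root inside the observed day range is the
knot. With two in-range roots the one nearer the depth-weighted median day
is chosen and both are reported; with none, the default is used with a
warning. Pooling is across groups (per-group knots are available by calling
the function per group); an empirical-logit continuity correction
$(y+0.5)/(n+1)$ keeps days with zero or saturated counts finite.

**Model criticism.** `zero_inflation_check()` compares observed zero
fractions per group-by-day bin against the fitted model's marginal zero
probability (random intercept integrated out), flagging bins beyond $z = 2$
standard errors. Because a *refit* can absorb even structural zeros into
the trend or the dispersion — the beta-binomial is flexible enough to fake
zero inflation with a U-shaped beta — the check accepts external data, and
perturbations show up most clearly when a clean-data fit is checked against
perturbed data. Empty bins are skipped and reported as such.

## The synthetic cohort generator

`generate_cohort()` produces count tables with the statistical structure
the analyses assume, so that every stage of the pipeline — and its
calibration — can be exercised without any sequencing data. Its defaults
encode the sampling design the package targets:

* **Design**: three outcome groups of 25/30/39 subjects; visits at
  enrollment (day 3) and target days 7/14/21, each jittered uniformly by up
  to ±2 days (±48 h). The enrollment visit is always collected; each later
  visit is missed with probability 0.6, with at least one retained, which
  puts samples-per-subject in 2–4 with median 2 — the observed shape of the
  emulated cohort (94 subjects, ~233 samples).
* **Depth**: log-uniform on [6,451, 196,691]. Only the observed range of
  the emulated study is known, not the distribution's shape; log-uniform
  spreads mass evenly across orders of magnitude.
* **Targets**: *Staphylococcus* and *Ureaplasma* carry explicit join-point
  logit trajectories (knot day 10) with per-group parameters, a per-taxon
  subject random intercept (SD 1.0), and beta-binomial thinning with
  group-specific dispersion — exactly the fitted model's data-generating
  process, which makes parameter recovery well-posed. Default trajectories
  give the mild group a steeper early *Staphylococcus* rise peaking higher
  by day 14, and the severe group a higher initial *Ureaplasma* level,
  with more overdispersion in the severer groups.
* **Background**: the remaining taxa (16 of 18 by default, named for
  common NICU airway genera) evolve as a Dirichlet random walk
  $\pi_{t+1} \sim \mathrm{Dirichlet}(c_g \pi_t + 0.01)$ with group-specific
  concentration $c_g$ (default 40/15/6 for mild/moderate/severe): lower
  concentration means larger steps, hence more within-subject turnover in
  the severer groups. Background counts are multinomial given the depth
  left after the targets.
* **Load**: $3.8 + 1.05\,(\mathrm{day}/7) + N(0, 0.6^2)$ log10
  copies/reaction, i.e. a median around 4.8–5 at day 7 rising by about one
  log per week.
* **Determinism**: one integer seed; the same seed reproduces the cohort
  bit-identically (the caller's RNG state is saved and restored).

`generate_null_cohort()` forces every group-specific parameter equal to the
first group's value, giving label-free cohorts for type-I-error studies. A
truth record (every generator knob plus each subject's latent intercepts)
is serialized as a flat key/value text file and round-trips.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: taxonomic misclassification, chimeras and
other upstream sequence-processing artifacts; antibiotic exposure and other
time-varying clinical covariates; informative missingness (visits are
missed at random, whereas sicker infants may be sampled more or less
often); correlation between the two target taxa beyond competition for
depth; and any relationship between depth and composition. Calibration
results (coverage, type-I error) are statements about data of this
structure, not about the emulated study's raw data.

## Numerical choices and edge cases

* Shannon alpha diversity defaults to log base 2 (the convention of the
  diversity software typically used on amplicon panels); the beta
  decomposition is in nats, where the Hill conversion `exp()` applies.
  Pielou evenness $H/\log S$ is undefined for fewer than two observed taxa
  and returns `NA`, never 0.
* Rarefied Good's coverage subsamples without replacement (exact
  multivariate hypergeometric via sequential conditionals), 100 draws by
  default, seeded; samples shallower than the rarefaction depth are
  excluded as not rarefiable, never imputed.
* `0 \ln 0 = 0` throughout the diversity computations; a tiny negative
  round-off in $H_\beta$ is clamped to 0 so Hill numbers never dip below 1.
* Duplicate (subject, day) pairs are an error, not averaged: the turnover
  statistics assume distinct time points.
* Rare-taxon collapsing (`< 1%` relative abundance in *every* sample)
  conserves per-sample totals exactly in integer arithmetic and appends a
  flagged `rare` pseudo-taxon that diversity statistics treat as ordinary;
  when nothing qualifies, no empty column is added.
* The cross-sectional window is [5, 9] days with the sample closest to day
  7 selected per subject; equidistant ties go to the earlier day — a
  deterministic rule where the emulated design leaves the choice open.
* GEE: the exchangeable correlation estimate is clamped to its valid range;
  non-positive outcome values are an error naming the record (the log-normal
  model is undefined there).

## Problem sizes in the test suite

The simulation studies in the tests use sizes chosen to bound Monte-Carlo
error while staying desk-scale: parameter recovery uses 100 cohorts of 150
subjects (Monte-Carlo SE of the mean slope estimate ≈ 0.004, small against
the 10%-of-truth bias bound); type-I error uses 200 null cohorts of the
default 94-subject design (binomial SE ≈ 1.5 points at the 5% level);
oracle-equivalence checks run on 1,000 random fixtures; drift monotonicity
uses 40 subjects per drift level.

## Known limitations

* The join-point model supports exactly one knot and a random intercept
  only — no random slopes, no spline bases, no Bayesian fitting. This
  matches its target use (a single early-life inflection) but will not
  capture multi-phase trajectories.
* Between-subject beta diversity (ordination across infants) is out of
  scope; the turnover statistics are strictly within-subject.
* The GEE assumes groups are constant within subject, as outcome severity
  is; it is not a general longitudinal regression tool.
* Wald inference relies on asymptotics in the number of subjects; with few
  clusters the sandwich variance is known to be liberal, which is why the
  type-I-error suite checks the realized size against a band rather than
  assuming exact nominality.
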