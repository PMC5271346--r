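# airwayturnover

Longitudinal turnover analysis of the lower-airway microbiome in
mechanically ventilated preterm infants.

## The problem

Preterm infants who need mechanical ventilation acquire bacterial
communities in the lower airway within days of birth, and the way those
communities *change* over the first weeks of life may carry more prognostic
information about bronchopulmonary dysplasia (BPD, graded
mild/moderate/severe) than any single snapshot. Quantifying that change is
awkward with standard ecology tooling: subjects contribute different numbers
of serial tracheal aspirates (2–4, typically 2), sequencing depth varies by
a factor of ~30 between samples, and taxon abundances are heavily
overdispersed counts dominated by one or two genera (*Staphylococcus*,
*Ureaplasma*).

This package implements the statistical machinery for that setting, for
anyone analysing serial marker-gene count tables grouped by subject:

* **Multi-sample Shannon beta diversity as a Hill number.** For subject *i*
  with counts *c<sub>ijk</sub>* (sample *j*, taxon *k*; `+` denoting
  summation over an index),

  *H<sub>β,i</sub>* = Σ<sub>j</sub> (c<sub>ij+</sub>/c<sub>i++</sub>)
  Σ<sub>k</sub> (c<sub>ijk</sub>/c<sub>ij+</sub>)
  ln[(c<sub>ijk</sub>/c<sub>ij+</sub>) / (c<sub>i+k</sub>/c<sub>i++</sub>)],

  the abundance-weighted divergence of each sample from the subject's pooled
  composition (equivalently, the mutual information between sample label and
  taxon label). Its exponential exp(*H<sub>β,i</sub>*) is the **effective
  number of communities** the subject's samples represent, ranging from 1
  (identical samples) to the number of samples *j<sub>i</sub>* (fully
  disjoint, equal depth), and (exp(*H<sub>β,i</sub>*) − 1)/(*j<sub>i</sub>* −
  1) rescales it to [0, 1] for comparison across subjects with different
  sample counts.
* **Pairwise Morisita-Horn similarity** within subjects (depth-invariant;
  lower = more turnover), compared across outcome groups with a log-normal
  **GEE** (exchangeable working correlation, sandwich SEs) that accounts for
  repeated pairs per subject.
* **A beta-binomial join-point mixed model** for a taxon's relative
  abundance over postnatal age: logit(μ) piecewise-linear with a slope
  change at a knot (day 10 by default, or selected from the data via a cubic
  fit whose derivative is solved for its root), per-group dispersions, and a
  subject random intercept integrated out by adaptive Gauss–Hermite
  quadrature.
* **A synthetic cohort generator** that emulates the sampling design this
  machinery targets (serial aspirates at ~3/7/14/21 days ± 48 h, 25/30/39
  subjects across three severity groups, depths 6,451–196,691, group-specific
  community drift and taxon trajectories), so the whole pipeline is testable
  without sequence data.

## Worked example

Simulate a cohort with the default design and run the longitudinal
analysis:

```r
library(airwayturnover)

coh <- generate_cohort(cohort_config(seed = 2))
res <- run_longitudinal(coh$table, coh$metadata)

tapply(res$turnover$subjects$hill_normalized,
       res$turnover$subjects$group, median)
#>       mild   moderate     severe
#> 0.03569451 0.07736331 0.13012259

res$gee_mh$contrasts
#>   group_a  group_b estimate      se     z        p
#>      mild moderate  0.13455 0.07128 1.888 0.059072
#>      mild   severe  0.19464 0.05938 3.278 0.001046
#>  moderate   severe  0.06009 0.05606 1.072 0.283781

res$gee_load$time_slope
#>  term estimate      se          p
#>  time    1.043 0.03697 5.198e-175
```

The median normalized Hill number rises from mild to severe — subjects in
the severe group effectively harbour more distinct communities across their
serial samples, i.e. more turnover, exactly the gradient this generator
encodes through its group-specific drift. The GEE finds mild-group
Morisita-Horn similarity significantly higher than severe (log-scale
difference 0.195, p ≈ 0.001; higher similarity = less turnover), and
recovers the generated bacterial-load trend of +1.05 log10 copies/reaction
per week (estimate 1.043 ± 0.037).

`run_cross_sectional()` performs the day-7 snapshot analysis (one sample
per subject within days 5–9, alpha diversity/evenness/load with
Kruskal-Wallis tests), and `fit_betabin_joinpoint()` models individual
genera over age; see the methods vignette (`vignettes/methods.Rmd`) for the
models, their assumptions, and the design of the generator.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/airway_turnover.R all --outdir out --seed 2
```

writes the simulated cohort plus stamped CSVs (`turnover_subject.csv`,
`gee_mh.csv`, `joinpoint_<taxon>.csv`, ...) and a consolidated
`report.txt`.

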