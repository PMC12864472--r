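---
title: "Along-tract statistics for tractometry: models, permutation inference and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract statistics for tractometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractstats)
```

## The setting

Automated fiber quantification (AFQ) pipelines segment major white
matter bundles from diffusion MRI and sample tensor-derived scalar
metrics — fractional anisotropy (FA), mean, radial and axial
diffusivity (MD, RD, AD) — at equidistant nodes along each bundle's
core, 100 nodes per tract by convention. `tractstats` implements the
statistics that are typically run downstream of such a pipeline in a
two-group developmental cohort (typically developing children, TD,
versus children with autism spectrum disorder, ASD): hemispheric
lateralization of each metric, covariate-adjusted group comparisons at
the whole-tract and single-node level, and brain–behavior association
models. The package never touches raw imagery; its input is the
long-format profile export (one row per subject × tract × node) plus a
demographics/behavior table.

## Models

**Lateralization.** For a bilateral pair the lateralization index of a
metric is LI = (R − L)/(R + L), computed on the tract-wise means (mean
over the node grid per hemisphere first, then LI). Positive LI means
larger values on the right. Three analyses are built on it:

* one-sample t tests of mean LI against zero, per group, pair and
  metric;
* the between-group model LI ~ group + age + sex;
* the behavior models LI ~ score + age + sex within each group and
  LI ~ group × score + age + sex for the interaction.

A detail that matters for interpretation: for FA a significantly
*positive* t means rightward lateralization, while for the diffusivity
metrics (MD, RD, AD) a significantly *negative* t means rightward
lateralization, because larger diffusivity loosely reads as lower
microstructural organization. `li_one_sample()` assigns its
`direction` label with exactly this rule.

**Group comparisons.** Each metric is compared between groups with
metric ~ group + age + sex, at the tract level (response = mean over
the node grid) and at the node level (one fit per node). Group is
coded TD = 0 / ASD = 1, sex M = 0 / F = 1, so a positive group
coefficient means ASD > TD in metric units.

**Associations.** Behavior scores (developmental language quotients;
ADOS symptom severity within ASD) enter as
metric ~ score + age + sex within a group, plus the group × score
interaction model across groups. Effect sizes are reported as squared
partial correlations of metric and score after both are residualized
on age and sex.

## Permutation inference

Parametric p values are reported alongside permutation p values; the
multiple-comparison machinery is entirely permutation-based.

* **Scheme.** For any model with covariates the default is
  Freedman–Lane residual permutation: residuals of the reduced model
  (the design without the tested term) are permuted, added back to the
  reduced-model fit, and the full model refit. Plain label permutation
  of the tested column is available as an option. With no covariates
  beyond the intercept the two schemes generate the same exhaustive
  null set, which the test suite verifies by enumeration at n = 5.
  For one-sample LI tests the null is generated by random sign flips
  of the subject LIs, the standard permutation analogue under a null
  symmetric about zero.
* **Family-wise correction.** Within a correction family one shared
  permutation stream drives every member, and corrected p values come
  from the max-statistic rule: the corrected p of test *i* is the
  add-one proportion of permutations whose maximum |t| over the family
  reaches |t_i|. Default families mirror how results are reported:
  the 8 tracts within a metric (tract-wise), the 4 tract pairs within
  a (group, metric) for LI, the 100 nodes within a (tract, metric)
  for point-wise tests, and the discovered clusters within a
  (metric, score, scope) for cluster-level associations. The family is
  configuration, not dogma — the published analyses do not state their
  exact family, so it is kept explicit and adjustable.
* **Estimator.** All permutation p values use the add-one rule
  p = (1 + #{|null| ≥ |obs|})/(B + 1), two-sided on absolute values,
  which is guaranteed valid (p ∈ (0, 1]). The default B is 5000.
* **Cluster-extent criterion.** A point-wise group difference is only
  reported when corrected-significant nodes form a run of *more than
  three* consecutive nodes, i.e. at least 4 (`min_cluster = 4`). All
  node intervals reported in the source study have length ≥ 4,
  consistent with this reading. Correction happens at the node level
  *before* cluster formation and no additional cluster-mass inference
  is applied; `find_clusters()` simply extracts the maximal qualifying
  runs, reported inclusively in the input node labels.

## The synthetic cohort generator

Because the motivating cohort's imaging data cannot ship with the
package, every analysis is exercised on synthetic cohorts whose
defaults encode the study conditions: 22 TD and 28 ASD children (17/5
and 24/4 male/female), ages drawn from truncated normals matching the
published group means, SDs and ranges, and behavior scores (ABC, six
GDS domains, ADOS SA/RRB with total = SA + RRB) likewise truncated to
the published supports.

Profiles are generated on two latent scales: log axial diffusivity
(baseline ≈ 1.3 × 10⁻³ mm²/s with gentle tract-specific undulation)
and the logit of the radial/axial ratio r (baseline r ≈ 0.42). From a
latent pair the four metrics follow as AD, RD = r·AD,
MD = (AD + 2 RD)/3 and FA = (1 − r)/√(1 + 2 r²) — the prolate-tensor
closed form — so FA ∈ (0, 1), positivity and RD ≤ AD hold by
construction and the metrics carry realistic mutual correlations.
Each latent gets a subject random effect (shared between the two
hemispheres of a pair — the same child — so that laterality noise is
not inflated), an age slope, a sex offset, and node noise drawn from a
stationary squared-exponential kernel with correlation length 10
nodes. Smooth node noise matters: real tract profiles are smooth, and
white node noise would make the consecutive-node criterion
unrealistically conservative.

On top of this null structure the generator injects:

* **Asymmetry:** per (group, pair, metric) a subject-level LI target
  drawn from N(μ, σ) with μ, σ defaulting to the published per-group
  LI table; the right profile is scaled by (1 + A), the left by
  (1 − A), so the LI of tract means recovers A in expectation.
* **Localized group effects:** additive shifts on ASD profiles over
  stated node intervals. Amplitudes may be given in metric units or
  standardized against the covariate-adjusted between-subject node SD,
  which the generator obtains by the delta method on the latent
  scales. Effects decay outside the interval with a half-cosine taper
  over 2 nodes, reflecting that real effects bleed smoothly past any
  nominal boundary. Defaults place standardized amplitude 1 on the
  node intervals reported in the source study (FA elevations in left
  AF 38–42, left SLF 82–90, left/right IFOF, right SLF; AD shifts in
  left SLF, right AF/ILF/SLF).
* **Behavior couplings:** within-group shifts
  slope × (score − mean score) added to a tract's metric, defaulting
  to the published within-ASD slopes (e.g. FA on language −0.001 per
  quotient point in the left arcuate).

Asymmetry scalings and interval effects are applied on the *metric*
scale after the latent derivation. This keeps each injected truth
exactly recoverable by the analysis that targets it, at the price that
the MD = (AD + 2 RD)/3 identity holds only approximately (to ~10⁻⁵ in
absolute terms) after metric-targeted perturbations; a final
projection smoothly squashes FA into (0, 1) (identity on [0.02, 0.98],
exponential approach outside) and caps RD just below AD in the rare
cells where a perturbation crosses — both counts are recorded in the
truth record. `null_spec()` zeroes every effect, coupling and mean
asymmetry while keeping the full nuisance structure, which is what
calibration suites need.

Everything is driven by a single integer seed; identical seeds give
bit-identical cohorts, and the truth record stores every injected
parameter.

## Numerical and design choices

* OLS is solved by QR; rank deficiency is an error naming the
  collinear columns rather than a silent drop. Standard errors use the
  unbiased residual-variance estimator; t = β/se with
  df = n − p always.
* Covariate columns that are constant in the analyzed subset (e.g. a
  single-sex subgroup) are dropped from the design rather than left to
  break the fit.
* Classical tests delegate to base R (`t.test`, `fisher.test`); the
  pooled-variance (Student) two-sample form is used rather than Welch
  because it reproduces the published df = 48 demographics table
  exactly. The published sex comparison prints a statistic labelled
  Fisher's exact; since Fisher's test has no such statistic the
  package reports the exact p only.
* Permutation p values never use the plug-in proportion; the add-one
  estimator keeps them valid at any B.
* LI is computed on tract means, not per node, matching how a single
  LI per tract per metric is conventionally tabulated; a node-wise LI
  profile would be a straightforward extension but is not a default.
* Cluster-level associations test segment means over intervals that
  were themselves selected by a group contrast on the same sample.
  This mirrors the published procedure; the outputs label the level
  explicitly so readers can treat those p values as
  selection-dependent.
* Missing whole profiles are allowed and excluded listwise from any
  analysis touching that tract, with a warning naming the subject.

## What the tests show — and what they cannot

The suite verifies three layers: exact worked examples (group-summary
t statistics and LI t statistics recomputed from published summary
tables; the cluster rule on the published intervals), oracle
equivalence (OLS against an SVD pseudoinverse, the Monte-Carlo
permutation null against exhaustive enumeration at n = 5, Fisher's
exact p against hypergeometric enumeration over all 2×2 tables with
N ≤ 30), and statistical guarantees on synthetic cohorts: under null
cohorts the point-wise cluster-report rate and the corrected LI
rejection rate stay at or below 0.05 plus twice the Monte-Carlo
standard error, association slope p values are uniform, and an
injected standardized-amplitude-1.5 effect at nodes 38–42 is recovered
as an overlapping cluster in well over 80% of replicates.

Scaled problem sizes keep the whole suite within minutes on one CPU:
calibration and recovery use 200 simulation replicates with 1000 (500
for recovery) permutations, single-metric families, and 30-node grids
where the node dimension is not itself under test; the full 100-node
grid is used wherever clusters are involved.

These simulations validate the *inference machinery*, not the biology:
the generator's Gaussian latent fields, stationary noise and linear
couplings are idealizations. Real profiles have heavier tails,
non-stationary along-tract variance, partial-volume artifacts near
tract endpoints, and site/protocol effects, none of which are
emulated. Passing calibration here means the permutation machinery is
correct under exchangeability — it cannot certify robustness to those
real-data violations.

## Known limitations

* Only complete node grids per (subject, tract) are accepted; no
  interpolation of missing nodes is offered.
* No mixed-effects, robust or Bayesian variants; no FDR control (the
  design is permutation FWE throughout); no threshold-free cluster
  enhancement or spatial smoothing.
* The between-hemisphere coupling of the generator is limited to the
  shared subject effect and the LI draw; genuine bilateral node-wise
  correlation structure is not modeled.
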