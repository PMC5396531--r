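---
title: "Topological length and connection atrophy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological length and connection atrophy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connatrophy)
```

`connatrophy` tests a single scientific idea on longitudinal structural
connectomes: that the *topological length* of a white matter connection in
the healthy brain network predicts how fast it degenerates in premanifest
Huntington's disease (preHD). This vignette documents the statistical
machinery, the choices made where the design was genuinely open, and what
the synthetic cohort does and does not establish.

## The data model

The unit of data is a **connectome observation**: one subject-visit
symmetric, non-negative matrix `W` of connection strengths over a labelled
parcellation (by default 70 cortical and 4 striatal regions — caudate and
putamen bilaterally). Strengths are unitless streamline-weight sums of the
kind produced by SIFT2-style tractogram weighting; absence of a connection
is a zero weight, while a *missing visit* is represented by the absence of
the matrix, never by zeros. Visits are annual; the model time metric is
`time = visit − 1` years so that baseline is time zero.

## Modular partitioning

Cortical modules are found on the network averaged over all participants.
Averaging uses **baseline visits only** by default
(`pipeline_config(partition_visits = "baseline")`): the average should
describe a common reference topology, and restricting to baseline keeps the
later-visit preHD degeneration from leaking into the reference network. An
`"all"` option is provided since either convention is defensible.

Louvain modularity maximization is stochastic, so the partition is
stabilized over repeated runs (default `n_runs = 1000`). Two consensus
variants are implemented:

* `"agreement"` (default): Lancichinetti–Fortunato agreement-matrix
  consensus. Co-assignment frequencies over the runs are thresholded at
  `tau` (default 0.5) and the thresholded matrix is itself re-clustered by
  the same number of runs, iterating (cap 50; exceeding the cap raises an
  error carrying the last agreement matrix) until every run agrees. This is
  the behaviour of the standard brain-connectivity toolbox chain that
  "most common assignment by consensus" describes.
* `"modal"`: literally the most frequent canonicalized single-run
  assignment.

Module labels are canonicalized (numbered by the lowest contained region
index), so partition equality is label-invariant. The resolution default
γ = 1 is classic modularity; the sensitivity sweep γ ∈ {0.6, 1, 1.7}
reports the module count per resolution, which must be nondecreasing in γ.

## Connection subtypes

Given the cortical partition, region pairs classify as: striatal–cortical →
**cortico-striatal** (the left and right striatum are pooled into a single
seed set, so there is one CS connection per cortical module — 6, not 12,
with 3 modules per hemisphere); same module → **intramodular**; different
modules, same hemisphere → **intrahemispheric**; different hemispheres →
**interhemispheric**. Striatal–striatal pairs are excluded by construction.
Classification uses region hemispheres, not module hemispheres, so it
remains well defined even if a consensus module ever straddled the midline.
Module-level connection strength is the sum of member-pair weights, and the
member pairs of all connections partition the analyzed pairs exactly —
`choose(n_cortical, 2) + n_striatal * n_cortical` of them, 2,695 for the
default 70 + 4 parcellation.

The voxel-connectivity-profile (VCP) normalization rule is exposed as the
standalone `vcp_normalize()`: a striatal voxel counts as connected to a
cortical target when **at least** 1% of its streamlines reach the target
(the bound is inclusive), and the connected-voxel count is divided by the
summed seed and target volumes (units 1/mm³). Tractography itself is out of
scope; only the thresholding arithmetic is implemented.

## The longitudinal mixed model

Per connection, strength is modelled as

`Y_ij = α + β t_ij + γ·group_i + δ·group_i·t_ij + θX_i + a_i + b_i t_ij + e_ij`

with covariates X (age and education numeric, sex and site reference-coded
factors), joint-normal random intercepts and slopes with unstructured 2×2
covariance, and i.i.d. Gaussian errors. Estimation is **maximum
likelihood, not REML**, and hypothesis tests on γ (baseline group
difference) and δ (slope difference) are two-sided normal tests of the
z-ratio `z = estimate/SE` — the stated inferential procedure this package
reproduces; no Satterthwaite/Kenward–Roger correction is applied. Subjects
with missing visits contribute through the likelihood (missingness treated
as ignorable). FDR control is Benjamini–Hochberg applied **within each
connection subtype**, separately for the intercept-contrast and
slope-contrast families.

Numerical care: single-level factors and rank-deficient fixed-effect
designs are detected before fitting and reported with the offending column
named. If the unstructured random-effects fit is singular or does not
converge, the model is refitted with independent random effects, then with
a random intercept only; the fallback level is recorded in the result (the
contrasts of interest are insensitive to this in the regimes the tests
exercise, which is itself verified by a robustness test).

The cognition variant replaces the group dummy with the continuous baseline
global cognitive composite (terms `γ·c_i + δ·c_i·t_ij`), restricted to
preHD subjects, with covariates age, site, education, CAG and time-by-CAG.

## Topological length and atrophy scores

Connection length is graph-theoretic, not anatomical: the edge-length
matrix is the elementwise reciprocal of the weight matrix (zero weight →
infinite length), and the shortest weighted path length is computed by
all-pairs Dijkstra on the baseline control-average network. Pairs left
disconnected (possible only in sparse networks; the default simulated
networks are fully connected) get infinite length and are excluded from the
correlation with their count reported.

Atrophy scores standardize each preHD subject against the control
distribution per connection, `Z = (C − μ_h)/σ_h`, with the **sample**
(n−1) standard deviation. Connections with zero control SD are flagged
degenerate and excluded with a warning. Age and sex are regressed out of
the strength (or rate) values across subjects **before** Z-scoring
(residualize-then-standardize; the other order is not exposed because
Z-scoring residuals against residual control moments is the only
combination in which a preHD subject identical to the control mean profile
scores exactly zero).

Two (0, 1) transforms of Z are provided, and the choice is deliberately
explicit rather than silent:

* `"logistic"` (default): `1/(1 + e^Z)`, strictly decreasing, so
  weaker-than-control strength (Z < 0) maps above 0.5 — higher score means
  more atrophy — and `score(z) + score(−z) = 1`.
* `"literal"`: `1/(e^{−Z} + e^{+Z}) = sech(Z)/2`. This form is
  non-monotone (maximal at Z = 0), so it cannot order connections by
  atrophy; it is retained for comparison because it appears in print in the
  source analyses. Both variants agree at Z = 0 (score 0.5).

The longitudinal score uses per-subject least-squares slopes of strength
over time, computed only for subjects observed at **all** visits, then the
same residualize/Z/transform/average chain against control rates.

The length–atrophy association is the Spearman rank correlation (average
ranks for ties) between per-connection length and the preHD-averaged
transformed score, with a two-sided t-approximation p-value on `df = n − 2`.
The subtype comparison of lengths is a classical one-way ANOVA followed by
Tukey–Kramer honest significant differences (valid for unequal group
sizes).

## The synthetic cohort

No public data accompany the analyses this package implements, so the
generator is a first-class module whose defaults *are* the study
conditions:

* **Cohort**: 85 controls and 82 preHD subjects, 3 annual visits, with each
  post-baseline visit missing independently with probability 0.15 —
  echoing an observational cohort with per-visit totals near 157–169 scans
  and 486 scans overall (`cohort_visit_counts()` records the emulated
  enrolment schedule exactly).
* **Network**: 70 cortical regions in 6 planted modules (3 per hemisphere,
  sizes 12/12/11) plus 4 striatal regions; every eligible pair gets an
  edge (density 1 — SIFT2-style weighting retains the full connectome and
  argues against thresholding), with base weights intramodular 20,
  intrahemispheric 4, interhemispheric 1.5, cortico-striatal 0.8 and
  multiplicative log-normal jitter (`noise_sd = 0.1`). The weight
  hierarchy simultaneously plants the modular structure and the
  path-length ordering in which cortico-striatal connections are longest.
  The ratios were fixed by a closed-form modularity calculation: at γ = 1
  the merge of two same-hemisphere modules must *lower* Q with a clear
  margin (ΔQ ≈ −0.012 per merge under these weights), because a hierarchy
  with intrahemispheric weights too close to intramodular ones places the
  planted optimum on the merge boundary and makes recovery unstable.
* **Degeneration**: preHD log-strength carries a cross-sectional deficit
  `λ·L*` (λ = 0.2 per unit path length) and declines by `κ0 + κ1·L*` per
  year (κ0 = 0.02, κ1 = 0.05), where `L*` is the true path length computed
  once on the noiseless base network. Degeneration on the log scale keeps
  weights positive and makes per-subject least-squares slopes estimate the
  planted rates; with these coefficients the cortico-striatal deficit is
  ≈ 15–20% at baseline and ≈ 7%/year, against ≈ 1% effects for
  intramodular connections.
* **Covariates and heterogeneity**: small multiplicative effects of age
  (−0.5%/year from the cohort mean), sex (−2% for female) and site
  (±3%), plus per-subject log-scale random intercepts (SD 0.05) and slopes
  (SD 0.02/year) that give the mixed model true random effects to absorb.
* **Cognition**: the standardized baseline interhemispheric strength mixed
  with independent noise at weight 0.5, so the cognition model has a
  planted positive association to find.

What the generator does **not** emulate: anatomical geometry and real
tract trajectories, site-by-sequence interactions, heavy-tailed or
zero-inflated weight distributions, correlated edge noise, gray matter
atrophy, or any relationship between topological and millimetric tract
length. Passing tests therefore demonstrate that the statistical chain
recovers the relationships it is designed to detect under a faithful
generative model of the *analysis assumptions* — not that those assumptions
hold in real diffusion data.

## Reproducibility, seeds, and problem sizes

Every stochastic stage takes its seed deterministically from a single
master seed (stage-name hashing), so `run_pipeline()` is bit-reproducible
and stable against stage reordering. The consensus stage spawns one seed
per Louvain run.

Problem sizes used by the shipped checks, chosen as the package's own
test-design points: unit tests run 12–20 subjects per group on reduced
parcellations (10–24 cortical regions); the consensus-recovery and
end-to-end checks run the full 70 + 4 parcellation with the default cohort
(85/82) and 200–1,000 Louvain runs; mixed-model calibration uses the
simulation design of 100 subjects per group over 3 visits, 500 null
replicates (the z-ratio test's type-I rate is within binomial error of 5%
at this size; at much smaller cohorts the normal approximation to what is
effectively a t-statistic becomes visibly anticonservative) and 200
replicates under a planted slope difference of −0.5.

## Known limitations

* Path length is purely topological; its relation to biological tract
  length is not modelled.
* The z-ratio inference ignores small-sample degrees-of-freedom
  corrections by design fidelity; do not use this package's p-values for
  cohorts with few subjects without switching to a t-based correction.
* The literal transform variant is non-monotone and should only be used to
  reproduce historical numbers, never for new analyses.
* Consensus convergence is not guaranteed for adversarial networks; the
  iteration cap surfaces the agreement matrix for inspection rather than
  looping forever.
* Intra-striatal connections are excluded everywhere, and the striatum is
  pooled at the module level; edge-level analyses keep the four striatal
  regions separate.
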