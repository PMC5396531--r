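# connatrophy

Connectome analysis of length-dependent white matter degeneration in
premanifest Huntington's disease (preHD).

## The scientific problem

In carriers of the Huntington's disease CAG expansion, white matter loss
follows a stereotyped spatial pattern years before motor onset, but why some
connections degenerate before others is unclear. One candidate principle is
**topological vulnerability**: connections that are topologically *long* in
the healthy structural connectome — weak direct links whose best alternative
routes are also costly — are the most metabolically demanding and may be the
first to fail.

`connatrophy` implements the full analysis chain that tests this principle on
longitudinal structural connectomes (region-by-region matrices of
streamline-weighted connection strengths), together with a synthetic-cohort
generator so the entire chain runs and is testable without imaging data.

The pipeline:

1. **Consensus modular partition.** The group-average cortical network is
   clustered with the Louvain algorithm, repeated (default 1,000 runs) and
   stabilized by agreement-matrix consensus, at resolution γ (default 1,
   classic modularity; γ ∈ {0.6, 1, 1.7} as a sensitivity sweep).
2. **Connection subtypes.** Region pairs are classified as cortico-striatal,
   interhemispheric, intrahemispheric or intramodular; module-level
   connection strengths are sums of member-pair weights. With 3 modules per
   hemisphere and a pooled striatum this gives 6 + 9 + 6 + 6 = 27
   connections.
3. **Longitudinal mixed models.** Per connection, the maximum-likelihood
   linear mixed-effects model

   `Y_ij = α + β t_ij + γ·group_i + δ·group_i·t_ij + θX_i + a_i + b_i t_ij + e_ij`

   with `t_ij = visit − 1` years, covariates X (age, sex, site, education)
   and joint-normal random intercepts/slopes. The group contrasts of
   interest are γ (baseline difference) and δ (slope difference), tested
   with z-ratios `z = estimate/SE` and Benjamini–Hochberg FDR within each
   connection subtype. A cognition variant replaces the group dummy by the
   baseline global cognitive composite.
4. **Topological length.** Connection length is the shortest weighted path
   length on the averaged healthy-control network: edge length = 1/weight,
   all-pairs Dijkstra.
5. **Atrophy scores.** Per connection, preHD strengths (cross-sectional) and
   per-subject least-squares rates of change (longitudinal) are residualized
   on age and sex, Z-scored against the control distribution,
   `Z = (C − μ_h)/σ_h`, mapped to a (0, 1) atrophy score by the logistic
   transform `1/(1 + e^Z)` (higher score = more atrophy), and averaged over
   the preHD group.
6. **Length–atrophy association.** Spearman rank correlation between
   per-connection path length and both atrophy scores across all analyzed
   region pairs (for 70 cortical + 4 striatal regions: C(70,2) + 4·70 =
   2,695 pairs, df = 2,693), plus a one-way ANOVA of path length across the
   four subtypes (df = 3, 2691) with Tukey–Kramer post-hoc comparisons.

The synthetic generator plants a known modular structure and makes preHD
connection strengths decline on the log scale at rate `κ0 + κ1·L` per year
for a connection with true path length `L`, with a cross-sectional deficit
`λ·L` — so downstream stages must recover a positive length–atrophy
correlation, the planted modules, and the subtype path-length hierarchy
(cortico-striatal > interhemispheric > intrahemispheric > intramodular).

## Worked example

```r
library(connatrophy)

cfg <- pipeline_config(
  simulation = sim_config(n_controls = 20, n_preHD = 20),
  n_runs = 200, seed = 1
)
report <- run_pipeline(cfg)
report
```

```
<pipeline_report>
  partitions (module count per gamma):
 gamma n_modules     Q
   0.6         2 0.560
   1.0         6 0.435
   1.7         6 0.318
  subtype connections:
          subtype n_connections
     intramodular             6
 intrahemispheric             6
 interhemispheric             9
 cortico_striatal             6
  length-atrophy correlation:
        analysis estimate  p_value   df    n n_excluded
 cross_sectional    0.793 0.00e+00 2693 2695          0
    longitudinal    0.364 2.69e-85 2693 2695          0
  subtype path-length ANOVA: F(3,2691) = 109365
  mixed-model effects with q < 0.05 : 46 of 54
```

Reading this: at γ = 1 the consensus partition recovers 6 cortical modules
(3 per hemisphere), yielding the 6/9/6/6 subtype connections; all 2,695
region-pair connections are analyzed (none excluded); both the baseline
atrophy score (ρ = 0.79) and the rate-of-atrophy score (ρ = 0.36) increase
with topological connection length, as planted; and the subtype path-length
ANOVA is overwhelmingly significant, with every Tukey–Kramer pairwise
comparison separating the four subtypes:

```r
report$tukey[, c("comparison", "estimate", "adj_p_value")]
#                          comparison estimate adj_p_value
# 1     intrahemispheric-intramodular    0.191           0
# 2     interhemispheric-intramodular    0.531           0
# 3     cortico_striatal-intramodular    1.042           0
# 4 interhemispheric-intrahemispheric    0.341           0
# 5 cortico_striatal-intrahemispheric    0.851           0
# 6 cortico_striatal-interhemispheric    0.511           0
```

Individual stages are ordinary functions on data frames and matrices:
`read_region_table()`, `read_connectome()`, `average_connectomes()`,
`consensus_partition()`, `enumerate_subtype_connections()`,
`fit_group_lmer()` / `fit_cognition_lmer()` (with `tidy()` / `glance()`
methods), `path_length_matrix()`, `atrophy_table()`,
`length_atrophy_correlation()`, `anova_subtypes()`, `tukey_kramer()`.
`plot_subtype_lengths()`, `plot_length_atrophy()` and
`autoplot()` on a partition produce the standard diagnostic figures.

## Vignette

`vignettes/length-dependent-atrophy.Rmd` documents the model and its
assumptions, the synthetic-cohort design, numerical choices (consensus
variant, transform variants, tie and degeneracy handling), and known
limitations.
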