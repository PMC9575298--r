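---
title: "Methods: Bayesian association networks and tripartite triangle motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian association networks and tripartite triangle motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadnet)
```

## The analysis

`triadnet` links the structure and function of the faecal metagenome to the
severity of extraintestinal symptoms — depression (HADS-D, 0–21) and fatigue
(WEIMuS, 0–68) — in small clinical cohorts such as patients with active
inflammatory bowel disease. Its inputs are post-annotation tables: a
genus-level taxonomic abundance matrix, a KEGG-module functional abundance
matrix (or a KO-level matrix plus module definitions, including an SCFA
production extension), and per-sample metadata. Read-level processing is out
of scope.

The analysis has three parts:

1. **Preprocessing.** Samples with fewer than 50 annotated features in
   either table are removed; features present in fewer than 15 retained
   samples are removed; counts are closed to relative abundances and
   centred log-ratio (CLR) transformed per modality; each CLR feature is
   then residualised against ten nuisance covariates by ordinary least
   squares. All associations are computed on these residuals, while the
   symptom scores enter raw.
2. **Bayesian association networks.** Every variable pair receives a
   Jeffreys–Zellner–Siow (JZS) Bayes factor computed from its Pearson
   correlation; edges with `log10(BF10) >= 0.5` (H1 at least ~3x as likely
   as H0) form an undirected network over taxon (T), module (M) and
   psychopathology (PP) nodes. Spearman coefficients carry the direction.
3. **Triangle motifs.** The tripartite triangles — one taxon, one module
   and one score, all three pairwise connected — are enumerated
   exhaustively and reported in a per-motif table.

## The Bayes factor

For a pair with `n` complete observations and sample correlation `r`, the
default (`method = "regression"`) evidence is the single-covariate
Zellner–Siow regression Bayes factor

$$
\mathrm{BF}_{10} \;=\; \int_0^{\infty} (1+g)^{(n-2)/2}
\bigl(1 + g(1-r^2)\bigr)^{-(n-1)/2}\, \pi(g)\, dg ,
$$

where $\pi(g)$ is the inverse-gamma$(1/2,\; n\,s^2/2)$ density that makes
the implied prior on the standardised effect a Cauchy of scale $s$
(`rscale`). The default `rscale = 0.354` ($\approx\sqrt2/4$) is the
conventional "medium" width for a single continuous covariate. The integral
is evaluated by adaptive quadrature on the $u=\log g$ axis after factoring
out the maximum of the log-integrand, to a relative tolerance of `1e-8`;
the result depends on `r` only through $r^2$.

The literature also uses a Bayes factor that places a stretched
Beta$(1/\kappa, 1/\kappa)$ prior directly on the population correlation and
integrates the exact sampling density of `r` (evaluated here with a
hypergeometric-series implementation). Which of the two forms produced a
published number can generally not be decided from a printed table, so both
are provided; `method = "stretched-beta"` switches the whole pipeline. Both
forms agree on sign and ranking; absolute values differ by up to ~0.1–0.2
log10 units in the relevant range.

Evidence classes follow the usual bands on `log10(BF10)`: substantial at
0.5, strong at 1.0, decisive at 2.0; the network threshold (0.5) is
inclusive.

A Monte-Carlo estimator (`jzs_log10_bf_mc()`) draws `g` from its prior and
averages the likelihood ratio; with $10^7$ draws it pins the quadrature to
about three decimals and serves as an independent numerical cross-check in
the test suite and the acceptance script.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `qc_min_features` | 50 | per-sample richness bound, applied to both tables |
| `prevalence_min` | 15 samples | feature prevalence cut, counted after QC |
| `rscale` | 0.354 | JZS prior width (unitless) |
| `bf_log10_threshold` | 0.5 | network edge cut on `log10(BF10)` |
| `pseudocount` | half the minimum nonzero relative abundance | CLR zero replacement |
| `covariates` | age, sex, diagnosis, CRP, 6 medication flags | the 10 nuisance variables |

**The tenth covariate.** Nine nuisance variables are unambiguous (age, sex,
CRP and six medication classes). We include diagnosis (CD vs UC, coded 0/1)
as the tenth: disease entity is a known driver of gut microbiome
composition, and it is the natural companion of the demographic/clinical
covariates in this setting. The configuration requires exactly ten named
columns so that the residual degrees of freedom are stated explicitly
(n − 11 with intercept), and refuses to run below 3 residual degrees of
freedom.

**Scores are never adjusted.** Only CLR abundances are residualised;
HADS-D and WEIMuS enter raw. A consequence quantified below is a
$\sqrt{1 - 11/n}$ attenuation (~10% at n = 57) of feature–score sample
correlations relative to the latent association, because the chance
component of the latent factor that the covariates absorb is removed from
the feature but not from the score.

**Diversity.** The Shannon index (natural log) is computed on the QC-passed
genus composition *before* prevalence filtering: diversity should reflect
the full annotated composition, not the aggressively filtered feature set
used for the network. The choice is configurable by passing a filtered
table to `marker_panel()`.

## Numerical choices

- CLR zeros are replaced multiplicatively by half the smallest nonzero
  relative abundance of the table, rows re-closed; CLR rows then sum to
  zero within `1e-9` and the transform is invariant to sample-wise count
  rescaling.
- The nuisance fit uses a single QR decomposition per modality;
  rank-deficient designs abort with the collinear columns named, and
  residuals are orthogonal to the design within `1e-8`.
- Degenerate pairs (zero variance, `|r| = 1`) are rejected by default; an
  explicit `cap_degenerate` option caps at `|r| = 1 - 1e-8` with a warning.
- Edges with pairwise-missing data (CRP, calprotectin) use
  pairwise-complete observations and record `n_obs` per edge.
- Hand-transcribed edge lists may contain conflicting duplicate rows; these
  are resolved to the maximum Bayes factor with a warning, so that an
  inconsistent transcription can still be analysed reproducibly.
- Motif enumeration is deterministic (sorted by taxon, then module). The
  `"screen"` edge strategy computes all feature–score edges and only the
  taxon–module edges that could close a triangle; it yields exactly the
  motifs of the full pairwise matrix (a triangle needs all three edges
  above threshold) at a fraction of the cost, and `"full"` remains
  available for complete edge exports.

## What the synthetic generator emulates

`cohort_spec()` / `generate_cohort()` produce cohorts with the statistical
structure the analysis assumes: by default 57 samples, 59 prevalent genera
and 209 modules (the post-filter dimensions of the motivating study),
compositional counts with zeros, covariate effects on abundances, and
planted taxon–module–symptom triangles.

- **Counts.** Per-feature CLR-scale baselines (6 natural-log units of range
  for genera, 8 for modules) plus covariate effects, latent-factor
  loadings, and unit-SD Gaussian noise are softmax-mapped to compositions
  and drawn as multinomials at a mean depth of `1e5` (±15%), a conservative
  stand-in for annotated read counts.
- **Zeros.** Dropout rises linearly with feature rarity; its mean over
  module features is `zero_inflation` (default 0.3), so that roughly a
  tenth of modules falls under the 15-sample prevalence cut, as in real
  functional profiles. The genus table receives one twentieth of that rate:
  it emulates a *post-QC* cohort, whose regular samples must retain at
  least 50 annotated genera; optional `low_richness_samples` are near-empty
  samples for exercising the QC stage.
- **Planted triangles.** A shared standard-normal latent factor `z` loads
  on one taxon, one module and (negatively) one symptom. For a target
  correlation $\rho$ each loading corresponds to $\sqrt\rho$, so all three
  pairwise latent correlations equal $\rho$ — the minimal mechanism that
  produces a triangle without asserting causal direction. Targets default
  to the 0.3–0.5 range of published motif tables; the specification errors
  out when the requested loadings are infeasible ($|\rho| \ge 0.95$, or a
  symptom's total variance share above 0.95).
- **Metadata.** Age 40 ± 16, 58% female, 18% UC, log-normal CRP
  (21.2 ± 24.8 mg/l) and calprotectin (365 ± 282 µg/g, ~7% missing),
  medication prevalences matching an active-IBD clinic population; every
  binary covariate is guaranteed at least two carriers and two
  non-carriers so the ten-covariate design stays full rank. Scores are
  rounded and clipped into their questionnaire ranges.

What it does **not** emulate: phylogenetic correlation among taxa,
KO-sharing correlation among modules, non-Gaussian latent structure,
batch or storage effects, and any causal coupling between inflammation
markers and symptoms. Passing the simulation-based checks therefore
demonstrates the statistical machinery under idealised independence
assumptions, not performance on real data.

## Calibration findings

Two quantitative properties of the default study dimensions are worth
stating because the test suite measures them (sizes: 200 replicates for
cohort-level checks, 1000 for the null pair rate, $10^7$ draws for the
Monte-Carlo oracle):

- **Per-edge null calibration is conservative.** At n = 57 an independent
  pair crosses `log10(BF10) >= 0.5` in about 1–2% of replicates
  (threshold correlation $|r^*| \approx 0.32$).
- **The Bayes factor is not monotone in n at small |r|.** For a fixed
  sample correlation below the consistency boundary (e.g. r = 0.2), a
  larger sample makes the data *more* compatible with the null, so
  log10(BF10) first decreases with n (−0.263 at n = 10, −0.272 at n = 30)
  before rising once r outgrows the shrinking null band. Quadrature and
  the Monte-Carlo oracle agree on this; it is a property of the statistic,
  and monotonicity in n should only be expected for clearly supra-threshold
  correlations.
- **Triangle-level multiplicity is not negligible.** A 59 x 209 x 2 node
  set offers 24,662 candidate triples; with per-edge null rates of 2–3%
  (the feature–feature rate is widened slightly by the 10-covariate
  residualisation), the *expected* number of false triangles in a null
  cohort is of order 0.2–0.7 by linearity of expectation, regardless of
  dependence between edges. Measured over 200 null cohorts the pipeline
  finds a mean of ~0.7 false motifs and returns zero motifs in only ~55%
  of replicates. A motif list of a handful of triangles from a single
  cohort of this size should therefore be read as hypothesis-generating:
  the triangle search has an expected false-discovery count of order one.
- **Power.** A planted triangle with target $\rho = 0.5$ is recovered
  (all three edges above threshold) in roughly 75–80% of replicates; at
  $\rho = 0.2$ recovery collapses to ~2%. Much of the shortfall from
  ideal power is the score-side attenuation described above.

## Known limitations

- Bayes factors are computed from Pearson correlations of residualised
  CLR values with `n_obs` taken at face value; no correction is made for
  the degrees of freedom consumed by the adjustment.
- The network is a marginal association network: no partial correlations,
  no multiplicity control across the ~36k candidate edges beyond the
  evidence threshold itself.
- T–T and M–M edges are computed (under the `"full"` strategy) and
  reported but never form motifs; motifs are restricted to exactly one
  node per modality.
- The stretched-beta Bayes factor is numerically exact but slower; the
  pipeline default remains the regression form.
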