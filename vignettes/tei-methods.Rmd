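---
title: "Methods: transcriptional E/I signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptional E/I signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teisig)
```

This vignette documents the statistical procedures implemented by
`teisig`, the assumptions behind them, the defaults and why they were
chosen, and what the synthetic-data generators do and do not emulate.

## The tE/I ratio and its assumptions

The transcriptional excitation/inhibition ratio is deliberately the most
basic, non-subunit-specific marker available from expression data:

$$t\mathrm{E/I} = \frac{\sum_{g \in \mathrm{AMPAR}} x_g}
                       {\sum_{g \in \mathrm{GABA_AR}} x_g},$$

the ratio of summed AMPA-receptor subunit expression (*GRIA1–4*) to
summed GABA\_A-receptor subunit expression, per sample or group. Summing
over all subunits makes no assumption about receptor stoichiometry or
synaptic versus extrasynaptic placement; it treats the transcript pool as
the available substrate for either gate. Sums are taken on the **linear
scale**: log2 tables are exponentiated base 2 first, because intensities
and FPKM/RPKM/uTPM abundances add on the linear scale while log2 values
do not. A `sum_scale = "log2"` switch is retained for sensitivity
analysis, since summing log intensities is a defensible alternative for
microarray data and the choice is not forced by the data themselves. The
ratio is invariant to global rescaling of the table and maps to its
reciprocal when the two panels are swapped — both properties are tested.

The AMPAR panel is fixed (*GRIA1–4*). The GABA\_A\_R panel defaults to
all 19 *GABR* family genes including the rho subunits (*GABRR1–3*);
because rho-containing receptors are sometimes classified separately
(GABA\_C), the panel is configurable and any subset can be passed to
every function that takes a panel. The transporter panel is *SLC12A1*
(NKCC2), *SLC12A2* (NKCC1) and *SLC12A5* (KCC2); the KCC2/NKCC1 ratio
indexes the developmental chloride switch that determines whether
GABA\_A signalling is hyperpolarizing.

## Representative-probe selection

Microarray designs carry several probes per gene (here 4 each for
*GRIA1–3* and 5 for *GRIA4*); their collinearity would dominate any
clustering of probe-level data. `select_representative_probes()` keeps
one probe per gene: the probe × probe Pearson correlation matrix,
computed across **all** samples (whole-brain, so that a single globally
representative probe is chosen rather than one per region; a `group_by`
argument exposes the per-group alternative), is factored by iterative
**principal-axis** extraction of a single factor with no rotation:

1. initialize communalities with squared multiple correlations,
   $h_i^2 = 1 - 1/(R^{-1})_{ii}$ (falling back to each row's largest
   absolute off-diagonal correlation if $R$ is singular);
2. replace the diagonal of $R$ with $h^2$, take the leading eigenpair,
   set loadings $\lambda = \sqrt{e_1}\,v_1$;
3. update $h^2 = \lambda^2$ and repeat until
   $\max_i |\Delta h_i^2| < \text{tol}$.

One factor is extracted because a single representative dimension per
gene is what selection requires. Defaults are tol = 1e-6 and 100
iterations, which place the loadings well within the accuracy that
selection needs; for exact benchmarking against analytically constructed
rank-1-plus-diagonal matrices the tests tighten to tol = 1e-12, where the
recovered loadings match the generating vector to 1e-6. Sign is fixed by
flipping the loading vector so its sum is non-negative. Heywood cases
(communality > 1, common when probes are nearly perfectly correlated)
are clipped to 1 − 1e-12 with a single warning. The selected probe is the
argmax of |loading|; ties fall back to higher mean intensity and then to
lexicographic probe id. The mean-intensity tie-break mirrors the
empirical observation that the best-correlated probe tends to also be the
brightest, and the selection report always carries per-probe mean
intensity so that diagnostic can be audited.

## Age adjustment

Expression is regressed on age per feature (OLS); adjusted values are the
residuals plus the fit at the **cohort mean age**, so the global level of
each gene is preserved and only the age trend is removed. Adjustment is
applied per dataset, never pooled across datasets with different
technologies. With fewer than three distinct ages the design cannot
separate an age trend from noise and the table passes through unchanged
with a warning. Ages are stored in years with birth at 0; prenatal ages
are negative years relative to birth at 40 post-conception weeks
(12 pcw = −0.537 y), which puts embryonic and adult samples on a single
numeric axis.

## Contributions, enrichment, summaries, nested ANOVA

*Proportional contributions* express each panel gene's linear-scale group
mean as a percentage of the panel total; rows sum to 100 by construction
and are invariant to global rescaling. *Fold enrichment* is the ratio of
a substructure's mean to the global mean, where means are taken on the
log2 scale and then exponentiated — i.e. ratios of geometric means on
the linear scale — matching data reported as per-region log2 averages.
Averaging before exponentiation (rather than exponentiating per sample
first) was chosen because the input tables are distributed as log2
summaries; the alternative ordering is a one-line change and a
sensitivity check worth running on real data. *Five-number summaries*
use linear-interpolation (type-7) quantiles — the dominant software
convention, unstated in most papers — with whiskers at the most extreme
observations inside the Q1 − 1.5·IQR and Q3 + 1.5·IQR fences and points
beyond them flagged as outliers.

The *nested ANOVA* decomposes one gene's expression into structure and
substructure-within-structure strata with both factors **fixed**:

$$SS_\text{total} = SS_A + SS_{B(A)} + SS_E,$$

with $F_A = MS_A / MS_{B(A)}$ — the substructure mean square is the
correct denominator for the structure effect when substructure effects
exist — and $F_{B(A)} = MS_{B(A)} / MS_E$. A random-substructure mixed
model is a defensible alternative; fixed effects were chosen because the
substructures are an exhaustive anatomical enumeration rather than a
sample from a population, and the decomposition then has a closed form
that the tests verify against an independent sequential-SS fit to
1e-10. Saturated designs (no residual df) are refused with an error
naming the deficient level. Under the null the structure-level p-values
are uniform, which the suite checks by KS test over 1000 simulated
datasets.

## Ward clustering and multiscale-bootstrap support

Structures (and, transposed, genes) are clustered by Ward's
minimum-variance method in the ward.D2 convention — squared-Euclidean
Lance–Williams updates with square-root merge heights — on Euclidean
distances, via `stats::hclust`. The tests verify merge heights against a
brute-force Lance–Williams implementation.

Cluster support is computed from scratch by multiscale bootstrap. The
feature axis is resampled with replacement at scales
$r \in \{0.5, \dots, 1.4\}$ (resample size $\lceil r n \rfloor$), the
items are reclustered, and each reference cluster's recurrence —
judged by leaf-set identity, invariant to child order — is counted,
giving per-scale bootstrap probabilities $BP_r$. The naive bootstrap
probability is $BP = BP_{r=1}$. Writing
$\psi(r) = \Phi^{-1}(1 - BP_r)$, the signed-distance/curvature model

$$\psi(r) = v\sqrt{r} + c/\sqrt{r}$$

is fit by weighted least squares with binomial delta-method weights
$w_r = B\,\phi(\psi_r)^2 / (BP_r(1-BP_r))$ (unweighted fallback when any
weight is non-finite), and the approximately unbiased p-value is
$AU = 1 - \Phi(v - c)$. Counts of 0 or $B$ are clamped by a 0.5/B
continuity correction rather than dropping those scales; a cluster whose
recurrence saturates at *every* scale carries no extrapolable curve and
is reported with AU = 1 (or 0) directly, and the root is BP = AU = 1 by
construction. AU standard errors come from the WLS coefficient
covariance by the delta method. With fewer than three scales the
two-parameter fit is unidentifiable, so AU is reported missing and BP
kept. In the flat-curve limit ($c \approx 0$) AU reduces to BP, which
the tests check on constructed counts.

The default budget is 10,000 total resamples split evenly across the 10
scales; the test suite and the acceptance script use 1,000 (100 per
scale), which is enough to separate AU > 0.95 clusters from unsupported
ones on the planted-partition benchmark while keeping the suite fast.
The matrix fed to structure clustering uses (gene × subject) expression
columns rather than a handful of per-gene means: with only four AMPAR
genes, scale-resampling of gene means would be degenerate at every
scale, while gene × subject columns give the bootstrap a meaningful
feature axis. Both conventions are available through
`cluster_matrix()`.

## Distance-vector variability

For each unit (a subject × substructure cell, or a structure) the
pairwise subunit distances $d(x, y) = \sqrt{(x-y)^2} = |x - y|$ are
assembled in fixed pair order into a length-$\binom{k}{2}$ vector (6 for
the AMPAR panel). The scalar formula is implemented literally so that the
same code generalizes to the multi-sample case, where the distance
between two gene columns is the full Euclidean norm. Each unit's vector
is Pearson-correlated against a consensus. Two consensus readings are
shipped because the pooled form of the consensus sum is ambiguous
between an average of distances and a distance of pooled squares:
`average_of_units` (elementwise mean — the default, and the natural
reading for a subject consensus) and `pooled_eq2` (elementwise
$\sqrt{\sum_i d_i^2}$). For structure-level comparisons the consensus
can be restricted to a reference structure's units. Correlations are
translation- and scale-invariant in expression, which the tests verify,
and a planted increase in per-subject variance strictly lowers the mean
consensus correlation.

## Group comparisons and trends

Welch's unequal-variance t test (Satterthwaite df) is used for pairwise
group comparisons, and one-way ANOVA followed by Tukey–Kramer HSD
(studentized-range critical values with unequal-n standard errors) for
multi-group comparisons; both delegate to base R (`t.test`, `aov` +
`TukeyHSD`) and both are verified against independent textbook-formula
oracles to 1e-10. Group summaries always report n, mean, SD and SEM
(SEM over units in the group) so that any mean ± SEM/SD figure has a
table counterpart.

Developmental trends are fit with a cubic smoothing spline
(`stats::smooth.spline`), smoothing chosen by generalized
cross-validation unless overridden, and evaluated only over the observed
age range. Pre/postnatal linear fits and correlations split at birth
(age 0). The log2 transform offered for regression of skewed linear sums
uses log2(x + 1); the pseudo-count is stated because the convention
matters at low abundances.

## Synthetic data: what it emulates, and what it does not

The generators are first-class, tested code and define the package's
study conditions:

- `gen_regional_microarray()` — default: 2 ontogeny groups × 2
  structures × 5 substructures, 6 subjects aged 24–57, the 17-probe
  AMPAR design plus one probe per GABA\_A\_R gene; probe $j$ of gene $g$
  is $\lambda_j F_{gs} + \sqrt{1-\lambda_j^2}\,\varepsilon +
  \beta_{\text{age}}\,\text{age}_s$ with default probe loadings
  (0.95, 0.85, 0.75, 0.65[, 0.55]), noise SD 0.5 log2 units, and
  per-subject-per-gene offsets (SD 0.3) shared across regions. The
  single-factor construction makes "most representative probe" exactly
  well-defined (argmax λ), and the ontogeny profiles (telencephalic
  GRIA2-high vs metencephalic GRIA3-low) make the planted 2-way
  partition recoverable with Rand index 1.
- `gen_single_cell()` — seven interneuron types with tE/I means
  (0.66, 1.7, 1.0, 0.80, 1.1, 10, 0.96) and SDs
  (0.13, 0.38, 0.43, 0.26, 0.22, 6.3, 0.13) at cell counts
  (64, 80, 52, 63, 136, 62, 127). Per cell the ratio is drawn lognormal
  with mean exactly $\mu_t$ (the lognormal is mean-corrected), so
  per-type sample means are unbiased estimates of the configured truth.
  Lognormal noise was preferred to a negative binomial because the
  emulated inputs are normalized abundances, not counts.
- `gen_developmental()` — ages from 12 post-conception weeks to 40
  years; constant AMPAR total A = 100; GABA\_A\_R total rising
  logistically to a ceiling of A/0.31, so the post-1-year tE/I plateau
  sits at 0.31; KCC2 rising and NKCC1 falling with midpoints near birth,
  planting a negative prenatal tE/I ↔ KCC2/NKCC1 association and none
  postnatally; multiplicative lognormal gene noise (sdlog 0.08).

Every generator is a pure function of (config, seed). What they do *not*
emulate: probe hybridization chemistry, batch effects, postmortem
degradation, single-cell dropout at realistic sparsity (zero-inflation
exists but defaults to off), or spatially correlated anatomical noise.
Passing recovery tests on this synthetic bed therefore demonstrates that
the algorithms are implemented correctly and are calibrated under their
own assumptions — not that real microarray or RNA-seq data satisfy
those assumptions.

## Numerical choices and degenerate inputs

- Scale (log2 vs linear) is always declared, never inferred; linear
  tables refuse negative values; missing values must be resolved at read
  time by an explicit policy (`error` default, `drop_sample`,
  `drop_feature`), because the analyses use complete regions only.
- Zero-variance probes are excluded from correlation matrices (warned,
  selected only if sole candidate); zero GABA\_A\_R sums give missing
  ratios with a warning rather than infinities; zero-variance distance
  vectors give missing correlations.
- Ward ties are resolved by `hclust`'s agglomeration order; cluster
  identity is by leaf set, so child order never matters.
- Problem sizes in the tests — 600-sample probe-selection replicates,
  1,000-resample bootstraps, 2,000-replicate calibration — were chosen
  as the smallest sizes at which the statistical claims are sharp
  (selection accuracy saturates, AU separates planted from spurious
  clusters, type-I error bounds are tight at ±1.5 points).

## Known limitations

tE/I is a transcript-pool marker, blind to translation, trafficking,
synaptic placement and receptor stoichiometry; its value is comparative
(across structures, cell types, ages), not an absolute physiological
E/I. The nested ANOVA is fixed-effects; a mixed model would generalize
to unbalanced subject sampling. The EFA is single-factor by design and
should not be reused for genes whose probes track multiple biological
signals. AU p-values inherit the usual multiscale-bootstrap caveats:
they are asymptotic, and extremely stable clusters saturate the
recurrence counts, where AU is reported as exact certainty rather than
extrapolated.
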