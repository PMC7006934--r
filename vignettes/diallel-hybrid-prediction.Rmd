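---
title: "Methods: line-informed genomic prediction and additive-dominance GWAS in hybrid maize"
author: "diallelgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: line-informed genomic prediction and additive-dominance GWAS}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific setting

Hybrid maize breeding works with two pools of fully homozygous inbred
lines (heterotic groups, e.g. flint and dent) whose inter-group single
crosses show heterosis. Association studies are usually run on the inbred
lines, where genotyping and phenotyping are cheap and genetics are clean —
but an inbred line never carries a heterozygote, so dominance deviations
are invisible there. For a dominance-driven trait, the markers a line GWAS
flags may therefore be useless, or worse, for predicting hybrids. This
package implements the full analysis needed to examine that question on a
trait like the low-nitrogen tolerance index,
LNTI = (1 − GY_LN/GY_IN) × 100, computed per hybrid from adjusted grain
yields under low and ideal nitrogen: phenotype adjustment, marker QC and
in-silico hybrid genotypes, kernels, eight prediction methods with
cross-validation, additive-dominance association scans, and a synthetic
generator that stands in for the undeposited field data.

## Phenotype adjustment

Trials are unreplicated augmented block designs: each incomplete block
holds a set of test hybrids (once each) plus replicated checks. The
adjusted-means model treats check, hybrid, environment (site × year) and
check × environment as fixed and block-within-environment as random;
because hybrids are unreplicated they contribute no pure-error degrees of
freedom, and the residual and block variances are identified by the
replicated checks. REML fitting is delegated to `lme4::lmer()` — a mature,
well-tested solver; any correct REML implementation agrees at tolerance,
and the package's own parameter-recovery tests confirm the generating
block and residual variances are recovered within 20% on average. A
hybrid's adjusted mean is its fixed-effect estimate evaluated at the
average environment, which makes means translation-equivariant and, in a
balanced complete design, reduces them exactly to arithmetic means.

For heritability the same model is refit with hybrid, environment and
check × environment random (hybrid-only and check-only random terms are
realised through indicator-weighted random slopes, so check plots never
leak into the hybrid variance). Plot-level and entry-mean-level formulas
are evaluated at the REML estimates with `a` environments and `r`
replications; negative inputs to the closed-form helper are clamped at
zero with a warning.

The factor-screening helper reports Wald and likelihood-ratio tests of
site, year, regime and block at the conventional 0.05 but gates nothing:
the per-regime split is always performed. The published analysis removed
two genotypes on LNTI grounds without stating a rule, so the default here
is no removal, with `lnti_bounds` as an explicit hook; entries with
non-positive ideal-N yield are always flagged and excluded (LNTI is then
undefined).

## Marker QC and hybrid genotypes

QC runs strictly in pipeline order: call-rate filter (default 0.95) →
removal of any locus with a heterozygous call among the inbred parents
(treated as a genotyping artefact) → seeded stochastic imputation of
missing parental calls to 0/2 with the marker's observed homozygote
frequencies → LD pruning → in-silico hybrid construction (hybrid dosage =
mean of the two parental dosages, exact for fixed lines) → MAF filter
(default 0.05) on the hybrids.

"Prune so the mean LD is 0.9" is not a mode any standard tool has, so it
is operationalised as: greedy windowed pruning in the PLINK
`indep-pairwise` style (drop the lower-MAF member of any pair above a
pairwise r² cut), with the cut chosen by bisection so that the mean
*adjacent-pair* r² of the retained panel is maximal while not exceeding
the target. Exact duplicates (r² = 1) are redundant at any target and are
always dropped. r² is the squared dosage correlation (composite LD) —
exact haplotype r² for homozygous parents, and phase-free for general
input. Coordinates are 1-based bp; dosages are strandless.

## Kernels

Four relationship matrices are built, each following its defining formula
literally:

* `G_Z` (and `G_W` on the non-significant subset): `ZZ' n / trace(ZZ')` on
  the *uncentered* {−1,0,1} coding — the published formula shows no
  centering, so none is applied by default; a `center` flag exposes the
  alternative because the original choice is not stated.
* `G_A`: VanRaden additive, columns centered at `2p`, denominator
  `2 Σ p(1−p)`.
* `G_D`: dominance indicators centered at `2pq`, denominator
  `Σ 2pq(1−pq)`.
* Gaussian kernel: `K = exp(−h d_ij / median(d))` on the squared genomic
  distances `d_ij = G_ii + G_jj − 2G_ij`, giving a unit diagonal. The
  source recipe for the bandwidth is not reproduced in the text it cites,
  so the default is `h = 1` with median-distance scaling — the common
  self-normalising choice — and `h` is a knob.

Allele frequencies for centering always come from the sample set the
matrix is built on (hybrids for hybrid kernels), never from the parents.
All builders are tested against naive double-loop oracles at 1e-10.

## Prediction methods

MAS is ordinary least squares on the coded significant markers (additive,
dominance, or both stacked), with aliased columns dropped by QR pivoting.
GBLUP and RKHS fit `y = μ + h + e`, `h ~ N(0, σ² G)`; MAS|GBLUP and
MAS|RKHS add the significant markers as fixed effects while the kernel is
built from the complement, `GEBV = M f̂ + ŝ`. Empty partitions degenerate
exactly: no significant markers → pure kernel model; no complement → pure
MAS.

Two engines exist for the kernel models. The default is exact REML on the
eigen-rotated restricted likelihood: the data are rotated into the
orthogonal complement of the fixed-effect space (this explicit rotation
matters — with a rank-deficient kernel the projected-kernel eigen-spectrum
mixes fixed-effect directions into the degenerate null space, which
silently corrupts the profile likelihood), the variance ratio is profiled
on a 40-point log grid refined by golden-section search to 1e-8, and test
samples are predicted through the kernel as the conditional expectation
given the training responses — equivalent to the joint model with missing
responses. The second engine is a Gibbs sampler (eigen-rotated so the
random-effect full conditional is diagonal, with missing responses imputed
by data augmentation), mirroring how the Bayesian software family these
models come from behaves; the two engines cross-validate each other in the
test suite (GEBV correlation > 0.98). REML is the default because it is
deterministic and faster at desk scale; `engine = "gibbs"` switches.

BayesB is Gibbs-only, with the per-marker spike-and-slab update loop in
compiled C++ (as the field's samplers do): each effect is exactly zero
with probability π (Beta prior, prior mean 0.5 with concentration 10) or
normal with its own scaled-inverse-χ² variance — a scaled-t slab.
Hyperparameters follow the R²-rule with `r2_prior = 0.5` and 5 prior
degrees of freedom: prior modes are set so the markers (or kernel) are
expected to explain half the phenotypic variance. Chains use R's RNG, so a
single `seed` reproduces them bit for bit. Full-scale settings
(30,000 / 5,000 / 5) are the `mcmc_config()` defaults; tests and the
orchestrator use desk-scale chains (≈ 1,500–3,000 iterations), which the
ridge-oracle and two-engine checks show are ample for posterior means at
these problem sizes.

Cross-validation draws 75/25 training-testing splits, 50 by default;
replicate k seeds its split with `seed + k` so any replicate can be rerun
alone. Predictive ability is the Pearson correlation on the *test set
only* (the whole-sample alternative would leak training fit). Replicates
with constant GEBVs are recorded as missing with a warning and excluded
from the mean; the summary carries a one-sample t-test against zero,
mirroring the convention of flagging methods whose mean ability is not
distinguishable from zero.

## Association scans

The hybrid scan fits `g = μ + PCs + S m + polygenic + e` per marker with
additive, dominance or both codings (each effect tested by a marginal 1-df
Wald test, so a marker can be significant for A, for D, or both). The
polygenic term uses `G_A`, `G_D` or both. Variance components are
estimated once on the marker-free null model and reused for every marker —
the P3D convention; this makes each marker test a rotated ordinary
regression and, crucially, makes 400-permutation thresholds affordable,
since the whole permutation batch reduces to matrix products in the
whitened space. Exact per-marker REML is deliberately not the default: at
these sample sizes P3D is the standard efficient choice and is what makes
permutation scans comparable across markers. Markers whose coding has no
variation (monomorphic; no heterozygotes under D) are reported with `NA`
and skipped.

The significance threshold is the empirical α-quantile — the order
statistic `ceiling(α · n_perm)`, i.e. the 20th smallest of 400 at
α = 0.05 — of the minimum p-value over markers across seeded permutations
of the phenotype vector. Permuting the phenotype breaks the
genotype-phenotype and kinship-phenotype links simultaneously, which is
valid under the global null (the regime the threshold addresses) though it
ignores polygenic structure under the alternative. Family-wise error
calibration is verified empirically in the acceptance suite
(0.05 ± 0.02 over 1,000 null replicates).

Model choice across codings/kinships/PC counts follows the genomic
inflation factor λ = median(χ²)/0.4549: the configuration with λ closest
to 1 wins, ties broken toward fewer PCs — a quantitative version of
"pick the best QQ plot". Marker heritabilities use
`H² = 2pqα²/Var(ĝ)`, `H² = 2pq[a + d(q−p)]²/Var(ĝ)` and
`H² = 4p²q²d²/Var(ĝ)` with `α = a + d(q−p)`; `Var(ĝ)` defaults to the
sample variance of the adjusted phenotype. Reported MAF refers to the
minor allele; the sign of β refers to the allele coded +1 in the dosage
file.

## The synthetic generator

`sim_config()` defaults describe the design this package targets: 35 + 15
parents in two heterotic groups, 906 single crosses, 2 sites × 2 years ×
2 N regimes, blocks of 16 test entries plus 2 checks, plot heritability
≈ 0.22 (the reported per-regime range is 0.19–0.25), an ideal-N mean of
7.37 Mg/ha with a 0.87 Mg/ha drop under low N. Because 906 exceeds the 525
inter-group pairs of a 35 × 15 diallel, the mating scheme must have
included intra-group crosses; `allow_intragroup` therefore defaults to
`TRUE`, and the generator samples unique pairs without replacement.

Group divergence uses the Balding–Nichols construction (one Fst-like
parameter; default 0.2, a typical flint-dent scale), validated by an
independent two-population Fst estimator in the tests. Linkage
disequilibrium comes from a blockwise copying model: markers in a block
share the block core's allele-frequency draw and copy its allele with
probability `ld_copy` — enough LD to exercise pruning without a coalescent
simulator, and constructed so every marker keeps its marginal frequency
exactly (copying from a core with a *different* frequency would distort
marginals and bias Fst, a failure mode the test suite checks for).

Trait architecture: `n_qtl` causal markers get additive effects on the
{−1,0,1} coding and dominance deviations on the heterozygote indicator,
rescaled so the realised Var_D/Var_A among the hybrids equals
`dominance_ratio` (default 1; dominance-dominated scenarios use 5).
Low-N genotypic values arise from per-QTL effects correlated with the
ideal-N effects at `gen_cor = 0.8` — at the *effect* level, so that both
regimes' genetic values are marker-determined and the true LNTI is itself
a genomic quantity (correlating the genetic values through a non-genomic
random vector instead would make the index largely unpredictable from
markers by construction). The residual standard deviation is solved from
the target plot heritability; checks carry fixed genotypic values plus a
check × environment term, matching the role checks play in the residual.
Parental-line values expose only the additive QTL content (no
heterozygotes exist in a line), plus noise at `line_h2`.

What the generator does not emulate: coalescent-grade LD decay,
genotype × environment interaction beyond the check × environment term,
multi-year cycles, and real-trial artefacts (spatial trend, missing
plots). Passing tests therefore validate the statistical machinery under
the stated architecture, not the magnitudes any particular field data set
would give.

## Validation battery and problem sizes

The published predictive abilities come from undeposited raw trial data,
so the acceptance layer checks properties instead, at sizes chosen to keep
the whole suite in minutes on one CPU: GBLUP against a ridge-regression
oracle (max |ΔGEBV| ≤ 1e-6 on 20 × 50); family-wise error of the
permutation threshold over 1,000 null replicates at n = 100, 200 markers,
100 permutations; Kolmogorov–Smirnov uniformity of null scan p-values at
1,000 markers; recovery of block/residual variances (10 augmented-design
replicates) and of the polygenic-to-residual ratio at n = 400; and the
headline qualitative pattern over 20 seeds of the full pipeline under the
stated study conditions — a polygenic (120 QTL), purely dominance trait,
35 + 15 parents with intra-group crosses, 300 hybrids, 1,200 markers,
plot-level trials adjusted per regime, LNTI as the response, and the four
best line-scan markers as the MAS set: no MAS variant predicts better
than chance, adding the line markers as fixed effects never beats pure
GBLUP, and every genome-wide method outperforms every MAS variant.
Choosing these conditions matters, and each is the stated study
condition, not a convenience: with appreciable additive QTL content the
line scan finds
real QTL and MAS legitimately transfers; with an oligogenic architecture
a handful of markers captures parent-identity (general combining ability)
structure and again transfers; and with a low-noise proxy phenotype every
channel is amplified. Under the stated conditions — dominance-driven,
many small QTL, trial-level noise — the genome-wide methods land at
predictive abilities near 0.1 while MAS sits indistinguishable from zero,
the pattern the package exists to study. The only published numbers
reproduced digit-for-digit are the per-marker heritability table entries,
recomputed from their printed inputs by `scripts/acceptance.R`.

## Known limitations

Single-trait analysis only; additive kernels only for prediction (no
additive + dominance multi-kernel GP — deliberately, to mirror the design
under study); no spatial field-trend correction; the two-kernel GWAS null
model optimises variance ratios numerically and can be slow above a few
thousand samples; LD pruning is quadratic within windows and intended for
array-scale, not sequencing-scale, panels.
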