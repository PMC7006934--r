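# diallelgp

Genomic prediction and additive-dominance GWAS for partial-diallel maize
hybrids, centred on one question that matters to hybrid breeders: **do
marker-trait associations discovered in inbred parental lines help predict
the performance of their single-cross hybrids?** For traits driven by
dominance — such as tolerance to low nitrogen, measured by the
low-nitrogen tolerance index LNTI = (1 − GY_LN/GY_IN) × 100 — the effects a
marker shows in fully homozygous lines (where no heterozygote ever exists)
need not say anything about heterozygous hybrids. `diallelgp` provides the
complete pipeline to study this: trial analysis, marker QC, kernel
construction, eight prediction methods with cross-validation,
additive-dominance association scans with permutation thresholds, and a
seeded synthetic-data generator so every step can be validated end to end.

## Models

Plot yields from unreplicated augmented-block trials are adjusted per
nitrogen regime with the mixed model

    y = X b + V u + e,  u ~ N(0, I s2_b),  e ~ N(0, I s2_e)

where checks, hybrids, environments (site x year) and check x environment
are fixed and blocks-within-environment random; replicated checks identify
the block and residual variances. Heritability is reported at plot level,
`H2 = s2_g / (s2_g + s2_ga + s2_e)`, and at entry-mean level,
`H2 = s2_g / (s2_g + s2_ga/a + s2_e/(a r))`, with `a` environments and `r`
replications.

Prediction of the adjusted phenotype `g` uses:

* **MAS** — `g = mu + M f + e`: ordinary regression on the significant
  markers, coded additively ({−1,0,1}), by dominance ({0,1,0}) or both;
* **BayesB** — `g = mu + Z b + e` with each marker effect zero with
  probability `pi` (Beta prior) or drawn from a scaled-t slab;
* **GBLUP / RKHS** — `g = mu + h + e`, `h ~ N(0, s2 G)` with the
  trace-normalised kernel `G_Z = Z Z' n / trace(Z Z')` or its Gaussian
  transform `K = exp(−h d_ij / median d)`;
* **MAS|GBLUP / MAS|RKHS** — `g = mu + M f + s + e` with
  `s ~ N(0, s2 G_W)`, the kernel built from the non-significant markers
  only.

Predictive ability is the mean Pearson correlation between test-set
phenotypes and GEBVs over repeated 75/25 training-testing splits.

The hybrid association scan fits, per marker,
`g = mu + PCs + S m + polygenic + e` with additive (`S_A`), dominance
(`S_D`) or both codings, polygenic control through the VanRaden additive
kinship `G_A = Z Z' / 2 Σ p_j(1−p_j)` and/or the dominance kinship
`G_D = W W' / Σ 2 p_j q_j (1 − p_j q_j)`, a family-wise significance
threshold from 400 phenotype permutations (the α-quantile of the minimum-p
distribution), and model choice by the genomic inflation factor λ.
Significant markers get a heritability decomposition:
`H2 = 2pq α²/Var(g)` (additive scan), `H2 = 2pq[a + d(q−p)]²/Var(g)` and
`H2 = 4p²q²d²/Var(g)` (additive + dominance scan), with
`α = a + d(q − p)` the allele substitution effect.

## Worked example

A desk-scale synthetic experiment — 32 parents in two heterotic groups,
240 single crosses, 1,500 markers, trials at 2 sites x 2 years x 2 N
regimes:

```r
library(diallelgp)

cfg <- sim_config(n_parents_group1 = 20, n_parents_group2 = 12,
                  n_markers = 1500, n_chromosomes = 10, n_hybrids = 240,
                  n_qtl = 80, dominance_ratio = 1, seed = 2025)
parents <- simulate_parents(cfg)
design  <- make_diallel(parents, cfg$n_hybrids, seed = cfg$seed,
                        allow_intragroup = TRUE)
qc   <- qc_pipeline(parents, design, seed = cfg$seed)
sim  <- simulate_phenotypes(qc$hybrids, design, cfg)
adj  <- adjusted_means(sim$plots)
y    <- setNames(adj$lnti, adj$entry_id)[rownames(qc$hybrids$dosage)]

cor(adj$lnti, sim$truth$lnti_true[match(adj$entry_id,
                                        sim$truth$hybrid_id)])
#> [1] 0.3265388

gp_cross_validate(y, "gblup", qc$hybrids, n_reps = 8, seed = 3)
#> <cv_result GBLUP: mean PA 0.094 (sd 0.110, 8 reps, t-test p 0.0465)>
```

The two numbers tell the LNTI story in miniature: the index is a ratio of
two noisy adjusted means, so even the *adjusted* phenotype correlates only
0.33 with the true genotypic index, and genome-wide prediction of it tops
out near 0.1 — a low ceiling set by trait heritability, not by the
prediction machinery (cross-validating the noiseless true index on the
same kernels gives ≈ 0.66).

`run_diallel_experiment(cfg)` chains everything — QC, adjustment, a
parental-line scan whose best markers become the MAS fixed effects, all
eight prediction methods, and the hybrid additive-dominance scan with
permutation threshold and marker heritabilities — and returns the stage
tables plus a written manifest when `out_dir` is given.
`autoplot()` methods produce Manhattan, QQ and predictive-ability plots.

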