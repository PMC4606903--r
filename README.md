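# pathpre

**Partitioned liability-scale heritability for ascertained case–control
cohorts.**

Complex diseases such as age-related macular degeneration carry a large
polygenic component beyond their genome-wide-significant risk SNPs. A
standard way to ask *which biological mechanisms* harbour that residual
signal is pathway-partitioned GREML: split the genotyped SNPs into a
pathway set (SNPs in and around the genes of a mechanism) and a remainder
set, fit both genetic relationship matrices (GRMs) jointly in a mixed
linear model on the observed 0/1 scale, test the pathway component by
likelihood-ratio test, and transform the estimate to the liability scale.
`pathpre` implements that pipeline end to end for R, together with a
synthetic-cohort generator so every stage is testable without restricted
patient data.

## The model in brief

For disease status `y` (0/1), covariates `X`, and SNP-set GRMs
`G_1, ..., G_c`:

    y = Xb + sum_i g_i + e,   g_i ~ N(0, s2_i G_i),   e ~ N(0, s2_e I)

* GRM: `A_jk = (1/m) sum_s (x_sj - 2p_s)(x_sk - 2p_s) / (2 p_s (1-p_s))`,
  with GCTA-compatible binary serialization (`.grm.bin` / `.grm.N.bin` /
  `.grm.id`).
* Estimation: EM-REML (monotone in the restricted likelihood; SQUAREM
  acceleration with a monotonicity safeguard), SEs from the
  average-information matrix at the solution.
* Testing: boundary LRT, `p = 1/2 P(chi2_1 > lambda)`.
* Liability scale: `h2_l = h2_o * K^2(1-K)^2 / (P(1-P) z^2)` at population
  prevalence `K` (constant or age-weighted from a stratified table) and
  sample case fraction `P`.
* Partitioning: gene bodies, ±50 kb flanks, and a (50 kb, 250 kb]
  open-chromatin (DHS) annulus; known-risk-region carve-outs (SNP ± 5 kb /
  50 kb) and LD-based exclusions (r² ≥ 0.10/0.05/0.01 within 500 kb, or a
  1 Mb blanket).
* QC: SNP filters (autosomes, call rate ≥ 95%, MAF ≥ 1%, HWE p ≥ 1e-6,
  duplicate positions) and sample filters (call rate ≥ 90%, required
  fields), every step recorded in an exclusion ledger whose arithmetic is
  validated exactly.

## Worked example

Simulate an ascertained cohort whose liability is 35% driven by one
pathway, then estimate each pathway's proportion of risk explained (PRE):

```r
library(pathpre)

spec <- sim_spec(n_population = 9000, m_snps = 800, n_sample = 600,
                 prevalence_K = 0.1, target_case_fraction = 0.6,
                 causal_spec = c(pw1 = 0.35),
                 covariate_effects = c(sex = 0.02, smoke = 0.03),
                 seed = 81)
cohort <- simulate_cohort(spec, n_genes = 18, dhs_density = 0.1)
ann <- cohort$annotations

res <- run_pathway_analysis(cohort, ann$genes, ann$pathways, dhs = ann$dhs,
                            strategy = "flank50", K = 0.1,
                            covariates = "sex", n_pcs = 2)
print(res[, c("pathway", "n_snps_pathway", "pre_liability", "se_liability",
              "p", "per_snp_pre")], row.names = FALSE)
```

```
 pathway n_snps_pathway pre_liability se_liability            p  per_snp_pre
     pw1            283   0.371812174   0.05429947 2.923947e-15 1.313824e-03
     pw2            301   0.066842206   0.04476143 5.448856e-02 2.220671e-04
     pw3            283   0.006171166   0.04472622 5.000000e-01 2.180624e-05
```

The causal pathway `pw1` (realized liability fraction 0.350 in this draw)
is recovered at 0.372 ± 0.054 with LRT p ≈ 3e-15; the two non-causal
pathways are near zero and non-significant (a component at the variance
floor reports the boundary p-value 0.5). `pre_liability` is
`pre_obs * c` with `c` from the run's prevalence and case fraction;
`per_snp_pre` divides by the pathway SNP count.

The numbered scripts under `analysis/` run the full study-shaped workflow
on a 1,813-individual synthetic cohort — simulation, QC ledgers, partition
construction, pathway GREML across all three strategies, risk-SNP and
LD-exclusion analyses, overlap decomposition, smoking adjustment and
stratification — writing tables to `results/`.

## Package layout

| Where | What |
| --- | --- |
| `R/simcohort.R` | cohort generator (genotypes, annotations, liability phenotype, ascertainment) |
| `R/qc.R` | SNP/sample filters and exclusion ledgers |
| `R/annotate.R` | pathway partitions, risk-region and LD exclusions, overlaps |
| `R/grm.R` | GRM computation and binary GRM I/O |
| `R/greml.R` | EM-REML, boundary LRT, GRM principal components |
| `R/liability.R` | prevalence weighting and liability transformation |
| `R/pipeline.R` | per-pathway / risk-SNP / overlap drivers |
| `R/validate.R` | the end-to-end parameter-recovery experiment |
| `R/plink-io.R` | PLINK1 BED/BIM/FAM, phenotype tables, BED4 intervals |
| `vignettes/` | methods vignette: model, assumptions, numerical choices, limitations |

See the methods vignette for the estimator's known limitation under strong
ascertainment (large liability fractions are conservatively biased) and
the reasoning behind the validation design.
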