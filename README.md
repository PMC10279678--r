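# plsmet

Partial least squares (PLS) genomic prediction for multi-environment
plant-breeding trials, in single-trait (ST) and multi-trait (MT) form.

Breeding programs phenotype a few hundred genotyped lines in a handful of
location-year environments and must predict everything else: unmeasured
line-environment combinations ("tested lines in tested environments") and
whole future environments ("tested lines in untested environments"). The
predictor matrix is wide and collinear — thousands of SNPs, kernel-derived
columns — which is exactly the regime PLS was built for, and the
multi-trait extension is free because the response is simply a matrix.

## The method

With `J` lines genotyped at `r` SNPs (dosages 0/1/2 in `M`) and records in
`I` environments, relationship information enters PLS through the predictor
columns:

- line kernel `K_L = M Mᵀ / r`, environment kernel `K_E = I`, interaction
  kernel `K_LE = K_E ⊗ K_L` (environment-major Kronecker grid);
- input matrix `X = [X_E, X_g L_g, X_gE L_gE]`, where `X_E`, `X_g`, `X_gE`
  are record-level incidence matrices and `L_g = K_L^{1/2}`,
  `L_gE = K_LE^{1/2}` are symmetric eigendecomposition square roots.

The PLS fit extracts components from centered blocks `E = X_c`, `F = Y_c`:
per component the leading singular pair of `S = EᵀF` gives weights `w, q`;
scores `t = Ew` (unit norm), `u = Fq`; loadings `p = Eᵀt`, `q_y = Fᵀt`;
deflation `E ← E − tpᵀ`, `F ← F − tq_yᵀ`. Coefficients are recovered as
`R = W(PᵀW)⁻¹`, `T = X_c R`, `b = (TᵀT)⁻¹TᵀY_c`, `B = Rb`, and predictions
are `Ŷ = X_new B + ȳ`.

Accuracy is evaluated by Pearson correlation (ρ) and normalized RMSE
(`NRMSE = RMSE/ȳ`) under two schemes, each with the number of components
tuned by a nested inner five-fold NRMSE search:

- **5FCV** — five random folds over line-by-environment records;
- **LOEO** — each environment held out entirely in turn.

A synthetic data generator (`sim_config()`, `simulate_genotypes()`,
`simulate_phenotypes()`) emulates a potato-breeding MET — by default 253
lines × 2503 SNPs × 6 environments and three correlated traits with
heritabilities 0.93/0.84/0.78 — and returns the true generating signals so
recovery can be verified. See the vignette
(`vignettes/pls-genomic-prediction.Rmd`) for the model, assumptions and
design choices.

## Worked example

```r
library(plsmet)

cfg <- sim_config(n_lines = 80, n_markers = 300, n_envs = 4,
                  trait_heritabilities = c(0.9, 0.8), genetic_correlation = 0.6,
                  gxe_variance_ratio = 0.05, seed = 42)
geno <- simulate_genotypes(cfg)          # 80 x 300 dosage matrix
sim  <- simulate_phenotypes(geno, cfg)   # 320 records, 2 traits

fcv <- run_5fcv(geno, sim$pheno, model_type = "MT", seed = 42)
fcv
#> 5FCV cross-validation, MT-PLS (2 traits, 4 environments)
#>       env  trait    rho   rho_se   nrmse  nrmse_se
#> 1      E1 trait1 0.9016 0.014529 0.02515 0.0009182
#> 2      E2 trait1 0.8948 0.020833 0.02143 0.0019518
#> 3      E3 trait1 0.8806 0.030890 0.02711 0.0031213
#> 4      E4 trait1 0.8788 0.024720 0.02220 0.0013897
#> 5      E1 trait2 0.8758 0.030436 0.02118 0.0031913
#> 6      E2 trait2 0.7331 0.026890 0.02847 0.0023165
#> 7      E3 trait2 0.7871 0.043569 0.02507 0.0019218
#> 8      E4 trait2 0.7803 0.047987 0.02869 0.0019301
#> 9  Across trait1 0.9542 0.005202 0.02384 0.0011246
#> 10 Across trait2 0.8530 0.013943 0.02664 0.0009098
```

Each row is one environment (plus the pooled `Across` row): `rho` is the
correlation between observed and predicted phenotypes in held-out records
(averaged over the five folds, SE = sd/√5), `nrmse` the fold-averaged
normalized prediction error. The high-heritability trait (h² = 0.9) is
predicted better than the h² = 0.8 trait, as expected.

Holding out whole environments is harder on the error scale — the held-out
environment's mean level is unseen, so NRMSE grows even where within-
environment ranking (ρ) stays good:

```r
summary(run_loeo(geno, sim$pheno, model_type = "MT", seed = 42))
#>       env  trait       rho      rho_se      nrmse    nrmse_se
#> 1      E1 trait1 0.9359667          NA 0.07546446          NA
#> ...
#> 9  Across trait1 0.9319185 0.002082476 0.08265215 0.007960360
#> 10 Across trait2 0.8424738 0.010099498 0.04234353 0.006418904
```

(LOEO per-environment cells are single values, hence no SE.)

File-based workflows use `write_simulation()` / `run_config()` /
`run_pipeline()`, or the command-line front end
`inst/cli/plsmet.R` (`simulate`, `cv`, `report` subcommands). Genotypes are
read from dosage TSV or biallelic VCF, phenotypes from long-format CSV.

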