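---
title: "Multi-environment genomic prediction with partial least squares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-environment genomic prediction with partial least squares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

Genomic selection in a crop breeding program asks: given genome-wide SNP
dosages for a set of lines and phenotypes measured on some of them in some
environments, how well can we predict the phenotypes we did not measure?
Two variants of the question matter in multi-environment trials (METs):

* **tested lines in tested environments** — every environment contributes
  records to training; evaluated here by random five-fold cross-validation
  over line-by-environment records (5FCV);
* **tested lines in untested environments** — a whole environment (a
  location-year) is held out; evaluated by leave-one-environment-out
  cross-validation (LOEO). This is the harder problem: nothing about the
  held-out environment's mean level or its genotype-by-environment (G×E)
  pattern is available at training time.

`plsmet` answers both with partial least squares (PLS) regression, in
single-trait (ST, one model per trait) and multi-trait (MT, one joint model
for all traits) form. PLS is attractive for breeding data because the
predictor matrix is wide and strongly collinear (markers in LD, kernel
columns by construction), and because the multi-trait extension is free:
the response simply becomes a matrix.

## Model and input construction

Phenotypes are modelled through the additive decomposition
*environment + genotype + genotype-by-environment*. PLS cannot ingest a
relationship matrix directly the way a mixed model does, so relationship
information enters through the predictor columns. With `J` lines, `I`
environments and `r` markers:

* line kernel `K_L = M Mᵀ / r` from the raw 0/1/2 dosage matrix `M`
  (allele-frequency centering is available behind a flag, but the raw form
  is the default — the kernel is a Gram matrix either way, so positive
  semidefiniteness is guaranteed);
* environment kernel `K_E = I` (environments carry no covariates, only
  incidence positions);
* interaction kernel `K_LE = K_E ⊗ K_L`, Kronecker product on the full
  environment-major grid.

Each record contributes a row of the input matrix

```
X = [ X_E , X_g L_g , X_gE L_gE ]
```

where `X_E`, `X_g`, `X_gE` are one-hot incidence matrices and `L_g`,
`L_gE` are symmetric square roots of `K_L`, `K_LE`. The square roots are
computed by eigendecomposition with eigenvalues below `1e-10 · λ_max`
clipped to zero: `K_LE` is rank-deficient by construction (rank at most
`I · rank(K_L)`), so a Cholesky factor does not exist and the symmetric
root is the right object. Post-multiplying an incidence block by the kernel
root makes the Gram matrix of that block equal the kernel on the observed
records — the PLS analogue of putting the kernel into a mixed-model
covariance. Eigenvector signs are fixed (largest-magnitude entry positive)
so factors are reproducible across BLAS implementations. `X_gE` keeps its
columns for unobserved (environment, line) cells so that its column space
always aligns with the full-grid `L_gE`.

## The PLS fit

Components are extracted from the centered blocks `E = X_c`, `F = Y_c`
(scaling is optional and off by default). Per component: the leading
left/right singular vectors of `S = EᵀF` give the weights `w` and `q` — a
single SVD of `S`, which is exactly the leading-eigenvector computation on
`SSᵀ` and `SᵀS` but numerically better behaved; scores `t = Ew`
(unit-normalized) and `u = Fq`; loadings `p = Eᵀt`, `q_y = Fᵀt`; deflation
`E ← E − t pᵀ`, `F ← F − t q_yᵀ`. The y-scores `u` are computed and stored
but play no further role — they are part of the algorithm's state, not of
the predictor. Extraction stops early when `‖E‖_F < 1e-12 ‖X_c‖_F`.

After extraction the model is re-expressed on the original predictors:
`R = W (PᵀW)⁻¹` (a least-squares solve; `PᵀW` is unit upper triangular in
exact arithmetic), `T = X_c R`, `b = (TᵀT)⁻¹ Tᵀ Y_c`, `B = R b`, and
predictions are `Ŷ = X_new B + ȳ`. Because the score columns are
orthonormal, the inner coefficients `b` are componentwise: a model fitted
with `a_max` components truncated to `a < a_max` equals a refit at `a`
exactly. The tuning loop exploits this — one fit per inner fold instead of
one per fold per grid point — and a test asserts the truncation/refit
identity so the shortcut can never drift from the definition.

Component weights carry a sign ambiguity; the largest-magnitude entry of
each `w` is forced positive (with `q` flipped jointly, preserving
`S ≈ σ w qᵀ`), which fixes every downstream quantity deterministically
without changing `B`.

## Cross-validation and metrics

* **5FCV** partitions *records* (line × environment cells), not lines, into
  five seeded folds of near-equal size. A line may legitimately appear in
  training (in some environments) and testing (in others); this is the
  "tested lines in tested environments" setting, and it is the main reason
  5FCV accuracy exceeds LOEO accuracy.
* **LOEO** trains on `I − 1` environments and predicts the held-out one;
  the held-out environment's incidence columns are all-zero in training
  rows, so its main effect and its G×E pattern are genuinely unseen.
* The number of components is tuned inside each outer training set by an
  inner five-fold split, minimizing NRMSE averaged across traits and folds
  (NRMSE is scale-free, so traits on different scales average sensibly);
  ties go to the smallest count. The default grid is
  `1..min(30, n_train − 2, p)`.
* Metrics: Pearson correlation ρ and `NRMSE = RMSE / ȳ` between observed
  and predicted values. For 5FCV, per-environment and global cells are
  fold-wise values averaged over the five folds with SE = sd/√5; for LOEO,
  per-environment cells are single values (no SE) and the Across row is the
  mean over environments with SE = sd/√I. Undefined cells (fewer than three
  pairs, zero variance, near-zero observed mean) propagate as missing, and
  negative correlations are reported as-is. All summary cells are exactly
  recomputable from the stored record-level predictions via `cv_metrics()`.

Randomness policy: one master seed; outer folds and each fold's inner
split draw from named substreams, so ST and MT runs (and runs with extra
traits) share identical partitions. With one trait, the MT and ST pipelines
are record-for-record identical.

Records with a missing trait value are dropped complete-case for MT fits
and per-trait for ST fits; no imputation is attempted, since none is
defensible without knowing the missingness mechanism.

## The synthetic data generator

`sim_config()` / `simulate_genotypes()` / `simulate_phenotypes()` emulate a
mid-size potato breeding trial: by default 253 lines × 2503 unlinked
biallelic SNPs (allele frequencies uniform on 0.05–0.5), six environments
(three locations × two years), and three traits with within-environment
heritabilities 0.93, 0.84 and 0.78 — the heritability ordering of tuber
starch, total tuber weight and reducing sugars in Scandinavian potato
germplasm — with exchangeable genetic correlation 0.5.

The generating model per record is
`y = μ_t + E_env + g + ge + ε` with marker-linear additive values
`g = M_c α` (effects `α` i.i.d. Gaussian per trait, correlated across
traits through a square-root factor of the genetic correlation matrix).
Three conventions matter:

* **Variances are enforced empirically, not in expectation.** `g` is
  rescaled to realized variance exactly 1 per trait, `ge` to exactly
  `gxe_variance_ratio`, and `ε` to exactly `1/h² − 1 − gxe_variance_ratio`,
  so recovery tests have exact rather than stochastic targets. All
  variances are therefore in units of genetic variance.
* **Heritability is within-environment**: `h² = Var(g)/(Var(g) + Var(ge) +
  Var(ε))`. This bounds the G×E share: `gxe_variance_ratio ≤ 1/h² − 1`.
  With the default heritabilities (max 0.93) the bound is ≈ 0.075, so the
  default ratio is 0.05; configurations that violate the bound error
  immediately rather than silently clipping.
* **Trait means** default to 20, 25, 30 — well away from zero so that
  NRMSE, which divides by the observed mean, is stable.

What the generator does *not* emulate: linkage disequilibrium between
markers, tetrasomic inheritance and dosage uncertainty (potato is
autotetraploid; real dosage calls are noisier than this), field-design
structure (the generator produces one record per line × environment, as if
design-adjusted means were analysed), kinship-structured G×E (the `ge`
draws are independent across lines), and informative missingness. Passing
tests on this generator therefore demonstrate that the pipeline recovers
the signal structure it assumes — not that real potato data satisfy those
assumptions.

## Validation-study design choices

The test suite runs the full pipeline on scaled-down generator settings so
the whole suite stays interactive; the sizes are chosen to keep the
signal-to-sampling-noise ratio high enough for directional claims:

* signal recovery: 150 lines × 300 markers × 4 environments at h² = 0.9
  without G×E, against a pure-noise control (h² = 0.01);
* 5FCV-versus-LOEO ordering: 100 lines × 200 markers × **6 environments**
  (the study layout; with very few environments the realized spread of
  environment means is itself highly variable, which blurs the comparison),
  h² = 0.6, G×E share 0.5, environment-effect SD 2 — environment main
  effects larger than genetic effects, as is typical for METs;
* MT-versus-ST: two traits with genetic correlation 0.9 and heritabilities
  0.9/0.3, where borrowing strength should help the low-heritability trait.

The acceptance script (`scripts/acceptance.R`) runs both schemes and both
model types at the full default scale (253 × 2503 × 6, 1518 records,
input matrix 1518 × 1777).

## Numerical choices

* eigenvalue clip for kernel roots: `1e-10 · λ_max`; anything below
  `−1e-10 · λ_max` raises a non-PSD error instead of being absorbed;
* `PᵀW` solved with tolerance `1e-12`; singularity there indicates a
  degenerate component sequence and should fail loudly;
* early-stop threshold `1e-12` (relative Frobenius) on the deflated
  predictor block; the achieved component count is recorded and truncation
  handles grid entries above it;
* correlation cells need ≥ 3 pairs and nonzero variance; NRMSE needs
  `|ȳ| ≥ 1e-8 · sd(y)`.

## Known limitations

Accuracy on this generator is optimistic relative to real potato trials:
marker effects are exactly linear, dosages are error-free, and residuals
are Gaussian and homoscedastic. The G×E kernel can only help prediction
when G×E is kinship-structured, which the generator deliberately does not
impose — so LOEO results here chiefly measure the transfer of main genetic
effects. The NRMSE of a held-out environment is undefined if that
environment's observed mean is near zero; choose trait scales accordingly.
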