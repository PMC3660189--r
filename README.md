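# morphodisp

Landmark-based cranial disparity analysis for comparing the morphological
variance of two clades — built around the classic marsupial-versus-placental
question: does the marsupial reproductive strategy (suckling at a highly
altricial stage, which demands an early-ossifying oral apparatus)
developmentally constrain the evolution of the marsupial skull?

The package is aimed at geometric morphometricians and macroevolutionary
biologists who have 3D cranial landmark data for two groups and want to ask
whether one group is significantly less disparate than the other, overall
and within developmental or functional skull regions.

## What it computes

Given landmark configurations `X_i` (k landmarks × 3 coordinates per
specimen):

1. **Generalized Procrustes analysis (GPA).** Each configuration is
   centered, scaled to unit centroid size
   `CS = sqrt(sum_j ||x_j - x̄||²)`, and iteratively rotated to the running
   consensus (rotations by SVD, reflections excluded), leaving only shape.
2. **Shape PCA with allometric correction.** Principal components of the
   aligned coordinates; every retained PC score column is regressed on
   `log CS` (ordinary least squares) and the residuals re-decomposed by a
   second PCA, so corrected scores are linearly uncorrelated with size.
3. **Procrustes variance (disparity).** For a group G of n specimens,
   `V(G) = Σ_i d(X_i, mean(G))² / (n − 1)`, with `d` the partial Procrustes
   distance from the group mean shape.
4. **Delta-variance permutation test.** The statistic is
   `Δ = V(B) − V(A)`. The null pools the individual residual distances from
   their own group means, randomly reassigns them to the two groups, and
   recomputes Δ; `p = (b + 1)/(B + 1)` over B permutations (two-sided on
   |Δ| by default). Unequal sampling is corrected by bootstrapping each
   clade-by-sex stratum to the smallest stratum size (1,000 replicates by
   default) before disparity is quantified.
5. **Region batteries.** A built-in 32-landmark cranial scheme assigns each
   landmark to the oral region, the non-oral viscerocranium, both, or the
   neurocranium; batteries test whole skull and regions (each region
   re-superimposed on its own landmarks), optionally per ecological group
   (diet, habitat, activity), with a Bonferroni threshold `α/m` over the m
   tests performed.
6. **Synthetic data with known truth.** A generator plants per-group
   tangent-space shape variance, allometry, log-normal sizes, sexes and
   ecological labels, so every stage above is testable without museum data.

## Worked example

```r
library(morphodisp)

spec <- synthetic_spec(seed = 42)   # marsupial-like vs placental-like defaults
ds   <- simulate_study(spec)        # 60 + 60 specimens, 32 landmarks
aligned <- gpa(ds)
space   <- remove_allometry(shape_pca(aligned))

res <- run_disparity_battery(
  ds, regions = c("whole_skull", "neurocranium", "viscerocranium", "oral"),
  groupings = clade_groupings(),
  plan = resampling_plan(n_bootstrap = 0, n_permutations = 999, seed = 1))
res[, c("region", "variance_a", "variance_b", "delta", "p_value", "significant")]
```

prints

```
          region variance_a variance_b  delta p_value significant
1    whole_skull     0.0184     0.0499 0.0314   0.001        TRUE
2   neurocranium     0.0223     0.0571 0.0348   0.001        TRUE
3 viscerocranium     0.0171     0.0464 0.0293   0.001        TRUE
4           oral     0.0166     0.0442 0.0276   0.001        TRUE
```

The marsupial-like group was simulated with planted Procrustes variance
0.018 and the placental-like group with 0.052; the battery recovers group
variances close to those values, a positive delta (group B more disparate),
and `p = 0.001` — the smallest value 999 permutations can resolve — in every
region. With `m = 4` tests the Bonferroni-adjusted threshold is
`0.01 / 4 = 0.0025`, so all four rows remain significant. (In real cranial
data the regions differ: that is the scientific question, not a property of
this homogeneous simulation.)

The same analysis runs from the command line:

```sh
Rscript inst/cli/morphodisp simulate --seed 42 --out study/
Rscript inst/cli/morphodisp run --config run.json --seed 1 --out results/
Rscript inst/cli/morphodisp pca --config run.json --out results/
```

where `run.json` points at the landmark, metadata and scheme files
(`{"landmarks": "study/landmarks.csv", "metadata": "study/metadata.csv"}`).
Every output directory carries a manifest with checksums, the seed, and a
configuration hash; re-running an unchanged configuration is bit-identical.

## Layout

- `R/` — landmark I/O and schemes, superimposition, shape space, disparity
  tests, synthetic data, pipeline/CLI.
- `vignettes/cranial-disparity.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations.
- `tests/testthat/` — unit, property and acceptance suites with independent
  oracles (Euler-grid rotation search, exhaustive permutation enumeration,
  brute-force hulls).
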