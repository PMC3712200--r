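# dosepath

Dose-response transcriptomics in R: monotone expression-pattern mining,
gene-set enrichment, topology-based pathway impact analysis, signed
pathway-activity scoring, pathway-similarity clustering, and survival-gene
cross-tabulation — with synthetic-data generators that emulate the full
study design so every stage is testable end to end.

The package is written for analysts working with short ordered treatment
series (a vehicle control plus a few increasing doses, one array per dose)
who want the complete chain from raw probe intensities to pathway-level and
prognostic conclusions, reproducibly seeded and tibble-native throughout.

## What it computes

* **Preprocessing** — background filter (signal ≥ 1.4× local background),
  quantile normalization, log2 treated/control ratios, duplicate-probe
  averaging, and fold-change selection (|log2 ratio| ≥ 1 in ≥ 1 sample).
* **Pattern mining** — integer model profiles over dose ranks anchored at 0
  (all trajectories with steps in {−c..c}; greedy max–min selection of m
  representatives), Pearson-correlation assignment of every gene, and
  per-profile permutation significance (B = 1,000 within-gene dose
  permutations). Significant monotone profiles form the Down-/Up-patterns.
* **Enrichment** — one-sided hypergeometric over-representation
  P(X ≥ k) per gene set with Benjamini–Hochberg FDR.
* **Pathway impact** — for each signed topology: over-representation
  evidence P_NDE; perturbation evidence P_PERT from the linear system
  PF = ΔE + B·PF (B the out-degree-normalized signed influence matrix,
  tA = Σ(PF − ΔE), bootstrap n = 3,000); combined global
  P_G = c − c·ln c with c = P_NDE·P_PERT; Bonferroni/FDR classes at 1%.
* **Pathway activity** — A_p(s) = Σ w_g·x_gs with activator/repressor
  weights ±1, per-pathway z-scoring, a size- and sign-matched random-set
  permutation FDR (screen at 0.05), and average-linkage clustering on
  correlation distance.
* **Similarity** — Jaccard matrix J = |∩|/|∪| over pathway memberships,
  clustered on 1 − J, with top-dose activities merged as annotation.
* **Survival** — univariate Cox (Newton–Raphson, Breslow ties), permutation
  p-values, screening at p < 0.05, the 2×2 pattern-vs-hazard-direction
  cross-tabulation, and an exact two-sided Fisher test (minimum-likelihood
  convention).

## Worked example

Simulate a four-dose design with planted monotone genes, mine the patterns,
and screen pathway activities:

```r
library(dosepath)

truth <- planted_truth(n_genes = 1000, frac_up = 0.1, frac_down = 0.1,
                       effect_size = 3, noise_sd = 0.5)
expr <- simulate_dose_expression(dose_design(), truth, seed = 1)

fit <- mine_patterns(expr, n_permutations = 1000, seed = 2)
fit
#> <pattern_fit> 1000 genes over 20 profiles | 85 Down-pattern, 85 Up-pattern genes (FDR < 0.001 )

dplyr::filter(tidy(fit), significant)
#> # A tibble: 4 × 7
#>   profile_id class n_genes expected eo_fdr   perm_p significant
#>        <int> <chr>   <int>    <dbl>  <dbl>    <dbl> <lgl>
#> 1          1 down       53     16.2  0.305 0.000500 TRUE
#> 2          2 up         46     14.3  0.310 0.000500 TRUE
#> 3         14 up         39     19.1  0.491 0.000500 TRUE
#> 4         15 down       32     17.0  0.530 0.000500 TRUE
```

Four monotone profiles are never reached by the 1,000-round permutation
null (`perm_p` = 0.5/1001 ≈ 0.0005 < 0.001); their member genes form the
Down-/Up-patterns. `n_genes` is the observed member count and `expected` the
count a random dose ordering would produce, so e.g. profile 1 holds about
three times more genes than chance would put there.

The packaged survival-gene table (98 dose-responsive genes screened at
log-rank p < 0.05 in a public lung-cancer cohort) reproduces the published
reciprocity test:

```r
ct <- cross_tabulate(survival_gene_table())
ct
#>        hazard
#> pattern HR>1 HR<1
#>    down   32   16
#>    up     24   26
#> odds ratio = 2.167, two-sided Fisher p = 0.06973
```

Down-pattern genes are enriched for high-hazard genes and Up-pattern genes
for protective ones (odds ratio 2.17), marginally significant at p ≈ 0.069 —
the treatment tends to suppress risk genes and induce protective ones.

Plotting: `autoplot(fit)` shows the significant profiles,
`plot_activity_heatmap()` the clustered activity matrix, `autoplot()` on a
pathway-impact fit the P_NDE/P_PERT evidence plane, and `autoplot()` on a
similarity clustering the ordered Jaccard heatmap with activities on the
diagonal.

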