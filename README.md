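# fruitniche

Habitat selection and fruit-resource partitioning analysis for sympatric
frugivores — built for the classic two-ape study design in which western
lowland gorillas and central chimpanzees share a forest, their nests are
counted along transects, their diets are reconstructed from seeds in fecal
samples, and fruit availability is tracked by monthly phenology scores and
botanical plot inventories.

The package is aimed at field ecologists who have (or want to simulate) the
six tables such a study produces, and who want the full inference chain from
raw records to classified resources in one reproducible pipeline:

1. **Habitat selection** — Manly design-1 selectivity ratios per season.
   For habitat *i* among *m* types, with *r_i* the proportion of nests and
   *p_i* the proportion of availability,

   W_i = (r_i/p_i) / Σ_k (r_k/p_k),  W′_i = m·W_i,

   with a chi-squared goodness-of-fit gate and Bonferroni-adjusted intervals
   on W′ classifying each habitat preferred / avoided / proportional.
2. **Fruit preference scoring** — stem density D_i = Σ_k n_ik/(K·S); monthly
   Fruit Availability Potential FAP_ij = (Σ_n SS·B / N_i)·D_i from phenology
   scores and basal areas; fruit-mass reconstruction from fecal seed counts
   (seeds below the per-fruit mean count as one fruit, otherwise round up);
   Mean Consumption Score MCS_ij = (QF share) × (sample frequency); and the
   Global Importance Score GIS_i = (Σ_j MCS_ij/FAP_ij)/J × Pe_i, which ranks
   fruit taxa by consumption relative to availability.
3. **Fallback/preferred classification** — seasons split into high/low total
   fruit availability; fallback species fruit in ≥3 seasons, are more
   available in high seasons yet more consumed in low seasons; fallback is
   assigned before preferred (list size = classified taxa / 3); statuses
   collapse to six plant consumption traits.
4. **Ordination and seasonal tests** — correspondence analysis of the
   habitat × trait stem-count table (inertia = χ²/n, deviation tables with
   zero margins), plus PERMANOVA and dispersion-homogeneity tests on
   Bray–Curtis dissimilarities of monthly FAP/MCS profiles across seasons.
5. **Synthetic data** — a seeded generator emulating the whole field design
   with known ground truth (true preference ranks, designed fallback taxa,
   true habitat selection weights) for end-to-end validation.

See `vignette("fruitniche-methods")` for the models, assumptions, parameter
defaults and design choices.

## Worked example

```r
library(fruitniche)

gen <- generate_dataset(generator_config(), seed = 7)  # six tables + truth
run <- run_all(gen$dataset, n_perm = 999, seed = 7)    # full pipeline

run$selection$gorilla$LDS
#> <manly_selection>  n = 200 nests over 5 habitats
#>   chi-squared GOF: chi2 = 201.481, df = 4, p = 1.805e-42
#> # A tibble: 5 × 10
#>   habitat     n     r      p      W W_prime     se ci_low ci_high class
#>   <chr>   <dbl> <dbl>  <dbl>  <dbl>   <dbl>  <dbl>  <dbl>   <dbl> <chr>
#> 1 MF         37 0.185 0.461  0.0630   0.315 0.0467  0.194   0.435 avoided
#> 2 YSF        31 0.155 0.187  0.130    0.652 0.108   0.375   0.929 avoided
#> 3 LG         21 0.105 0.0829 0.199    0.994 0.205   0.465   1.52  proportional
#> 4 SW         98 0.49  0.147  0.525    2.62  0.189   2.14    3.11  preferred
#> 5 RF         13 0.065 0.122  0.0833   0.417 0.112   0.129   0.704 avoided
```

The long-dry-season gorilla result: 98 of 200 nests fell in swamp (SW)
against 14.7% availability, giving W′ = 2.62 with a Bonferroni interval
entirely above 1 — swamp is preferred — while mature forest (W′ = 0.315) and
riparian forest are avoided; the global χ² (201.5, df 4) licenses those
per-habitat calls. The generator's truth for this dataset was SW 2.4, MF 0.4,
RF 0.4, LG 1.

```r
head(run$scores$gis$chimpanzee[, c("taxon", "gis", "rank", "pe", "status")], 5)
#> # A tibble: 5 × 5
#>   taxon      gis  rank    pe status
#>   <chr>    <dbl> <int> <dbl> <chr>
#> 1 taxon_02  728.     1     1 classified
#> 2 taxon_01  248.     2     1 classified
#> 3 taxon_09  224.     3     1 classified
#> 4 taxon_03  150.     4     1 classified
#> 5 taxon_04  149.     5     1 classified
```

GIS ranks the chimpanzee's fruit preferences; `pe` is the fraction of
fruiting months in which the taxon was eaten. Designed fallback taxa
(here 02, 09, 16) rise in rank because their consumption is concentrated
where availability is scarce.

```r
run$traits
#> <trait_assignment>
#>        Fallback apes                 none Preferred chimpanzee
#>                    3                    3                    7
#>    Preferred gorilla
#>                    7

run
#> <fruitniche_run>
#>   0 empty plots excluded; trait CA axes 1-2: 100.00%
#>   PERMANOVA fap: F = 28.792, p = 0.001; dispersion p = 0.015
#>   PERMANOVA mcs_gorilla: F = 7.879, p = 0.004; dispersion p = 0.227
#>   PERMANOVA mcs_chimpanzee: F = 19.790, p = 0.005; dispersion p = 0.365
```

All three designed fallback taxa are recovered as "Fallback apes", the first
two correspondence-analysis axes carry essentially all of the
habitat-by-trait inertia, and the PERMANOVAs confirm that monthly fruit
availability and consumption profiles differ between seasons. Results are
written to CSV with `write_results(run, "out/")`; datasets round-trip through
`write_dataset()` / `load_dataset()`.

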