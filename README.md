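# tftgenrich

Transcription-factor target-gene (TFTG) enrichment analysis of differential
chemotherapy response, plus xenograft growth kinetics.

## What it is for

Colorectal tumors contain phenotypically distinct cancer-cell populations —
a CD44⁺/CD166⁺ compartment enriched in cancer stem cells (CSC) and a
CD44⁻/CD166⁻ non-tumorigenic (NT) compartment — that can respond very
differently to chemotherapy. Given a small 2×2 factorial expression
experiment (treatment × phenotype, replicated; e.g. 8 arrays), this package
identifies the transcription factors whose target programs shift
*asymmetrically* between the two phenotypes after drug exposure, and
quantifies chemo-sensitization in xenograft experiments from caliper
measurements. It is aimed at computational biologists analyzing sorted-
population expression data from treated vs. untreated tumors.

## The method

Per gene *g*, log2 expression is modelled as

    x_gijr = mu_g + d_gi + c_gj + e_gij + eps_gijr

with treatment *i*, phenotype *j*, replicate *r*. Under reference-level
coding (control, NT as baselines) the interaction *e* is the
difference-of-differences

    e = (mean[CSC, drug] − mean[CSC, ctrl]) − (mean[NT, drug] − mean[NT, ctrl]),

the degree to which the drug response differs between phenotypes. Genes in
the top and bottom 5% of the *e* ranking are called **responsive**, and
each TF target set (or pathway) is tested for overlap with the responsive
set by a two-tailed Fisher exact test, with sample odds ratios
(Haldane–Anscombe-corrected on zero cells), directional per-tail odds
ratios, a conservative fixed cutoff p < 10⁻⁵ for TF compendia and
Benjamini–Hochberg q-values for pathway collections. For a chosen factor,
per-gene drug fold-changes are contrasted between its targets and
non-targets (means, 95% CIs, Welch t-tests). The growth module computes
ellipsoid tumor volumes V = L·W·H·π/6, per-tumor exponential growth rates,
fold-increases, and the vector × treatment interaction ANOVA. A seeded
synthetic-data generator with a planted "dampened induction" program makes
the whole pipeline testable end to end.

## Worked example

```r
library(tftgenrich)

expt <- simulate_experiment(simulation_config(
  n_genes = 2000, n_tfs = 10, targets_per_tf = 100, seed = 42
))
fits <- fit_interactions(expt$matrix, expt$design)
sel  <- rank_and_select(fits, fraction = 0.05)
enr  <- rank_tfs(enrich_sets(sel, expt$sets, measured = rownames(expt$matrix)))
head(dplyr::select(enr, set_name, a, odds_ratio, or_top, or_bottom, p_value, significant), 3)
#> # A tibble: 3 × 7
#>   set_name     a odds_ratio or_top or_bottom    p_value significant
#>   <chr>    <int>      <dbl>  <dbl>     <dbl>      <dbl> <lgl>
#> 1 TF001       26      3.70   0.103     8.20  0.00000191 TRUE
#> 2 TF005        4      0.333  0.702     0.137 0.0242     FALSE
#> 3 TF006        5      0.426  0.451     0.433 0.0817     FALSE
```

The planted factor (`TF001`) ranks first: 26 of its 100 targets fall in the
responsive set (odds ratio 3.7, p ≈ 2×10⁻⁶, below the 10⁻⁵ cutoff), and the
directional ratios show the signal sits in the *bottom* tail — its targets
are induced less in the CSC phenotype, exactly the planted dampening.

```r
targets <- expt$sets$genes[[match(expt$config$active_tf, expt$sets$set_name)]]
fc <- fold_changes(expt$matrix, expt$design, targets = targets)
glance(summarize_by_target(fc))
#> # A tibble: 1 × 4
#>   delta_of_deltas welch_t welch_df  welch_p
#>             <dbl>   <dbl>    <dbl>    <dbl>
#> 1           0.611    18.2     120. 2.99e-36
```

The recovered shift of the target program (0.61 log2 units) matches the
planted dampening of 0.6, and the Welch test against non-targets is
decisive. `plot_volcano(enr)`, `plot_fold_changes(fc)` and
`plot_target_summary()` draw the corresponding figures;
`run_pipeline()` wires all stages (real or simulated input) into an output
directory with a JSON manifest.

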