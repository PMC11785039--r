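---
title: "Methods: inferring differential chemotherapy response of transcription-factor programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring differential chemotherapy response of transcription-factor programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tftgenrich)
library(dplyr)
```

## The scientific problem

Colorectal tumors harbor phenotypically distinct cancer-cell populations:
a CD44^+^/CD166^+^ "bottom-of-the-crypt" compartment enriched in cells with a
cancer stem cell (CSC) phenotype, and a CD44^neg^/CD166^neg^
"top-of-the-crypt" non-tumorigenic (NT) compartment. Chemotherapy can act
very differently on the two. This package implements the computational
pipeline for detecting that differential response from a small factorial
expression experiment — two treatments (control vs. irinotecan) crossed with
two sorted phenotypes, a couple of replicates each — and for tracing it back
to transcription factors (TFs) whose target programs shift asymmetrically
across the phenotypes. A second, independent component quantifies
chemo-sensitization in xenografts from caliper measurements.

## The factorial interaction model

For gene $g$, sample of treatment $i$, phenotype $j$ and replicate $r$, the
log2 expression level is modelled as

$$x_{gijr} = \mu_g + d_{gi} + c_{gj} + e_{gij} + \varepsilon_{gijr}.$$

The model as written is over-parameterized (one $d$ per treatment level,
one $c$ per phenotype), so `fit_gene_model()` imposes reference-level
(treatment-contrast) coding with the untreated control and the NT phenotype
as baselines. The four estimable parameters are then: $\mu$ (baseline log2
level), $d$ (drug effect in the reference phenotype), $c$ (phenotype offset
under control) and a scalar interaction $e$ — the difference-of-differences

$$e = (\bar x_{\text{CSC,drug}} - \bar x_{\text{CSC,ctrl}}) -
      (\bar x_{\text{NT,drug}} - \bar x_{\text{NT,ctrl}}),$$

positive when the drug response is stronger in the non-reference (CSC)
phenotype. On a saturated balanced design ordinary least squares reproduces
the cell means exactly, and the residual standard deviation uses $n-4$
degrees of freedom (zero when $n = 4$). `fit_interactions()` solves all
genes in one closed-form pass against the shared design matrix; the test
suite checks it against per-gene `lm()` fits and against the explicit
difference-of-differences.

Genes are then ranked by the raw signed $e$ — no standardization, no
per-gene significance filter, since the downstream enrichment consumes the
extreme tails, not p-values. `rank_and_select()` takes the top and bottom
5% by default ("responsive" genes), with $k = \max(1, \lfloor
\text{fraction} \times G \rfloor)$ per tail and lexicographic tie-breaking
at the boundary so the selection is deterministic and order-invariant.
Rank-based tails were chosen over interpolated percentile thresholds:
they are exact, deterministic, and match the "top 5% + bottom 5% of genes"
reading.

## Preprocessing

When starting from probe-level intensities, `preprocess_expression()`
quantile-normalizes across arrays, log2-transforms, then averages each
gene's uniquely-mapping probes ("promiscuous" probes mapping to more than
one gene are excluded entirely). Quantile normalization replaces each value
by the mean across columns of the values at its rank; within-column ties
receive the mean of the reference values over the tied rank range — the
dominant software convention, and the package's own implementation matches
`limma::normalizeQuantiles(ties = TRUE)` to 1e-12 in the tests. Whether
probe means are taken before or after the log transform is configurable
(`summarize_when`); the default is after, and both steps can be skipped for
gene-level log2 input. Background correction (as in full RMA) is out of
scope: input is assumed background-corrected or synthetic.

## Enrichment of TF target and pathway sets

The responsive set is tested for overlap with each gene set of a collection
(a TF-target compendium, or MSigDB-style pathway lists) by a two-tailed
Fisher exact test on the 2×2 table of responsive × set membership within a
universe. Conventions, each of which the tests pin down:

* **Two-tailed definition**: sum of hypergeometric probabilities of all
  tables with the observed margins whose point probability is at most the
  observed one (with a 1e-7 relative slack for floating-point ties) —
  checked exhaustively against an enumeration oracle for every margin
  combination with universe ≤ 25.
* **Odds ratio**: the sample cross-product $(ad)/(bc)$, with the
  Haldane–Anscombe half-count correction when any cell is zero, so volcano
  coordinates stay finite. Directional ratios (`or_top`, `or_bottom`)
  recompute the overlap using one tail at a time, revealing which phenotype
  drives an association.
* **Universe**: the intersection of measured genes with genes covered by
  the collection, by default. The alternative (`"measured"`, all measured
  genes) is a flag: both are defensible and the choice materially affects
  marginal counts, so it is explicit configuration rather than a silent
  default.
* **Significance**: TFs use a fixed conservative cutoff $p < 10^{-5}$,
  strict inequality — a Bonferroni-style bound for a compendium of fewer
  than 2,000 factors. Pathway collections instead get Benjamini–Hochberg
  q-values (`bh_qvalues()`, the step-up $q_{(i)} = \min_{j \ge i} m
  p_{(j)}/j$ capped at 1), verified against the naive quadratic definition.
* Sets with fewer than 2 members in the universe are flagged `too_small`
  and not tested.

## Target versus non-target response

For the factor of interest, `fold_changes()` computes each gene's drug
log2 fold-change per phenotype (difference of mean log2 levels,
treated minus control — never back-transformed), and `summarize_by_target()`
contrasts targets with non-targets: group means of `fc_ref`, `fc_alt` and
the per-gene `delta = fc_ref − fc_alt`, 95% t-based confidence intervals
($\bar x \pm t_{0.975, n-1} s/\sqrt n$; a t-interval on per-gene values is
the natural reading of an unspecified "95% CI"), and two-tailed Welch
t-tests with Welch–Satterthwaite degrees of freedom. The Welch test on the
per-gene `delta` is the headline comparison (its group-mean difference is
the `delta_of_deltas`); per-phenotype comparisons on `fc_ref` and `fc_alt`
are also emitted, since either reading of "compare the average
fold-changes" is plausible. Zero-variance or singleton strata yield flagged,
not fabricated, statistics. On balanced designs `fc_alt − fc_ref` equals
the fitted $e$ exactly — a cross-module identity the tests enforce.

## Tumor growth kinetics

`tumor_volume()` applies the ellipsoid caliper formula $V = L W H \pi/6$.
`fit_growth()` fits each tumor's exponential rate $k$ as the OLS slope of
$\ln V$ on day — per tumor, over all its recorded timepoints (per-tumor
rates feed the ANOVA naturally; optional `day_min`/`day_max` restrict the
fit to a treatment window), excluding zero volumes — plus the fold-increase
from the first to the last measurement. `interaction_anova()` then tests
sensitization as the vector × treatment interaction in a two-way
fixed-effects ANOVA on either endpoint. The interaction sum of squares is
computed as the RSS drop from the additive to the full model, which for
this highest-order term coincides with the sequential and, on balanced
data, partial decompositions — so balanced and unbalanced designs share one
code path. Repeated-measures modelling over time is deliberately out of
scope: it adds covariance-structure choices the endpoint analysis does not
need.

## The synthetic-data generator

`simulate_experiment()` is the test bed for everything upstream. Its
defaults are the study conditions of the assay it emulates: 8 samples
(2 treatments × 2 phenotypes × 2 replicates), 10,000 genes, 50 TFs with
200 targets each (disjoint by default; `overlap_fraction` shares a pool),
log2 baselines $\mathcal N(7, 1.5^2)$ (typical microarray log2
intensities), and one active factor whose targets carry a planted
treatment effect $d^\star = 1$ log2 unit that is *dampened* by
$\delta^\star = 0.6$ in the CSC phenotype — i.e. a true interaction of
$-0.6$ under the coding above. Non-target genes receive small random
$d, c, e$ effects ($\sigma_{bg} = 0.25$) so that tail selection under the
null ranks real, if modest, biological variation rather than pure noise;
measurement noise is $\mathcal N(0, 0.25^2)$. The planted interaction is
constant across targets (matching the aggregate-shift picture the analysis
summarizes), with an optional `dampening_spread` for heterogeneity. One
seeded generator drives every draw, and the seed is echoed in the truth
object, so identical configurations reproduce byte-identical outputs.

What the generator does **not** emulate: probe-level artefacts (probe
affinity, saturation), array batch effects, correlated co-regulation
between overlapping programs, and heavy-tailed noise. Passing tests
therefore demonstrate that the statistical machinery is correct and well
calibrated under the design's idealized assumptions — not that the
pipeline is robust to every failure mode of real arrays.

`simulate_growth()` plants per-cell exponential rates, multiplies in
log-normal noise, and inverts the volume formula with $L = W = H$ so the
caliper reader reproduces the simulated volumes exactly.

## Calibration and verification, at a glance

The test suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) checks, among others: the interaction estimate
against the cell-mean oracle on 200 random balanced designs (agreement to
1e-10); exact noiseless parameter recovery; Fisher p against exhaustive
enumeration for all ~23,000 margin combinations with universe ≤ 25; BH
against the quadratic definition on 500 random vectors; recovery of the
planted TF at $p < 10^{-5}$, ranked first, across 20 simulation seeds, with
a clean null when $\delta^\star = 0$; coverage of $\delta^\star$ by the
targets' 95% CI; null calibration of the interaction ANOVA (rejection rate
in [0.03, 0.07] over 1,000 two-by-two experiments with 5 tumors per cell);
and byte-identical pipeline reruns under a fixed seed. Problem sizes in the
routine unit tests are scaled down (hundreds of genes, handfuls of sets) so
the default test run stays fast; the full-size properties live in the
acceptance tests.

## Worked example

```{r example}
expt <- simulate_experiment(simulation_config(
  n_genes = 2000, n_tfs = 10, targets_per_tf = 100, seed = 42
))
fits <- fit_interactions(expt$matrix, expt$design)
sel <- rank_and_select(fits, fraction = 0.05)
enr <- rank_tfs(enrich_sets(sel, expt$sets, measured = rownames(expt$matrix)))
head(enr, 3)

targets <- expt$sets$genes[[match(expt$config$active_tf, expt$sets$set_name)]]
fc <- fold_changes(expt$matrix, expt$design, targets = targets)
glance(summarize_by_target(fc))
```

The active factor ranks first, far below the $10^{-5}$ cutoff, and the
recovered `delta_of_deltas` sits near the planted 0.6.

## Known limitations

* Identifier matching is exact (case-sensitive, whitespace-stripped); no
  symbol aliasing or namespace translation is attempted, so the expression
  matrix and the gene-set collection must share a namespace.
* The enrichment is overlap-based; it does not use per-gene effect sizes
  beyond tail membership (no GSEA-style rank statistics).
* The growth ANOVA analyses one endpoint per tumor; longitudinal
  covariance is ignored by design.
* With very few genes, the floor/minimum-1 tail rule makes the "5%"
  selection coarse; at least `1/fraction` genes are recommended.
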