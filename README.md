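# pomanet

Network-based prioritisation of candidate biomarker microRNAs from
case/control expression data — an R implementation of the "outlier miRNA"
pipeline used to subtype acute coronary syndrome (acute myocardial
infarction vs unstable angina), applicable to any two-group design with a
reference miRNA–mRNA regulatory network.

## The method

miRNAs that are useful as biomarkers tend to regulate genes *independently*
(few other miRNAs share their targets) and to regulate *transcription
factors* (so their perturbation propagates). The pipeline quantifies both
ideas on a condition-specific regulatory network:

1. **Differential expression.** Each miRNA is fit with a two-group linear
   model; residual variances are shrunk toward a prior estimated across
   features (empirical-Bayes moderated *t*): with per-feature variance
   *s*²_g on *d*_g degrees of freedom and prior (*d*₀, *s*₀²),

       s̃²_g = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g),
       t_g = lfc_g / (s̃_g · √(1/n₁ + 1/n₂)),  df = d₀ + d_g.

   P-values are Benjamini–Hochberg adjusted; miRNAs with adjusted
   *p* < 0.05 are DE.
2. **Condition network.** The DE miRNAs induce a bipartite subgraph of the
   reference network (DE miRNAs + all their targets). For each miRNA:
   *N* (targets), **NOD** (novel out-degree — targets with in-degree 1,
   i.e. genes this miRNA alone regulates), the TF-target count, and
   **TFP** = TF targets / *N*.
3. **Selection.** A miRNA is a candidate biomarker when both its NOD and
   its TFP are significantly large: a one-sided, one-sample Wilcoxon
   signed-rank test of all other miRNAs' values against its own value
   (*p* < 0.05 for both statistics; exact null enumeration up to 25
   nonzero differences, tie-corrected normal approximation beyond).
4. **Characterisation.** Hypergeometric enrichment (with BH FDR) of the
   candidates' uniquely regulated genes in pathway gene sets (GMT);
   per-miRNA pathway-coverage percentages; literature-overlap precision
   (100·|predicted ∩ reported| / |predicted|) and cross-subtype overlap.

A synthetic-data generator plants biomarkers with known NOD/TFP structure
and expression effects drawn from the same scaled inverse-chi-square
variance model the moderated-t estimator assumes, so every stage is
testable end to end with ground truth.

## Worked example

```r
library(pomanet)

sim <- simulate_network(seed = 42)                     # 200 miRNAs, 10 planted
ex  <- simulate_expression(sim$network, seed = 42,
                           planted = sim$truth$planted_biomarkers)
de  <- de_analysis(ex$expr)
de
#> <poma_de> 200 features, 61 DE at adjusted p < 0.05 (d0 = 4.71, s0sq = 0.0524)

cond  <- build_condition_network(sim$network, select_de(de), label = "disease")
sel   <- select_candidates(compute_stats(cond))
glance(sel)
#> # A tibble: 1 × 5
#>   n_mirnas n_selected alpha mode        label
#>      <int>      <int> <dbl> <chr>       <chr>
#> 1       61         13  0.05 signed-rank <NA>

head(tidy(sel), 3)
#> # A tibble: 3 × 8
#>   mirna    n_targets   nod tf_targets   tfp    p_nod    p_tfp selected
#>   <chr>        <int> <int>      <int> <dbl>    <dbl>    <dbl> <lgl>
#> 1 mir-0065        29    26          9 0.310 7.70e-12 3.59e-11 TRUE
#> 2 mir-0136        26    24          8 0.308 8.31e-12 3.78e-11 TRUE
#> 3 mir-0168        24    22          8 0.333 1.44e-11 1.14e-11 TRUE

precision(candidates(sel), sim$truth$planted_biomarkers)$percent
#> [1] 76.9
```

The fit recovers the generator's variance prior (true d₀ = 4,
s₀² = 0.05), flags 61 of 200 miRNAs as DE (60 are truly shifted), and 10
of the 13 selected candidates are the 10 planted biomarkers —
precision 76.9 % against the planted list. `run_pipeline()` performs the
same steps from a config file and writes every stage's table (TSV) plus a
JSON report into a run directory; `autoplot()` methods draw the volcano,
NOD–TFP scatter and enrichment plots.

The package also ships curated candidate-biomarker tables for the two ACS
subtypes under `inst/extdata/acs/` (per-miRNA *N*, NOD, TF counts,
regulated-pathway counts, and literature-reported biomarker lists), used
by the reproduction script below.

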