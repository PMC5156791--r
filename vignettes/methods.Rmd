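---
title: "Methods: network statistics for miRNA biomarker prioritisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network statistics for miRNA biomarker prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomanet)
```

## The model

The pipeline identifies candidate biomarker miRNAs in two-group
(control/disease) expression studies by combining differential expression
with two structural statistics on a bipartite miRNA–mRNA regulatory
network.

**Differential expression.** Each miRNA is modelled as
log2-scale expression with a group-mean shift; the per-feature residual
variance $s_g^2$ (pooled over both groups, $d_g = n_1 + n_2 - 2$ df) is
assumed to follow a scaled inverse-chi-square prior
$\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$. The prior is estimated by
method of moments on $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$:
the excess of $\mathrm{var}(e)$ over $\overline{\psi'(d_g/2)}$ equals
$\psi'(d_0/2)$ (solved by Newton inversion of the trigamma function), and
$\log s_0^2 = \bar e + \psi(d_0/2) - \log(d_0/2)$, the mean of a log-F
variate. When the observed dispersion does not exceed its sampling
expectation, $d_0 = \infty$ and every feature is moderated to
$s_0^2 = \exp(\bar e)$ — the no-heterogeneity branch. The moderated
$t_g = \mathrm{lfc}_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$ with
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ is referred to a
t-distribution on $d_0 + d_g$ df, two-sided, followed by
Benjamini–Hochberg adjustment; adjusted $p < 0.05$ (strict) defines the
DE set. The test suite cross-checks the whole chain against the limma
implementation of the same estimator to $10^{-8}$.

Assumptions worth keeping in mind: the input matrix is already
normalised (no array-level normalisation is applied, and quantitative
RT-PCR inputs are assumed log-scale/ΔCt-transformed upstream); the design
is strictly two-group with no covariates; zero-variance features are kept
with $s_g = 0$ and are moderated by the prior alone rather than dropped.

**Network statistics.** The DE miRNAs induce a condition-specific
subnetwork: the DE miRNAs present in the reference network plus every
gene any of them targets. For each miRNA, $N$ is its out-degree, NOD
(novel out-degree) is the number of its targets with in-degree exactly 1
*within the condition network*, the TF count is
$|{\rm targets} \cap {\rm TF\ genes}|$, and ${\rm TFP} = {\rm TF}/N$.
Because targets are never pruned, $N$, TF and TFP equal their
reference-network values for any retained miRNA; NOD alone is
condition-dependent — evaluating uniqueness inside the condition network
is a deliberate choice (the statistic is meant to capture independent
regulatory power *among the deregulated miRNAs*), and it makes NOD
monotone non-decreasing as the DE set shrinks. The identity
$\sum_m {\rm NOD}(m) = \#\{\text{genes with in-degree } 1\}$ holds
exactly and is tested on random networks, alongside a brute-force oracle
on small networks.

**Selection.** The criterion "significantly large NOD and TFP" needs a
concrete test; the original pipeline's pairing is not restated in the
source material for this implementation, so the package makes a
deterministic choice: for each miRNA $m$, a one-sample, one-sided
Wilcoxon signed-rank test of *all other* miRNAs' statistic values with
$m$'s value as the null location (`alternative = "less"`). A small p
means the rest of the population sits significantly below $m$ — i.e. $m$
is an upper outlier. A miRNA is selected when both its NOD and its TFP
test give raw $p < 0.05$ (no multiplicity correction on selection, by
design). An alternative permutation null — degree-preserving double-edge
swaps of the condition network, per-miRNA empirical p — is available via
`select_candidates(mode = "permutation")` for sensitivity analysis; the
two modes agree on which miRNAs are clear outliers in the planted
simulations, and the signed-rank mode is the default because it is
deterministic and has no iteration-count parameter.

**Enrichment and reporting.** The enrichment query is the union of the
selected miRNAs' *unique* (NOD) targets: those genes are the ones the
candidates regulate independently, matching the selection rationale. The
universe defaults to all genes of the reference network (the sampling
frame targets arise from; `universe = "gmt-union"` is available).
Pathways are tested by the upper hypergeometric tail (log-space
`phyper`), BH-corrected, and flagged enriched only when raw $p < 0.05$
*and* FDR $< 0.05$. Pathway coverage for a miRNA counts enriched pathways
intersecting its unique-target set (an `targets = "all"` mode exists,
since either reading is defensible; unique targets keep the
interpretation aligned with the query definition). Prediction precision
is $100 \cdot |\text{predicted} \cap \text{reported}|/|\text{predicted}|$
— the denominator is the prediction, so it measures how much of the
candidate list is literature-supported.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha_de` | 0.05 | adjusted-p cutoff for DE (strict `<`) |
| `alpha_select` | 0.05 | raw-p cutoff on both NOD and TFP tests |
| `exact_max` | 25 | largest n for exact signed-rank enumeration |
| `p_cut`, `fdr_cut` | 0.05, 0.05 | double threshold for the enriched flag |
| `perm_iters` | 1000 | rewired networks in permutation mode |

Generator defaults (`simulate_*`): 200 miRNAs, 2000 genes, 10% TF genes,
mean out-degree 8 (Poisson truncated at 1), 10 planted biomarkers with 15
private targets each and a 0.3 TF share among their targets; 20 + 20
samples, 30% DE at |lfc| = 1.5 (log2), variance prior $d_0 = 4$,
$s_0^2 = 0.05$. These mirror a modest clinical microarray study: tens of
samples per arm, a few hundred features, shrinkage-relevant variance
heterogeneity, and planted candidates whose NOD/TFP signature is strong
but not degenerate. Background set sizes for simulated pathways are
20–50 genes with a 0.8 planted-enrichment share.

## What the generator does and does not emulate

It reproduces the statistical structure the analysis relies on: bipartite
topology with controlled target uniqueness, gene-level TF flags, group
shifts of fixed magnitude and random sign, and gene-wise variances drawn
from exactly the prior family the moderated-t estimator assumes (which
makes recovery of $(d_0, s_0^2)$ a meaningful end-to-end test). It does
not emulate microarray artefacts — batch effects, background, saturation,
probe cross-hybridisation — nor scale-free degree distributions,
correlated expression between miRNAs, or annotation errors in the
reference network. Passing tests therefore demonstrate correctness of the
computation and calibration under the stated model, not robustness to
real-data violations of it.

## Numerical choices

- **Exact signed-rank with ties.** Average ranks make the rank-sum
  half-integral; the exact null is enumerated by dynamic programming over
  doubled ranks, $O(n \cdot n(n+1))$, up to 25 nonzero differences
  (~0.1 ms at n = 25). Beyond that, a normal approximation with
  tie-corrected variance and continuity correction 1/2; the two branches
  agree within 0.01 at the crossover. Zero differences are dropped; a
  miRNA whose test is degenerate (all other values equal to its own) is a
  non-candidate, with a message.
- **Trigamma inversion** uses Newton's method from the asymptotic start
  $0.5 + 1/x$ with closed-form first derivative (tetragamma), tolerance
  $10^{-10}$.
- **Hypergeometric tails** are computed via `phyper(..., log.p = TRUE)`
  to avoid underflow for deep tails.
- **Rounding** is half-away-from-zero (`round_half_up`), applied only at
  presentation time: TFP and pathway fractions at 2 decimals, precision
  percentages at 1 decimal. Internal values keep full precision.
- **Ordering.** Candidate tables sort by decreasing NOD, ties by
  decreasing TFP then ID, so output is deterministic.
- **Seeding.** Every generator seeds a local RNG (restoring the caller's
  state) from the master seed plus a fixed per-component offset, so
  stages are reproducible and independent.

## Design decisions that were genuinely open

- The signed-rank pairing (above): per-miRNA one-sample test against the
  miRNA's own value, one-sided, both statistics required. The permutation
  mode exists precisely because this reading is one of several.
- Coverage counts unique targets, not all targets (flag provided).
- The enrichment universe is the network's gene set, not the GMT union
  (flag provided).
- Star miRNAs (`mir-340*`) are distinct IDs from their major arm —
  collapsing them would silently merge distinct candidates; ID
  normalisation only canonicalises the star's typography.
- Duplicate expression rows collapse by mean (logged), matching common
  probe-summarisation practice.
- No shell entry point is shipped: the exported functions and
  `run_pipeline()` (config file in, run directory of TSV/JSON stage files
  out) are the interface; every stage writes plain files so any stage can
  be rerun standalone.

## Problem sizes in the test suite

Property tests run on networks of 3–15 miRNAs against brute-force
oracles, and on the generator defaults (200 miRNAs × 40 samples) for
calibration and recovery: 50-seed batches for null p-value uniformity
(KS at $\alpha = 0.01$), variance-prior recovery (2000 features), and
planted-biomarker recovery (median sensitivity and false-discovery
proportion over seeds). These sizes give stable medians while keeping the
whole suite under half a minute.

## Known limitations

Two-group designs only; no covariates, paired samples or array weights.
No probe-to-miRBase remapping across releases — IDs must already refer to
the same annotation universe, and gene symbols are matched case-folded
verbatim. The reference network is an input; results inherit its biases
(well-studied miRNAs have more annotated targets, inflating N and
potentially NOD). Precision depends entirely on the completeness of the
user-supplied reported-biomarker list.
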