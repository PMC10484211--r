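---
title: "Detecting random allelic expression from multi-tissue allele counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting random allelic expression from multi-tissue allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raescan)
```

## The problem

Most genes are assumed to express both parental alleles at similar levels.
Random allelic expression (RAE) breaks that assumption: the relative
expression of the two alleles varies randomly between cells or tissues of
one genetically identical individual, as it does for X-inactivated (XCI)
genes in females. `raescan` detects RAE genome-wide from haplotype-phased
allele-specific read counts measured in many tissues of the same person,
then aggregates per-person calls across a cohort into reproducible,
high-confidence gene catalogs.

The central idea is that, within one individual, all tissues share one
genome. A consistently balanced gene, a gene skewed by a cis-regulatory
variant, and an imprinted gene all produce allele ratios that are *stable*
across tissues — only their mean differs. RAE produces ratios that are
*variable* across tissues: overdispersed relative to sequencing noise.

## The model

For gene $i$ with haplotype-A counts $X = (X_1, \dots, X_T)$ and totals
$N = (N_1, \dots, N_T)$ over $T$ tissues:

* **Null (biallelic / skewed / imprinted):**
  $X_t \sim \mathrm{Binomial}(N_t, p)$ with the pooled MLE
  $\hat p = \sum X_t / \sum N_t$.
* **Alternative (RAE):**
  $X_t \sim \mathrm{BetaBinomial}(N_t, \mu, \rho)$, parameterized by mean
  $\mu$ and intra-class correlation $\rho$, with shape parameters
  $\alpha = \mu(1-\rho)/\rho$, $\beta = (1-\mu)(1-\rho)/\rho$. At
  $\rho \to 0$ this collapses to the binomial.

The likelihood-ratio statistic $\mathrm{LRT} = 2(\ell_1 - \ell_0)$ is
referred to the upper tail of $\chi^2_1$ (two free parameters minus one).
Because $\rho = 0$ lies on the boundary of the parameter space, the
correct asymptotic null is a half-mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; using plain $\chi^2_1$ is
*conservative*, and we keep it deliberately — it matches the source
procedure and the empirical type-I error is verified (one-sided) by the
null-calibration tests. Benjamini–Hochberg correction is applied within
each individual, and genes with $q < 0.10$ are flagged.

Working across tissues of one person is what makes the test specific:
cis-eQTL skew and imprinting shift $\hat p$ but remain binomial, so they
are *not* called RAE. Conditioning on the total $N_t$ also makes the test
expression-aware — weakly expressed genes simply lack the evidence to
reject the null.

## Numerical choices

* The beta-binomial log-pmf is evaluated through `lbeta` (log-gamma)
  differences, stable for counts in the thousands. Tests compare it to an
  independent rising-factorial evaluation to 1e-9.
* The MLE is found with bounded quasi-Newton (`L-BFGS-B`) on
  $(\mu, \rho) \in [10^{-8}, 1-10^{-8}] \times [0, 1-10^{-8}]$,
  multi-started at $(\hat p, \rho_0)$ for
  $\rho_0 \in \{10^{-4}, 0.05, 0.3\}$; the best of the three starts is
  kept and checked against a zooming grid-search oracle to 1e-4 in
  log-likelihood.
* Nesting is enforced: $\ell_1$ is clamped to $\ge \ell_0$, and any
  numerically negative LRT is clamped to 0 before the tail probability.
* Degenerate inputs are resolved before optimization: a single
  informative tissue carries no between-tissue variance information and
  returns LRT 0, p 1; perfectly monoallelic data ($\hat p \in \{0, 1\}$,
  the imprinting-like extreme) fit both models perfectly and likewise
  return p 1.
* Upper-tail p-values that underflow double precision are floored at
  `.Machine$double.xmin` so the $(0, 1]$ contract holds.

## From individuals to a population catalog

Per-gene calls are aggregated over a cohort: for each gene, the number of
individuals with data (`n_tested`), the number significant, and the
population frequency $f$. Frequencies are standardized into Z scores
against the mean and population (divide-by-$n$) SD of the combined
autosomal + XCI frequency distribution, so $f$ and $Z$ are affinely
related and rank-equivalent.

The RAE threshold is not fixed a priori: it is calibrated on female XCI
genes (biological positive controls for random allelic behavior) against
autosomal genes (presumed predominately true negatives). Sensitivity
(positives with $Z \ge z$) and specificity (negatives with $Z < z$) are
scanned over every observed $Z$; the threshold is where the curves
converge, i.e. the $z$ minimizing $|\mathrm{sens} - \mathrm{spec}|$,
smallest $z$ on ties so the RAE class is maximal at equal separability.
Classification is then: RAE at $Z \ge z_{\mathrm{RAE}}$, biallelic at
$Z \le 0$, otherwise not categorized. The boundary at exactly 0 is
ambiguous in the source material (text says $\le 0$, one caption $< 0$);
the default is inclusive, with `biallelic_inclusive = FALSE` to flip.

High-confidence (hc) catalogs require independent replication: a gene is
hc-RAE only if classified RAE in *both* the female and the male cohort
(threshold derived in females, where XCI controls exist, applied to
both). Genes tested in only one sex cannot replicate and are excluded.
Males carry no XCI positives, so male summaries are standardized over the
male cohort's own autosomal genes; this puts male Z on a slightly
different scale than female Z — an accepted asymmetry, since the
threshold transfer is exactly what the calibration design prescribes.
Brain-only or body-only catalogs are the same pipeline run on a
tissue-label subset, not separate code.

## What the synthetic cohorts emulate — and what they do not

Protected individual-level data cannot ship with a package, so
`generate_cohort()` provides the stated world every pipeline stage is
tested against. Per gene and individual it draws a tissue count
(default: uniform on 3–30, the multi-tissue regime of donor biopsies), a
total depth per tissue (log-normal around 100 reads, truncated at 10, so
the depth filter is exercised but not dominant), and counts from the
gene's class:

| class | generator | share |
|---|---|---|
| balanced biallelic | Binomial(N, 0.5) | 0.70 |
| cis-skewed | Binomial(N, p), p fixed per gene in (0.2, 0.8) | 0.15 |
| imprinted-like | Binomial(N, p), p ∈ {0.02, 0.98}, consistent direction | 0.05 |
| RAE | BetaBinomial(N, 0.5, ρ), ρ per gene ~ U(0.3, 0.7), independent per tissue | 0.10 |

RAE and XCI-like genes are overdispersed only in a *penetrant* subset of
individuals (gene-level penetrance ~ U(0.5, 1)); elsewhere they behave
biallelically. This reproduces the observed population structure: XCI-like
genes significant in the majority of people (some in all), autosomal RAE
genes with intermediate, gene-specific population frequencies. The
XCI-like stratum (high ρ, females only) is what makes threshold
calibration testable. Independent per-tissue beta-binomial draws emulate
dynamic RAE; stable clonal mosaicism (one allele fixed per tissue) is the
extreme-ρ corner of the same family, and the test is agnostic between
them — which is also why a green test here cannot distinguish clonal from
dynamic RAE, only overdispersion itself.

Deliberately *not* modeled: read-level sampling, mapping bias,
sequencing error, SNP phasing mistakes (handled upstream of the input
contract by WASP-style correction and genome-wide phasing), correlated
depth between genes, and tissue-specific expression structure. Green
tests establish statistical correctness of the pipeline on its input
contract, not robustness to upstream artifacts.

Generation is hierarchically seeded (cohort seed for gene-level
parameters, derived per-individual streams consumed gene-by-gene), so
cohorts are byte-reproducible and appending genes does not perturb
earlier draws.

## Empirical FDR by null simulation

`simulate_null_counts()` keeps every observed total $N$ and missingness
pattern and redraws $X \sim \mathrm{Binomial}(N, 0.5)$ — the biallelic
probability of the source procedure. `estimate_fdr()` re-runs the full
per-individual test on these null cohorts and reports the falsely
significant fraction at $q < 0.05$ and $q < 0.1$, alongside the observed
data's significant fraction for contrast. A `use_observed_p` option
substitutes each gene's pooled $\hat p$ for a sharper per-gene null;
the default stays at 0.5 to match the reference procedure. One replicate
per individual is the default (the pseudocode's loop); `n_reps` tightens
the estimate.

## Genomic-context statistics

All interval arithmetic is 0-based half-open internally; GTF's 1-based
closed coordinates are converted at the parsing boundary only, and
abutting intervals do not overlap. Domain (TAD) enrichment forms, per
domain, the 2×2 table of (inside/outside) × (RAE/biallelic), computes the
odds ratio and Pearson chi-squared p (no continuity correction — the
named test is Pearson's; cells with expected counts under 5 warn that an
exact test may be preferable), adjusts across domains with BH, flags
domains at $q < 0.10$ and OR ≥ 1.5, and merges significant domains by
interval union. The background is genome-wide by default (a
per-chromosome restriction would condition the question on chromosome
identity; the source procedure does not state one). Genes spanning
several domains count once per domain, with a largest-overlap option.

Sense–antisense analysis flags, per stranded gene, any ≥1 bp overlap with
another gene on the opposite or same strand (self excluded; unknown
strands dropped with a warning), then tests the flag against class labels
with the same 2×2 machinery; Pearson residuals $(O-E)/\sqrt{E}$ give the
signed enrichment per cell. Chromatin-state density splits dichotomize
genes at the genome-wide median of a per-bp (length-normalized) density;
exact-median ties fold into "low" (the definitions are strict
inequalities; ties are unassigned by the source and folding them low is
the conservative choice for RAE enrichment, logged). The regulatory
complexity score is the median of four per-metric percentile ranks
(average rank on ties, scaled to [0, 1]) — rank-based, hence invariant to
monotone transforms of any metric. The telomere/centromere comparison
positions each domain by its midpoint's normalized distance to the
nearest chromosome end, $\min(m, L-m)/L \in [0, 0.5]$, compared between
domain sets by Kruskal–Wallis; the metric itself is this package's
construction (the source states the comparison but not the statistic) and
is documented as a stand-in.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 10 reads | minimum total phased reads per gene×tissue cell |
| `min_tissues` | 3 | minimum surviving tissues per gene per individual |
| `fdr` | 0.10 | BH q cutoff, both per-individual calls and domain tests |
| `min_individuals` | 10 | tested-individual floor below which a gene is Untested (the source plots frequency against sample size without a floor; 10 keeps binomial noise in $f$ below ~0.16 SD) |
| `min_or` | 1.5 | odds-ratio floor for a significant domain |

## Known limitations

* Bulk multi-tissue counts cannot resolve clonal vs dynamic RAE, nor
  cellular-level allelic states.
* The plain $\chi^2_1$ reference is conservative at the $\rho = 0$
  boundary; power at 3–5 tissues is modest, so low-penetrance RAE genes
  near the calibrated threshold are the main source of missed calls in
  the class-recovery tests.
* Threshold transfer from females to males assumes comparable frequency
  scales; genes tested in very different tissue panels between sexes can
  shift scale.
* The per-gene unit is the haplotype-phased gene; per-SNP effects and
  phasing errors are out of contract.
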