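---
title: "The BOMP hybrid likelihood model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The BOMP hybrid likelihood model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bomp)
```

## The problem

Case-control sequencing studies of common disease routinely observe
hundreds of rare coding variants per gene, most of them carried by a
handful of individuals. Single-marker tests are hopeless at these
frequencies, and simple collapsing (burden) tests lose power whenever a
functional group mixes deleterious, neutral, and protective variants, or
when cases and controls carry *similar numbers* of variants that fall in
*different places* on the gene.

`bomp` implements a hybrid likelihood model that addresses both failure
modes by combining two complementary statistics over a *functional
group* (one gene, or a gene set such as a pathway):

* a **directional mutation burden statistic** — sensitive when cases
  carry more (weighted) variants than controls;
* a **non-directional mutation position statistic** — sensitive when
  the distribution of variants along the coding sequence differs
  between cases and controls, regardless of totals.

Both are log-likelihood ratios, which is what makes their combination
into a single statistic natural, and both are assigned permutation
p-values, which is what keeps the data-driven optimizations inside each
statistic honest.

## The burden statistic

For individual $i$, the burden over a group's variants is
$b_i = \sum_j s_j\, g_{ij}$, with $g_{ij} \in \{0,1,2\}$ the allele
count and $s_j$ a per-variant weight (below). Under the dominant
genetic model $g_{ij}$ is replaced by $\mathbf{1}\{g_{ij} \ge 1\}$; the
additive model (the default) counts both copies of a homozygote.

Each individual is dichotomized at a threshold $T$: $z_i =
\mathbf{1}\{b_i \ge T\}$. Writing $k_\mathrm{case}$, $k_\mathrm{ctrl}$
for the exceedance counts in $n_\mathrm{case}$ cases and
$n_\mathrm{ctrl}$ controls, the statistic compares Bernoulli likelihoods
under separate and pooled exceedance probabilities,

$$\Lambda_B(T) = \ell(k_\mathrm{case}; \hat p_\mathrm{case}) +
  \ell(k_\mathrm{ctrl}; \hat p_\mathrm{ctrl}) -
  \ell(k_\mathrm{case}; \hat p) - \ell(k_\mathrm{ctrl}; \hat p),$$

with add-one smoothed estimates $\hat p_\mathrm{case} =
(k_\mathrm{case}+1)/(n_\mathrm{case}+2)$ etc., so that no probability is
ever 0 or 1. Smoothing is applied to the *parameters only*; the
likelihood exponents keep the raw counts. The threshold is optimized:
every distinct positive observed burden is a candidate, and the
$T$ maximizing the statistic is chosen (ties go to the smallest, most
inclusive $T$). Because only observed values can change the exceedance
counts, this scan is equivalent to a maximization over all real
thresholds; a property test checks this against brute-force search.

The statistic is returned as a **signed magnitude**,
$\mathrm{sign}(\hat p_\mathrm{case} - \hat p_\mathrm{ctrl})\,
|\Lambda_B|$: case-enriched groups score high, control-enriched groups
score low, and swapping the labels negates the value exactly. The
signed-magnitude form matters: because the smoothed parameters are not
maximum-likelihood estimates, the raw ratio can be slightly negative
even at case-enriched counts, and a naive "negate when controls lead"
rule would break the label-swap antisymmetry that the permutation null
relies on.

For a gene set, burdens are aggregated across all member genes before
thresholding — the procedure is otherwise identical.

### Variant weights

Four weighting modes feed the burden statistic (`weight_config`):

* `none` — unit weights, raw allele counting;
* `af` — frequency weights $1/\sqrt{2 n \hat q_j (1-\hat q_j)}$ with
  $\hat q_j = (a_{\mathrm{case},j} + a_{\mathrm{ctrl},j} + \alpha) /
  (2n + \alpha + \beta)$, a beta-posterior mean with
  $\alpha = \beta = 1$ pseudocounts by default. Rare variants get large
  weights, following the familiar inverse-variance convention with $2n$
  chromosomes in the denominator;
* `score` — externally supplied functional-impact scores in $[0,1]$
  (e.g. from a missense classifier; protein-truncating variants are
  conventionally scored 1). Missing scores fall back to 1 with a
  warning;
* `product` — the product of the two.

Weights enter *only* the burden statistic; the position statistic always
uses unweighted counts. Because $\hat q_j$ pools cases and controls, the
weights are invariant under label permutation and need not be
recomputed in the permutation null.

## The position statistic

The codons of a gene are partitioned into windows and the aggregated
per-window mutation counts of cases ($x_{\mathrm{case},w}$) and controls
($x_{\mathrm{ctrl},w}$) are compared by a multinomial likelihood ratio

$$\Lambda_P = \sum_w x_{\mathrm{case},w}
  \ln\frac{\hat\theta_{\mathrm{case},w}}{\hat\theta_w} +
  x_{\mathrm{ctrl},w}
  \ln\frac{\hat\theta_{\mathrm{ctrl},w}}{\hat\theta_w},$$

with add-one smoothing per window, $\hat\theta_{g,w} = (x_{g,w}+1) /
(X_g + K)$ for $K$ windows (multinomial coefficients cancel). The
statistic is symmetric in the two groups — there is no directionality in
where mutations fall — and it is large whenever the two spatial
distributions differ, including when the totals are equal. A worked
example: `multinomial_llr(c(6, 3), c(3, 6))` is about `0.98` even
though both groups carry 9 variants.

One subtlety of the smoothing: the pooled estimate
$(x_{\mathrm{case},w}+x_{\mathrm{ctrl},w}+1)/(X_\mathrm{case} +
X_\mathrm{ctrl}+K)$ smooths *less* than the per-group estimates, so a
gene whose case and control placements coincide exactly scores slightly
*negative* (never positive); the score is exactly zero when the window
counts are uniform. This is harmless — segmentation selection and the
permutation null are unaffected — but worth knowing when reading raw
statistics.

### Segmentations

Since the informative window partition is unknown, a grid of candidate
*segmentations* is enumerated: for each (window size $w$, shift
increment $s$) pair, one segmentation per offset in
$\{0, s, \ldots, w-s\}$. A segmentation with offset $o$ has a leading
partial window $[0, o)$, interior windows of length $w$, and a trailing
partial window with the remainder, so every codon belongs to exactly
one window. The default grid $(8,1), (16,2), (32,4), (64,8)$ yields
$8+8+8+8 = 32$ candidates per gene. The best segmentation — the one
maximizing $\Lambda_P$ — is selected per gene (ties resolve to the
first in enumeration order), and for gene sets the per-gene maxima are
summed. Genes shorter than a window size still receive the full
candidate family; coinciding duplicates are deliberately not removed,
preserving the 32-candidate contract.

Counting has two modes: `mutations` (every allele copy counts) and
`positions` (every distinct mutated codon counts once per group,
however many carriers). The default is `mutations`.

## Combination and permutation p-values

The combined statistic is, by default, the **sum** of the two
log-likelihood ratios — the natural combination on the log scale — with
`max` available as an option (the method's "burden *or* position"
reading). Since the two components are computed from the same data the
combined statistic has no analytic null; all three statistics get
permutation p-values instead.

For each of $B$ permutations of the case-control labels the *entire*
pipeline — threshold optimization and segmentation selection included —
is re-run, which is what makes the data-driven optimizations legitimate.
The p-value is the add-one estimator $p = (r+1)/(B+1)$, with $r$ the
number of permuted statistics at least as large as the observed one
(ties count toward $r$); it can never return 0 and lies on the grid
$\{1/(B+1), \ldots, 1\}$. One shared permutation stream scores all three
statistics, so their p-values are comparable row by row. The default is
$B = 10{,}000$; the power studies in this package use $B = 199$, which
resolves the $\alpha = 0.05$ decisions they need.

The permutation engine is vectorized: all $B$ label vectors form a
matrix, case allele counts for every permutation come from one matrix
product, window counts from indexed `rowsum()` aggregations, and the
burden exceedance counts from cumulative sums over a single
burden-sorted ordering. Because pooled window counts are
label-invariant in `mutations` mode, control counts are obtained by
subtraction rather than a second aggregation pass. These are pure
reformulations — a test checks the vectorized path bit-for-bit against
the scalar reference functions.

When the samples carry known structure (ancestry strata, sequencing
batches), `stratified = TRUE` permutes labels only within each stratum,
preserving the per-stratum case counts in every draw. A stratum that is
all-case or all-control contributes no permutation variability and is
flagged with a warning. Covariate adjustment beyond stratification is
out of scope by design.

Across functional groups, `bh_adjust()` (Benjamini-Hochberg step-up,
via `stats::p.adjust`) controls the FDR; per-group permutation p-values
are never themselves adjusted internally.

## The simulation framework

The generator produces extreme-phenotype case-control studies from
populations with a controlled site-frequency spectrum, a disease
etiology, and a Gaussian liability trait.

**Allele frequency spectra.** Per-site minor allele frequencies are
drawn from mixtures of log-uniform components (log-uniform because
neutral-spectrum site frequencies are approximately $\propto 1/x$).
Two presets emulate the qualitative contrast between an
African-American-like bottleneck population and a European-American-like
exponential-growth population:

| preset | components (weight: MAF range) |
|---|---|
| `AA-like` | 0.70: $[10^{-4}, 0.01]$; 0.20: $[0.01, 0.05]$; 0.10: $[0.05, 0.5]$ |
| `EA-like` | 0.92: $[5\times10^{-5}, 10^{-3}]$; 0.08: $[10^{-3}, 5\times10^{-3}]$ |

`EA-like` consists almost entirely of rare variants (more than 90% of
sites below MAF 0.001), while `AA-like` retains rare, low-frequency and
common mass. Genotypes are Binomial(2, MAF) at linkage equilibrium —
the association statistics respond to the case-control frequency
spectrum and to positional clustering, both of which the sampler
controls directly, so forward-in-time simulation with selection is
deliberately not reproduced. Real data differ in ways the generator does
not emulate — linkage disequilibrium, population substructure,
calling artifacts correlated with batch — so passing tests demonstrate
correctness of the statistics under the model, not robustness to those
phenomena (stratified permutation is the provided mitigation for
structure).

A standard gene has 500 codons (1500 coding bases) and 60 segregating
sites — roughly four segregating nonsilent sites per 100 coding bases,
a plausible figure for a large sampled population; key-region genes are
1000 codons (100 segments of 10 codons) with 120 sites. Variant codons
are uniform over the gene.

**Etiologies.** Eight preset disease models plus a null
(`etiology_config`): causal variants are *rare* (MAF < 0.01, effect
+0.5), *low frequency* (0.01–0.05, +0.25), *key region* (rare, +1.0,
restricted to 10 randomly designated segments of 100), or *common* (a
single randomly selected variant with MAF > 0.05, +0.25), each with a
protective companion model adding a −0.5 effect to 25% of the causal
variants (for the common etiology, protective modifiers come from the
rare spectrum). Effects are per allele copy. Heterogeneity within an
etiology is modeled by a `null_fraction` (default 0.25) of eligible
variants receiving no effect — all rare variants are not causal even
when all causal variants are rare. The single common causal variant is
exempt from the null fraction: a "common variant" disease study with no
causal variant at all would not be a study of that etiology. Every one
of these constants is a configurable argument with the stated default.

**Traits and study construction.** Individual $i$'s liability is
$\Phi_i \sim N(\sum_j g_{ij} c_j, 1)$; with no causal variants this is
standard normal, which also defines the null study. The top 1% of the
population by trait is the affected pool and the bottom 25% the
unaffected pool; cases and controls are drawn from the pools without
replacement, so intermediate phenotypes never enter a study and
phenocopies (affected non-carriers) arise naturally from the Gaussian
noise. Sites monomorphic within a study are retained and flagged.

`simulate_study()` draws genotypes in two stages: effect-carrying sites
for the whole population (to generate traits and select the extremes),
then the remaining sites only for the sampled individuals. Because
sites are independent, this is distributionally identical to
materializing the full population — `build_gene_set_population()` does
materialize it, and is the path the equivalence and invariant tests
exercise — but it makes 250-replicate power runs cheap. Population-scale
allele counts are drawn per site as Binomial($2N$, MAF) with carriers
scattered uniformly over chromosomes, again exactly equivalent to
per-individual draws.

**Population sizes.** The module default is 50,000. The single-gene
1000-case power scenario uses 100,000 — the smallest population whose
1%-prevalence affected pool (1,000) supports 1,000 cases — and the
100-gene, 200-individual gene-set scenario uses 20,000 (affected pool
200 for 100 cases). Pool fractions and sizes are all arguments.

## Power analysis

`estimate_power()` simulates independent studies (seeds derived
deterministically from a master seed), runs the full test on each with
all genes forming one functional group, and reports the fraction of
replicates with combined-statistic p-value at or below $\alpha$
(default 0.05), with a binomial standard error. Two preset designs are
shipped: `single_gene_power_scenario()` (one rare-etiology gene,
1000 + 1000 samples) and `gene_set_power_scenario()` (100 genes, 25
causal — a 1:3 causal ratio — with per-gene etiologies drawn 10:1:1
across the rare-dominated, common, and protective-containing
categories, 100 + 100 samples). The package's own runs use 250
replicates at $B = 199$, sizes at which both designs are comfortably
inside a desktop compute budget; under these defaults the single-gene
design saturates (power near 1) and the gene-set design retains power
near 0.9 despite 75 non-causal genes.

Type-I error is controlled by construction of the permutation test;
the acceptance suite verifies calibration empirically on 500
null-etiology studies (rejection rate at $\alpha = 0.05$ inside the
binomial 99% interval, Kolmogorov-Smirnov uniformity of p-values not
rejected at 0.01). The p-values are very slightly conservative on the
achievable grid — a known property of permutation tests on discrete
statistics with few variants.

## Numerical and design notes

* **Pseudocounts** appear in parameter estimates only, never in
  likelihood exponents; this keeps the worked examples exact
  (`smoothed_bernoulli_llr(2, 4, 2, 4)` is identically 0).
* **Tie-breaking** is deterministic everywhere: smallest burden
  threshold, first segmentation in enumeration order ((w, s) pairs as
  listed, offsets ascending).
* **Degenerate inputs**: all-zero burdens give statistic 0 with an
  undefined threshold; genes with no variants contribute 0 to a group;
  empty windows contribute 0 to the multinomial kernel but still count
  toward $K$.
* **Missing genotypes** are imputed as 0 copies with a logged
  per-variant missingness count — the burden semantics of "variants
  carried" — and half-calls contribute their called alleles.
  Multiallelic VCF records are split into one biallelic variant per
  alternate allele.
* **Coordinates**: VCF positions are 1-based; internal codon indices
  are 0-based offsets into a gene's concatenated CDS
  (`floor(offset/3)`), with minus-strand gene models walked in reverse
  genomic order. Variants outside every gene model are dropped with a
  logged count. Upstream filtering to coding non-silent variants is
  assumed; the package performs no annotation.
* **Determinism**: every stochastic entry point takes a seed, and a
  (data, configuration, seed) triple reproduces results bit for bit,
  including through the file-based front-end and CLI.
* **Bayesian extension** (adding a log prior ratio for the group to the
  combined statistic) and analytic p-values are intentionally not
  implemented.
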