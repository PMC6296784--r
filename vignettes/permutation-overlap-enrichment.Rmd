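---
title: "Permutation overlap enrichment and Ct quantitation with rloopstat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation overlap enrichment and Ct quantitation with rloopstat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopstat)
library(dplyr)
```

## The scientific problem

Studies of R-loop biology routinely ask two statistical questions of the
same shape: *does a set of genomic intervals fall inside a gene set of
interest more often than chance would predict?* The interval set may be
ChIP-seq binding peaks compared against the most highly transcribed genes,
or the gene bodies of the most differentially expressed genes compared
against R-loop prone regions mapped by DRIPc-seq. Alongside the sequencing
analyses sit plate-based qPCR assays — ChIP-qPCR percent of input,
DRIP-qPCR fold enrichment, and comparative-Ct (2^-ddCt) expression fold
changes — whose quantitation formulas are simple but easy to implement
inconsistently.

rloopstat packages both halves as tidy, seeded, testable functions: a
gene-set resampling permutation test with exact binomial confidence
intervals on the permutation p-value, the interval plumbing around it
(BED I/O, bead-control filtering, top-fraction gene selection,
top-k-by-p-value selection), the Ct quantitation formulas, and generators
that simulate every input with known ground truth.

## The permutation model

Let $Q$ be a fixed set of $n_Q$ query intervals and $G$ a gene set of size
$k$ drawn from an annotation universe of $N$ genes. The test statistic is
the overlap fraction

$$\hat f(G) = \frac{1}{n_Q}\sum_{q \in Q} \mathbf 1\{\exists g \in G :
q \cap g \neq \emptyset\},$$

with any-overlap (at least one shared base) semantics on 0-based,
half-open coordinates; strand is ignored and a query hitting several genes
counts once. The null distribution is estimated by drawing $B$ random
gene sets of size $k$ uniformly without replacement from the universe —
equivalent to re-selecting the set of interest after randomly permuting
gene identities — and recording $\hat f$ for each. Sampled sets are
matched to the real set in *count only*: no length or chromosome matching
is attempted, which mirrors how such nulls are usually constructed for
gene-set (rather than position-randomization) questions. Circular
rotation and block-bootstrap genome randomizations are deliberately out
of scope.

The p-value uses the add-one estimator

$$p = \frac{r + 1}{B + 1}, \qquad
r = \#\{b : \hat f_b \ge \hat f_{\text{obs}}\},$$

with ties counted as exceedances (both choices conservative; the add-one
rule can be disabled). Because $r$ is a binomial count out of $B$, the
Monte-Carlo uncertainty of $p$ is quantified by the exact
Clopper–Pearson interval for $r/B$ at the requested level (default 99%),
mapped endpoint-wise through the same $(r+1)/(B+1)$ rule so the interval
always brackets the reported p-value. Clopper–Pearson was chosen over
normal or mid-p intervals because it remains valid at $r = 0$, exactly
the regime where enrichment calls are made. An observed set is called
enriched when even the *upper* end of the interval is small.

The default $B$ is 1000 permutations, which bounds the resolution at
$p \ge 1/1001 \approx 10^{-3}$; raise `n_perm` if smaller p-values are
needed.

## A worked run

```{r enrich}
cfg <- synthetic_config(enrichment_theta = 0.9, seed = 11)
ann <- generate_annotation(cfg)
pk  <- generate_peaks(ann$genes, ann$truth, cfg)
top <- top_fraction_genes(ann$genes, fraction = 0.1)
res <- enrich(pk$peaks, ann$genes, top, n_perm = 1000, seed = 12)
tidy(res)
```

With 90% of peaks placed inside top-decile genes the observed fraction
sits far above the null and the p-value hits the $1/1001$ resolution
floor. `autoplot(res)` draws the null histogram with the observed
fraction marked.

The differential-expression front-end asks the same question in the
gene-to-peak direction: the fraction of the top `n_top` genes by p-value
whose body overlaps at least one peak region, with the null resampling
`n_top` genes from the *full tested table* (not from a whole-genome
annotation — the universe is the set of genes the DE model actually
tested):

```{r de}
rk <- generate_ranked_table(ann$genes, p_top = 0.6, p_background = 0.35,
  n_top_true = 100, seed = 13)
tidy(de_peak_enrichment(rk$ranked, rk$peaks, n_top = 100,
  n_perm = 1000, seed = 14))
```

Whether "gene overlaps peak" should use gene bodies, promoters or
extended windows is a judgement call; rloopstat uses the gene-body
intervals supplied in the table, and callers who want windows can expand
the intervals before testing.

## Ct quantitation

Three formula families are implemented exactly as printed on a qPCR
worksheet, with the dilution factor of the measured template entering as
$\log_2(\text{dilution})$:

* **ChIP percent enrichment**, optionally mock-subtracted:
  $100 \cdot 2^{C_T^{\text{input}} - C_T^{\text{IP}} - \log_2 d}
  - 100 \cdot 2^{C_T^{\text{input}} - C_T^{\text{mock}} - \log_2 d}$.
  A mock exceeding the IP yields a negative value, which is reported
  as-is with a `below_background` flag rather than clipped: clipping
  would bias any downstream normalization to a reference sample.
* **DRIP fold enrichment over input**:
  $2^{C_T^{\text{input}} - \log_2 d - C_T^{\text{DRIP}}}$, with a
  per-sample mock IP's fold subtracted when present.
* **Comparative Ct**: $2^{-\Delta\Delta C_T}$ against a reference
  amplicon and a control sample.

Amplification efficiency is fixed at 2 per cycle; efficiency-corrected
(non-2 base) models and standard-curve fitting are out of scope.

Replicate handling is configurable because practice varies: the default
averages Cts within (sample, locus, role) before evaluating the formula,
and reports as `sd` the standard deviation of replicate-wise evaluations
(replicates paired across roles by index); `average = "value"` instead
evaluates per replicate and averages the values. The linear-range helper
`select_linear_dilution()` keeps, per (sample, locus, role), the dilution
whose mean Ct falls inside a configurable window, default (15, 32) — the
usable span of a 40-cycle run; no instrument-specific value is implied.

```{r qpcr}
cfg_q <- synthetic_config(ct_noise_sd = 0.2,
  true_folds = c("ADH1-2" = 4, "ENO2-3" = 2, "FBA1-2" = 8), seed = 21)
quantify_qpcr(simulate_ct("drip", cfg_q), mode = "drip")
```

## What the generators emulate — and what they do not

`generate_annotation()` places non-overlapping genes (round-robin across
equal-length chromosomes, exponential-stick-breaking gaps) with
log-normal expression; `generate_peaks()` drops each peak, independently,
inside a uniformly chosen top-fraction gene with probability
`enrichment_theta` (clipped to the gene body, so enrichment is exact by
construction) and uniformly on the genome otherwise; `simulate_ct()`
inverts the quantitation formulas with additive Gaussian noise on the Ct
scale — the conventional qPCR error model; `generate_ranked_table()`
gives each gene a private peak with probability `p_top` (truly
differential genes) or `p_background`, so the per-gene overlap
probabilities are exact and independent. The defaults — 3 chromosomes ×
300 kb, 600 genes of mean length 800 bp, 150 peaks of 300 bp,
`ct_noise_sd = 0.2` cycles, DE overlap rates 0.60 vs 0.35 — are a
deliberately small genome with yeast-like gene density and study-like
overlap rates, sized so the full simulation-based test suite runs in
seconds.

The generators do *not* emulate: clustered or length-varying peaks,
correlation between expression and gene length or chromatin context,
overlapping or nested genes, amplification-efficiency drift, or
rank-correlated DE p-values. Tests passing on these synthetic inputs
therefore demonstrate correctness of the statistical machinery and
formula inversion — not robustness to every artefact of real sequencing
data.

Because per-gene overlap status is independent of rank when
`p_top == p_background` (and of gene identity when
`enrichment_theta = 0`), the permutation p-values are uniform up to the
slight super-uniformity induced by the add-one rule and tie handling.
The calibration test therefore applies a one-sided
Kolmogorov–Smirnov check that rejects only anti-conservative behaviour.

## Numerical and contract choices

* Coordinates are 0-based half-open everywhere; abutting intervals do not
  overlap. `top_fraction_genes()` keeps `floor(fraction × n)` records
  with ties at the cutoff broken by `gene_id` — so a one-gene universe at
  fraction 0.1 legitimately yields an empty top set.
* Overlap queries run through `IRanges::findOverlaps()`; the test suite
  checks them against a naive $O(nm)$ pairwise oracle on random
  instances.
* TSV writers print doubles at 17 significant digits and readers parse
  them with correctly rounded `strtod`, so every artifact round-trips
  bit-exactly (the fast approximate double parsers in common TSV readers
  lose the last bit).
* Every stochastic function takes an explicit integer seed and is a pure
  function of (inputs, seed); `run_pipeline()` threads one seed through
  all stages and echoes it, the full configuration and input checksums in
  its report, so a run is reproducible from the report alone.

## Limitations

The resampling null ignores gene length and composition, so strong
length–expression confounding in a real annotation could inflate
enrichment; a length-matched null is intentionally not provided.
Permutation resolution is bounded by `n_perm`. The qPCR models assume
perfect doubling per cycle. The altered-transcript summary
(`de_summary()`) is bookkeeping over externally produced DE calls — no
differential-expression model is fitted here.
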