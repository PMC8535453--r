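---
title: "Methods: codon usage bias, positional composition and skew analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias, positional composition and skew analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

This vignette documents the statistical procedures implemented in
`codonbias`, the assumptions behind them, the tunable parameters and
their defaults, the numerical conventions adopted where the literature
is silent, and what the validation on synthetic data does and does not
establish.

## CDS filtering

`filter_cds()` applies the standard quality rules for codon-usage work:
sequences must be unambiguous (A/C/G/T only), at least 300 nt
(inclusive — 300 is a valid multiple of three), a multiple of three in
length, start with ATG, end with TAA/TAG/TGA, contain no in-frame
premature stop, and be the longest transcript of their gene. Rejections
are *charged to exactly one rule* so that the per-rule counts reconcile
with the input count. The charging order is fixed: ambiguous_base,
too_short, not_multiple_of_3, bad_start, bad_stop, internal_stop,
not_longest_transcript. Length-based rules precede frame and content
rules because a truncated record is most informatively described as too
short; a 299-nt fragment is therefore reported as `too_short`, not as
`not_multiple_of_3`. Transcript grouping parses the gene id from the
record id by stripping a trailing `.N` isoform suffix (configurable
regular expression); length ties are broken by the lexicographically
smallest id so the output is deterministic. Ambiguity codes are
rejected outright because every downstream index requires exact codon
counts.

The terminal stop codon is retained for the length rules but excluded
from *all* counting: codon counts, GC, positional matrices and
profiles. Stops carry no synonymous-choice information and including
them would distort the composition of short genes.

## Usage indices

All indices operate on the per-gene count vector over the 61 sense
codons (`count_codons()`).

**Third-position frequencies.** A3s/T3s/G3s/C3s divide the number of
synonymous codons ending in the given base by the number of synonymous
codons, where "synonymous" means belonging to a family of size two or
more (59 codons; Met, Trp and stops excluded — the "s" in the index
names). GC3s is defined as G3s + C3s, so the four frequencies sum to
one and GC3s decomposes exactly. Other conventions exist (per-base
denominators over all third positions); this one is used consistently
and is configurable nowhere, on purpose — mixing conventions across
stages is a classic source of irreproducibility.

**ENC.** The observed effective number of codons uses Wright's
family-homozygosity estimator: for a family observed with $n \ge 2$
codons, $\hat F = (n\sum \hat p^2 - 1)/(n - 1)$, class means over
degeneracies 2, 3, 4, 6, and
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$.
Conventions for sparse genes: if Ile (the only three-fold family) is
unobserved, $1/\bar F_3$ is estimated as $(1/\bar F_2 + 1/\bar F_4)/2$;
a missing 2-, 4- or 6-fold class mean is replaced by the mean of the
computed class means; values above 61 (possible because $\hat F$ is
unbiased rather than bounded below by $1/k$) are capped at 61. A class
mean of exactly zero makes the estimate undefined (`NA` with a reason
attribute) rather than infinite. The estimator is verified against an
independently written brute-force implementation to 1e-9 before
capping.

**Expected ENC.** The mutation-only reference curve is
$2 + S + 29/(S^2 + (1-S)^2)$ with $S$ = GC3s. `enc_gc3_table()` reports
per-gene deviations (observed − expected) and the fraction of genes
below the curve; genes below it use fewer codons than their composition
alone predicts, the classic signature of selection on top of mutation
pressure.

**PR2.** Parity rule 2 states that without strand-specific
mutation/selection pressure A = T and G = C at third positions.
Coordinates are $G_{3s}/(G_{3s}+C_{3s})$ and $A_{3s}/(A_{3s}+T_{3s})$
computed from the all-synonymous-codon indices (not restricted to
four-fold degenerate sites — a common alternative deliberately not
used, to match the index definitions above). Genome-level biases are
unweighted means over genes; genes with an empty denominator are
excluded and counted.

**GRAVY / aromaticity.** Kyte–Doolittle mean hydropathy over all
encoded residues (initiator Met included) and the Phe+Tyr+Trp residue
fraction.

## Correspondence analysis

`run_coa()` implements classical CA: the genes × 59 RSCU matrix is
scaled to a correspondence table $P$, the standardized residuals
$D_r^{-1/2}(P - rc^{\top})D_c^{-1/2}$ are decomposed by SVD, and
principal coordinates are returned for genes and codons; the inertia
fraction of an axis is its squared singular value over the total
inertia. CA runs on RSCU rather than raw counts so that amino-acid
composition and gene length do not dominate the ordination; genes with
absent families are retained with zeros rather than dropped (dropping
would bias the gene set toward long genes). Four axes are reported by
default; axis signs are arbitrary, and no canonicalization is imposed —
the left/right placement of low/high-GC genes can flip between runs or
datasets, which is why every downstream consumer orients itself
explicitly (see optimal codons). Numerically, singular values below
`max(dim) * max(sv) * 1e-12` (with an absolute floor of 1e-10; the
residual matrix is scale-free) are treated as rank deficiency, so a
constant matrix yields zero informative axes instead of noise axes. The
implementation is tested for equality (to 1e-8, up to axis sign)
against a brute-force eigendecomposition oracle and cross-checked
against `MASS::corresp`.

## Optimal codons

The 5% of genes at *each* extreme of axis 1 (per-end, matching the
"extreme right and left" reading; `ceiling(0.05 N)` genes per end) form
the high- and low-bias datasets; their codon counts are pooled. Because
the axis sign is arbitrary, the end with the larger pooled GC3s is
labelled high-bias — consistent with the empirical pattern that optimal
codons in high-GC monocot genomes are C/G-ending — with a manual
override available. Each of the 59 candidate codons is tested with a
2×2 Pearson chi-square (no continuity correction, 1 df): codon count vs
the count of its other synonyms, high vs low set. A codon is *optimal*
when p < 0.01 **and** its within-family relative frequency is higher in
the high-bias set. No multiple-testing correction is applied by
default, matching the field's raw p < 0.01 convention; a Bonferroni
option exists. Note the direction condition halves the null call rate:
the chi-square test size is alpha, the directional call rate under the
null is about alpha/2.

## Positional hydrogen bonds

CDSs are left-aligned from the start codon in a matrix (rows = CDSs,
columns = codon positions, terminal stops excluded). A codon's hydrogen
bonds are 6 plus its G+C count (A:T pairs contribute two bonds, G:C
three), so the per-position mean obeys the identity
`mean_hbonds = 6 + 3 * (per-base GC fraction)` — asserted exactly in
the tests as a link between the positional and composition code paths.
Codons with 6–7 bonds are "cheap", 8–9 "expensive"; exactly 32 of the
64 codons fall in each class.

Uncertainty uses a nonparametric bootstrap with 1000 replicates
(percentile 95% intervals, seeded). Whole CDSs (matrix rows) are
resampled, not per-position values, to respect within-gene correlation;
resampling is implemented with multinomial row weights, which is
distributionally identical to row resampling but vectorizes. Positions
covered by fewer than 30 CDSs (configurable) are omitted — deep-tail
positions otherwise produce noisy, misleading profile ends. The default
window of interest is the first 500 codons.

`crossing_position()` reports the first position where the
expensive-codon fraction drops to ≤ 0.5 and stays there for 10
consecutive reported positions (a run reaching the end of the profile
also qualifies); the run requirement suppresses single-position noise
dips.

## Skew profiles

CG-skew $(C-G)/(C+G)$ and AT-skew $(A-T)/(A+T)$ are computed in 100-bp
windows stepped 1 bp, anchored at the CDS 5′ end; the x-axis is the
window *start*. Positive CG-skew means C enrichment. Windows with a
zero denominator are excluded from aggregation rather than zero-filled
(zero-filling would shrink means toward zero where one base pair is
absent). Aggregation is the unweighted mean over the CDSs long enough
to contain the window; trend slopes are ordinary least squares of the
mean skew on window start (per bp), with optional bootstrap standard
errors from CDS resampling.

## The synthetic generator

`generate_genome()` draws CDS sets with the statistical structure the
analysis assumes, so that every stage can be validated by parameter
recovery:

- **Lengths**: `min_codons` (default 100, i.e. the 300-nt filter
  boundary) plus a negative-binomial excess (mean 450 codons overall,
  dispersion 2), giving a realistic right-skewed length distribution
  with mean protein length ≈ 450 residues.
- **Per-gene GC3 target**: a two-component normal mixture, weight 0.62
  on mean 0.48 and 0.38 on mean 0.78 (sd 0.05). This reproduces the
  bimodal per-gene GC distribution of grass genomes with the low-GC
  mode heavier and a mean GC3s near 0.59.
- **Codon choice**: interior codons are amino-acid-uniform over the 18
  synonymous families (the analysis targets synonymous usage, not
  amino-acid usage, and uniformity keeps closed-form expectations
  simple; an override via family weights exists). The third base is G/C
  with the gene's target probability; where the family offers both C-
  and G-ending codons, C is chosen with probability
  `skew_p0 - skew_beta * (position - 1)` (defaults 0.55 and 1e-4 per
  codon), planting the 5′ C preference and its decline. The family
  structure itself then makes C3s > G3s and T3s > A3s, the ordering
  seen in real grass CDS sets.
- **Optional structure**: `gc3_decay` plants a linear 5′-to-3′ decline
  of the GC3 target (needed to emulate declining hydrogen-bond
  profiles); `family_bias` draws genome-level Dirichlet weights within
  family subclasses; `preferred_codons`/`preference_strength`/
  `preferred_fraction` tilt the within-family distribution of a gene
  subpopulation, which mechanically raises that subpopulation's GC3s —
  the configuration used for optimal-codon recovery.

Because the codon distribution is *linear* in the (clamped) per-gene
GC3 target, exact conditional expectations are available:
`expected_positional_profile()` evaluates the distribution at the mean
target per position, and `expected_skew_profile()` averages per-gene
expected-count skew ratios — deliberately matching the estimand of
`aggregate_skew_profile()`, which is a mean over genes of per-gene
ratios (pooling counts first would weight GC-rich genes more and gives
a measurably different slope under a bimodal mixture). These
expectations are only defined for specs without preference tilts
(which break linearity) and for regions covered by every gene, so stop
codons and coverage edges never enter.

What the generator does **not** emulate: real amino-acid composition,
gene-family and orthology structure, isoforms, length–GC correlations,
within-genome regional (isochore-like) autocorrelation, and any direct
model of expression level. Passing parameter-recovery tests therefore
shows the estimators are correct and well-calibrated under the stated
sampling model — not that real genomes satisfy that model.

## Validation design and problem sizes

The test suite validates each stage at the smallest size that gives the
assertion adequate power, chosen once at design time:

- oracle equivalence: 25 random genes of 2000 codons (ENC, 1e-9), 20
  random 10×8 matrices (CA, 1e-8);
- mixture recovery: 500 genes (mixture-mean tolerance ±0.02);
- optimal codons: 500 genes, 10 planted codons at strength 4 in a 30%
  subpopulation (exact set recovery), and 200 null replicates of 50
  genes for the test size (0.01 ± 0.005, about three binomial standard
  errors plus asymptotic slack);
- gradients: 1000 genes of ≥ 400 codons for the skew slope (within two
  bootstrap SE of the analytic slope) and hydrogen-bond coverage
  (share of positions whose analytic mean falls in the 95% bootstrap
  interval, tested against 0.95 minus three binomial standard errors —
  per-position coverage events are nearly independent here, so the
  strict fraction fluctuates around its nominal level by design);
- crossing recovery: 8000 short genes with `gc3_decay = 2e-3`, measured
  crossing within ±10 codons of the analytic crossing (the detection
  spread scales as per-position noise over profile slope, which sets
  the required gene count).

## Known limitations

- Only the standard nuclear genetic code is supported; no CAI or tAI.
- The ENC small-sample conventions (Ile substitution, class-mean fill)
  follow one established lineage of implementations; genes with very
  few families are reported `NA` rather than extrapolated.
- The expected-ENC curve is an approximation even under pure mutation
  pressure; simulated mutation-only genomes sit near it (mean deviation
  within ±2 ENC units in the tests), not exactly on it.
- The optimal-codon procedure inherits the axis-1-extremes-as-
  expression-proxy assumption; without expression data it identifies
  composition-driven bias, and the GC3s orientation rule encodes
  exactly that.
- Bootstrap intervals quantify sampling uncertainty across genes, not
  model misspecification.
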