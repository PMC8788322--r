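---
title: "Models and methods behind magscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(magscreen)
```

# The screen in one paragraph

A pooled RB-TnSeq library — hundreds of thousands of transposon mutants,
each carrying a unique 20-nt barcode — is grown under a condition of
interest and filtered through a magnetic column. Strains that make
magnetosomes stick to the column (magnetic fraction); strains that do not
flow through (nonmagnetic). Barcode amplicon sequencing (BarSeq) of the
time-zero, precolumn, magnetic, and nonmagnetic samples turns strain
abundances into a per-gene magnetic column score (MCS): low MCS in the
magnetic fraction means the gene's mutants fail to biomineralize; positive
MCS means they are retained better than wild type. This package implements
the computational side of that screen end to end, and a forward simulator
that makes every stage testable at desk scale.

# Coordinates and the central region

All coordinates are 1-based inclusive, the GFF3 convention; half-open
arithmetic never leaks across a function boundary. A transposon insertion
is considered disruptive when it falls in the gene's *central region*,
by default the 10–90% span:

```
[start + floor(0.1 * length), start + ceiling(0.9 * length) - 1]
```

clamped to the gene and always nonempty. Terminal insertions often leave a
working protein, so they assign the strain to the gene but do not count it
as a knockout. The same region defines both fitness-strain eligibility and
essentiality densities, so one disruption notion is used pipeline-wide. An
insertion central to two overlapping genes is ambiguous: it is excluded
from gene-level analyses rather than double-counted.

# Pool construction choices

TnSeq reads are modeled as `flank5 | barcode(20) | flank3 | junction`. The
flank sequences are a property of the sequencing construct; the defaults
are arbitrary fixed flanks shared with the simulator, so simulated data
parse out of the box, and real data supply their own model. Junction
mapping is exact-match only (forward strand and reverse complement; a
palindromic junction is counted once, since its reverse-strand match is
the same genomic occurrence). Fuzzy alignment is deliberately out of
scope: synthetic reads are error-free, and real pools are usually mapped
with a dedicated aligner and imported as a pool TSV.

A barcode seen at several loci keeps its modal locus; it is flagged
`multimapped` when the minority fraction of its locus evidence exceeds
0.25, when the mode is tied, or when its junction occurs at multiple
genomic positions. `n_reads` is the support for the modal locus. The 0.25
threshold is a determinism-first convention for chimeric barcodes, exposed
as `conflict_frac`.

Library QC follows the usual RB-TnSeq summary. A *hit protein* is a gene
with at least one central, uniquely mapped strain; hits per protein and
reads per hit protein are averaged **over hit proteins** (the phrasing
"per hit protein" in the field's summaries), and the read bias is mean
minus median reads per hit protein.

# Essential-gene calling

Mutants of essential genes cannot survive library construction, so
essential genes show no central insertions. The calling rule has to guard
against short genes that could be empty by chance. With `d` the median
central insertion density (insertions per nt, computed over genes that
survive the exclusions), the minimum calling length is the smallest
integer `L` with

```
P(Poisson(d * L) = 0) = exp(-d * L) < alpha        (alpha = 0.02)
```

i.e. `L_min = floor(-log(alpha)/d) + 1`. Classes partition the annotated
gene set: `excluded_short` (< 100 nt), `excluded_duplicate` (user list, or
genes whose assigned barcodes are ≥ 50% multimapped — the package's
operationalization of "very similar to other parts of the genome" when no
list is given), `not_called_below_threshold` (< `L_min`), `essential`
(eligible, zero central strains), `nonessential` (everything else). The
hard call is *exactly zero* central strains — a deterministic rule; genes
with unusually low but nonzero density (< 0.2 × median) carry an advisory
`low_density` flag instead of a softer call.

# Strain scores, gene scores, and the MCS

Strain score against the matching time-zero sample, with totals `N` and
pseudocount 1:

```
f_s = log2( ((n_cond + 1) / N_cond) / ((n_t0 + 1) / N_t0) )
```

Strains are eligible when central, uniquely mapped, and with at least
`t0_min_reads = 3` reads at time zero (low-count t0 strains give unstable
ratios). The gene score is the inverse-variance weighted mean of its
strains' scores, with the Poisson-motivated variance

```
V_s = (1/(1 + n_cond) + 1/(1 + n_t0)) / ln(2)^2 ,   w_s = 1 / V_s
```

which reduces to the plain mean on balanced counts. The published
framework this emulates uses a position-dependent smoothing normalization
inherited from growth-fitness analysis; that is intentionally simplified
here to optional per-sample median-centering (`median_center`, off by
default — simulated samples need no recentering), and declared as such.

The normalized MCS subtracts the precolumn gene score from the magnetic
and nonmagnetic gene scores within each (condition, replicate):

```
MCS(g, fraction, rep) = raw(g, fraction, rep) - raw(g, precolumn, rep)
```

A mutant that merely grows slowly is depleted in *both* samples equally,
so the subtraction cancels growth effects; this is verified by simulation
(growth fitness 0.5, neutral retention, |mean MCS| < 0.2). Replicates are
averaged after normalization. Hit calling (|mean MCS| ≥ 1, sign-consistent
replicates) is a package convention — the field reports scores, not
significance tests — and both knobs are exposed.

# What the simulator emulates — and what it does not

The generator's defaults are the stated world of the screen it emulates,
scaled to desk size: 200 genes on a 200 kb scaffold (lognormal lengths,
median ≈ 900 nt, non-overlapping), 10% planted essential genes, enough
insertions for ≈ 34 surviving central strains per nonessential gene,
20-nt random barcodes, 3 biological replicates, four fractions, 3 × 10⁵
reads per sample. A magnetosome-island-like block of 12 contiguous genes
has column retention p_g = 0.25 against wild type p_wt = 0.9, and one
distal gene has p_g = 0.99, emulating the enrichment phenotype of an
ex-island inhibitor.

Column retention is modeled per cell as Bernoulli(p_g), so for strain
cells `c`: magnetic ~ Binomial(c, p_g), nonmagnetic = c − magnetic, and
cells are conserved strain by strain. This is the simplest exchangeable
retention model with a closed-form expectation: the magnetic MCS of an
effect gene converges to `log2(p_g / p̄)` ≈ `log2(p_g / p_wt)` at large
depth, which is what the recovery tests check. Growth is a single
multiplicative fitness step — enough to exercise the precolumn
subtraction, not a generation-resolved model. Not emulated: PCR
amplification bias, chimeric barcodes, index hopping, sequencing errors
(available but off by default), bottleneck drift between replicates, and
any magnetosome physics. A green recovery test therefore establishes that
the pipeline's estimators are unbiased and well-calibrated *under this
model*, not that the laboratory protocol behaves binomially.

Default cell depth (10⁶ cells over ≈ 8,500 strains) and read depth were
chosen once for statistical comfort — roughly 35 reads per strain per
sample, giving gene-score standard errors near 0.05 — because the real
screen's column bottleneck sizes are unpublished.

Determinism: every stage derives its RNG stream from the single config
seed (`stage_seed`), so a (seed, config) pair reproduces the genome, pool,
counts, and FASTQ bytes exactly; derived seeds stay below 2³¹.

# Numerical and design choices

* `L_min` is computed in closed form and property-tested against direct
  evaluation of the Poisson zero-class probability; the boundary case
  where `-log(alpha)/d` is an integer rounds *up* (the inequality is
  strict).
* Ties for a barcode's modal locus flag the barcode rather than breaking
  the tie arbitrarily.
* Genes missing from either side of the precolumn subtraction are dropped
  and tallied (`coverage` attribute) — never scored 0.
* The BarSeq counter retains zero-count rows for every pool barcode so
  pseudocounted ratios are defined everywhere; off-pool barcodes are
  tallied per sample, never added as rows. Exact matching only — a
  Hamming-1 rescue would trade determinism for sensitivity on real data
  and is left to preprocessing.
* Two identifier systems (RefSeq-style primary tags, legacy-style
  aliases) are both stored; the primary tag is the key everywhere.

# Morphometry comparisons

Crystal-length datasets are compared with a normality-gated test: both
samples are screened with Shapiro–Wilk at α = 0.05; if both pass, a
two-sided unpaired Student's t test (equal variances, as "Student"
implies; Welch behind `var_equal = FALSE`); otherwise a two-sided
Mann–Whitney U. The gate depends only on the two Shapiro p-values, and the
result is symmetric in the sample order. The continuity-corrected normal
approximation is used for the U test so that tied measurements (common in
binned TEM length data) are handled deterministically. Samples below the
conventional 200 measurements per strain and condition warn rather than
error.

# Known limitations

* Exact-match junction mapping cannot place insertions in repetitive
  regions; such barcodes are dropped or flagged, which is the desired
  behavior for duplicate-gene exclusion but loses real signal in repeats.
* The essentiality call is binary on zero central strains; a gene kept
  alive by a single mis-assigned barcode escapes the call (it is flagged
  `low_density`).
* The MCS has no attached significance statistic by design; the hit
  threshold is a convention to be tuned against controls.
* The simulator's closed-form expectations hold for the binomial retention
  model only; systematic column effects (e.g. chain-length-dependent
  retention) would need a different generator.
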