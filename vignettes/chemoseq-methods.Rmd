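---
title: "Methods: tissue-enhancement calling from appendage RNA-seq"
author: "chemoseq developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-enhancement calling from appendage RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoseq)
```

## The analysis this package implements

chemoseq re-implements, as a tested and reusable pipeline, a classic
single-replicate bulk RNA-seq design for chemosensory appendages: six
single-end 43 bp libraries — female and male whole bodies (FB, MB),
antennae (FA, MA) and maxillary palps (FP, MP) — mapped to a
*gene-condensed* transcriptome (all isoforms of a gene collapsed under one
gene identifier), quantified as weighted read counts and RPKM, and screened
for *tissue-enhanced* genes: genes whose appendage expression exceeds
whole-body expression at least 2-fold with a Bonferroni-significant
Fisher's exact test.  A synthetic-data generator with ground truth stands
in for the original sequencing libraries, so every stage of the pipeline is
testable against known answers.

## Model and procedure

### Trimming and mapping

Reads are uniformly trimmed 4 nt from the 5' end (adapter contamination)
and 12 nt from the 3' end (reaction degeneration), leaving 27 nt of a 43 nt
read (original 1-based positions 5..31).  Trimmed reads are mapped allowing
at most 3 mismatches on either strand.  The mapper is an exact
seed-and-verify k-mer index: a read is split into `max_mismatches + 1`
non-overlapping seeds of length *k* (default 6, the largest *k* with
`4k <= 27`); by the pigeonhole principle any placement with at most 3
mismatches contains at least one exact seed, so seed lookup followed by
full verification finds **all** qualifying placements, not a heuristic
subset.  `N` counts as a mismatch at every position (so an N-rich read
simply fails).  Verification packs sequence into 2 bits per base and counts
mismatches with XOR + popcount.  The test suite proves exactness against
two independent oracles: a pure-R all-offsets Hamming scan (placement by
placement) and Biostrings' shift-or matcher (gene sets, on a 100-gene x
10^4-read instance).

Design choices where the upstream convention was unknowable:

* **All placements, not best-stratum.** Every placement with <= 3
  mismatches is reported; a `best_stratum` flag restricts to the minimal
  stratum.  All-hits makes multi-mapping weights well defined.
* **Both strands are searched** because library strandedness is unstated;
  the simulator emits sense-only reads by default with an
  `antisense_fraction` option.
* Multiple placements inside one gene (several isoforms or offsets)
  collapse to a single gene membership — isoform-level expression is
  explicitly out of scope.
* Coordinates are 0-based half-open internally; human-facing reports are
  1-based.

### Weighted counting and RPKM

A read hitting one gene adds 1 to its unique and weighted counts.  A read
hitting *k* > 1 distinct genes contributes only to weighted counts, by
default 1/k to each gene (*equal split*).  The equal split is deterministic
and auditable; an optional *rescue* scheme apportions ambiguous reads
proportionally to each candidate's unique count (uniform fallback when no
candidate has unique evidence), approximating the behaviour of early
RNA-seq quantifiers.  The two schemes coincide exactly when no read is
ambiguous, and both conserve reads: weighted counts sum to the number of
mapped reads (tested to 1e-6 on every simulated library).

Expression is normalized as RPKM,

$$\mathrm{RPKM} = \frac{10^9\,C}{L\,N},$$

with \(C\) the weighted count, \(L\) the longest annotated transcript
length of the gene (bp) and \(N\) the per-sample total of
transcriptome-mapped weighted reads.  Whether the original \(N\) included
genome-only reads cannot be determined from the source; the
transcriptome-mapped convention is this package's stated choice.  Detection
for per-library summaries means weighted count > 0 (equivalently RPKM > 0);
the reported standard deviation is the sample sd (n − 1), flagged in the
output because the upstream convention is unstated.

### Enhancement calling

For each gene in a pairwise comparison (tissue vs matched body), a 2x2
table is formed from the gene's reads versus all other reads in each
sample.  Weighted counts are fractional, Fisher's test needs integers: they
are **rounded half-up**, a logged design decision.  The two-sided p-value
uses the probability-mass definition — the sum of hypergeometric
probabilities of all tables (same margins) no more probable than the
observed one, with the conventional `1 + 1e-7` relative slack — computed in
log space and floored at 1e-300 so p is never exactly zero.  The test suite
checks this against exhaustive enumeration (fully for margins <= 15, and on
2000 seeded random tables with margins <= 200) at 1e-12 relative.

A gene is called *enhanced* in the higher sample when both

1. the RPKM ratio is at least `fold_threshold` (default 2), after
   replacing exact-zero RPKMs by a pseudo-value of 0.10 so ratios stay
   finite, and
2. p is below the Bonferroni threshold `alpha / n_tests`.

`n_tests` defaults to the full annotation size — the genome-wide
correction — not the number of genes actually tested; with alpha 0.05 over
12669 protein-coding genes this gives 3.9e-6 at two significant figures.
The published divisor is ambiguous (a transcript-level count of 13319
yields 3.75e-6), so `n_tests` is configurable.  The pseudo-value rule was
described upstream for plotting only; this package applies it to calling
as well, because calling needs finite ratios for zero denominators, and
the conjunction with the Fisher criterion makes the choice irrelevant for
well-covered genes.

### Comparative layer

Enhanced gene sets feed pairwise overlap counts (with shared percentages
rounded to integers for reporting, exact values retained), Pfam best-hit
tallies per enhanced set (ranked by total representation, ties broken by
accession; genes without a Pfam hit drop out), per-family RPKM profile
matrices in the fixed heatmap order FP, FB, FA, MA, MB, MP, and cross-sex
normalization.  Normalization factors are either morphological
(female:male trichoid-sensilla ratio 630/225 = 2.8; grooved-peg factor 4.2
and palp factor 4, shipped as fixed constants because their underlying
counts are not re-derivable here) or expression-based (the fold-difference
in the obligate co-receptor Orco's RPKM between female and male antennae,
916/186 = 4.9).  Factors are reported to one decimal with exact values
retained; any positive factor preserves within-sample expression ranking.

## The synthetic world

The generator emulates the study design at desk scale, and its defaults
are fixed once:

| parameter | default | rationale |
|---|---|---|
| genes | 500 | desk-scale stand-in for 12669 protein-coding genes |
| transcript length | uniform 300–1500 bp | typical insect mRNA span |
| isoforms/gene | 1 (prefix isoforms optional) | isoform structure only matters via the longest-length rule |
| baseline abundance | log-normal, sdlog 1.5 | several orders of magnitude of expression, as in real libraries |
| paralog families | 10 pairs, 2% divergence | forces genuine multi-mapping at 27 nt |
| library size | 200,000 reads | deliberate ~150x scale-down of the ~30 M-read libraries |
| read length / errors | 43 bp, 0.5% substitutions | study geometry; Illumina-scale error rate |
| enhanced design | 20 genes per antenna, 15 per palp, folds 2/4/8, partial overlap between sexes | a designated minority of enhanced genes at folds spanning the 2x threshold |

Designed folds are capped at 8x deliberately.  True abundances are
per-column *relative* quantities (columns sum to 1), so enhancing some
genes shrinks every other gene's relative abundance in that sample
(closure).  The analysis — like all single-library RPKM comparisons —
assumes most genes are unchanged between tissue and body; keeping the
designed mass a minor fraction of the library keeps the closure shrink
mild, so a designed fold-4 gene still exceeds the 2-fold calling threshold.
Fold-2 genes sit *at* the threshold and are expected to be missed after
shrink: they document the boundary rather than the power of the caller.
Truth labels are recorded against the designed fold before
renormalization.

Reads are drawn multinomially over (isoform, start) cells with weights
`abundance x (length - read_length + 1)`, uniform starts, independent
per-base substitution errors, exactly `library_size` reads per library, and
deterministic output given the master seed (per-stage sub-seeds are derived
from it).  The generator does **not** model PCR duplication, GC or
positional bias, indels, paired ends, or quality-score structure (qualities
are constant `I` and never used).  A green recovery test therefore
establishes correctness of the pipeline's arithmetic under the stated
sampling model — not robustness to real-library artifacts.

## Numerical choices and degenerate inputs

* Weighted-count rounding: half-up (`floor(x + 0.5)`), applied to both the
  gene row and the library total.
* p-values: log-space accumulation, `1 + 1e-7` relative slack on the
  "at most as probable" comparison (matching standard implementations),
  floor 1e-300; `-log10 p` capped at 300 in volcano tables with the cap
  recorded.
* Samples with zero mapped reads get all-zero RPKM columns and are listed
  in `zero_n_samples` rather than producing NaN; `compute_rpkm()` itself
  rejects `N = 0`.
* Reads too short to survive trimming are excluded and tallied, not
  errors; malformed FASTQ records are skipped with a logged count.
* Ties in Pfam ranking break lexicographically by accession; overlap
  percentages round half-even via R's `round()` at reporting time only.

## What the acceptance layer establishes

`scripts/acceptance.R` recomputes only in-study arithmetic — the
Bonferroni threshold, the two cross-sex normalization factors, three
enhanced-set overlap percentages (from the published set sizes shipped as
a fixture), and the pooled library statistics (mean 30.5 M reads; 57.4%
transcriptome-mapped) — because the full-scale result tables cannot be
reproduced at desk scale without the original supplementary count table.
The `read_counts_table()` dialect exists precisely so that such a table,
when available, can be fed straight into the enhancement and comparative
modules.  The property suites (Fisher enumeration, mapper oracles, count
conservation, null family-wise error, designed-fold recovery) are run by
the test suite, with the family-wise-error suite at the count level — the
exact marginal of error-free simulation plus perfect mapping — to stay
within time budget, and the power suite end-to-end at read level.

## Known limitations

* Single library per tissue: the Fisher test treats sequencing sampling as
  the only noise source; biological replication and dispersion-aware
  models (negative binomial DE) are out of scope by design.
* Equal-split weighting is conservative for paralog families; rescue
  weighting is provided but neither reproduces a specific upstream
  quantifier exactly.
* The mapper is transcriptome-only; genome/spliced alignment and
  genome-coverage comparisons are out of scope.
* RPKM comparisons are compositional (see closure discussion above); very
  large true enhancement of a few genes depresses apparent ratios of all
  other genes.
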