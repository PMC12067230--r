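---
title: "Scoring amyloid nucleation from selection sequencing"
author: "nucleateR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring amyloid nucleation from selection sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleateR)
```

## The assay and its statistical structure

In a nucleation selection assay, a library of peptide variants is expressed
in yeast fused to a prion reporter domain. Variants that nucleate amyloid
aggregation allow growth under selection; variants that do not are depleted.
Sequencing the variant pool before (input) and after (output) selection
turns growth into a per-variant enrichment measurement. Two library designs
are supported end to end:

* **Designed libraries**: every single amino-acid substitution (19 per
  position) and every truncation (stop at each position) of a wild-type
  peptide. `enumerate_variants()` produces exactly `20 * L` unique protein
  variants for a length-`L` peptide — 680 for a 34-residue peptide.
* **Random-extension libraries**: a fixed 22-residue base peptide extended
  by `n` NNK degenerate codons. The 32-codon NNK set encodes all 20 amino
  acids and exactly one stop (TAG), so extension lengths follow a truncated
  geometric law: `P(len = k < n) = (31/32)^k / 32` and
  `P(len = n) = (31/32)^n` (about 0.683 for `n = 12`).
  `sample_nnk_extensions()` samples this space uniformly.

## The score model

For variant $i$ in replicate $r$, with read frequencies $F$ computed after
adding a pseudocount to every read count,

$$ ES_{i,r} = \ln F^{out}_{i,r} - \ln F^{in}_{i,r}, \qquad
   NS_{i,r} = ES_{i,r} - ES_{wt,r} . $$

The wild-type term is used for designed libraries (`centering = "wt"`).
Because both terms are double ratios, the sample depths cancel: the score
only depends on the four counts involved. Errors come from a Poisson delta
method on the pseudocounted counts,

$$ \sigma^2_{i,r} = \frac{1}{c^{in}_{i,r}} + \frac{1}{c^{out}_{i,r}}
   \;\left(+ \frac{1}{c^{in}_{wt,r}} + \frac{1}{c^{out}_{wt,r}}\right), $$

and replicates are merged by the inverse-variance (error-weighted) mean
with merged error $(\sum_r 1/\sigma^2_r)^{-1/2}$, which is never larger
than the best single replicate. The Poisson delta method is the simplest
defensible error model for multinomial sequencing counts; it is isolated
behind `merge_replicates()`/`ns_fit()` internals so a more elaborate
replicate-regularised model could replace it without touching the rest of
the pipeline.

Natural logarithms are used throughout. Centered scores are invariant to
the log base, but error magnitudes are not, so the convention is fixed and
documented rather than configurable.

### Centering and imputation

Random libraries have no meaningful wild type (the experimental convention
is an arbitrary high-count reference), so raw enrichment scores are centered
on the **mode** of the merged-score distribution: most random sequences do
not nucleate, so the dominant density peak is the null bulk. The mode is the
argmax of a Gaussian kernel density estimate (Silverman's rule-of-thumb
bandwidth, 512-point grid), which is robust to the heavy right tail of
nucleators; at least 50 measured sequences are required. Centering is
idempotent up to KDE grid resolution.

Sequences present in the input but absent from **every** output sample
carry no score information beyond "did not grow"; they are imputed at the
mode (0 after centering) and assigned the largest observed merged error, so
they can never reach significance. A sequence with output reads in at least
one replicate is scored from those replicates instead. With the default
pseudocount of 0.5, a zero output count in a single replicate is still
scorable (strongly negative, large error) rather than lost; with
`pseudocount = 0`, such replicates are treated as missing and skipped by
the merge.

## Classification

`classify_designed()` performs a two-sided Z-test of $NS/\sigma$ against 0
(the centered wild type) with Benjamini–Hochberg correction at FDR 0.1,
labelling significant variants `NS_inc` or `NS_dec` by sign. Both
directions are biologically meaningful and are reported at the same FDR,
hence the two-sided choice. A reliability filter then normalises each
error by the interquartile range of the score distribution and excludes
`WT_like` variants with normalised sigma above 0.2 — an imprecise score
near zero is compatible with anything, so it cannot support a confident
wild-type-like call. Significant variants are never excluded by this
filter.

`classify_random()` uses the one-sided (greater) Z-test at FDR 0.05:
rejected sequences are `nucleator`, all others (including every imputed
sequence) `nonnucleator`. The strongest 10 % of the library by score is
flagged as a top-nucleator tier; the flag is intersected with the
nucleator set so it can never mark a nonnucleator.

`merge_duplicates()` collapses repeated protein sequences (within or across
experiments) to the arithmetic mean score and the modal status, with ties
broken conservatively to `nonnucleator`. Afterwards, nonnucleators with
"big errors" — normalised sigma above the same 0.2 cutoff, a single
coherent reliability notion — whose mean score exceeds the minimum
nucleator score are discarded as irresolvable.

`count_gatekeepers()` tallies `NS_inc`/`NS_dec` calls per position of a
designed library and flags gatekeeper positions, where mutations are more
likely to increase nucleation than to decrease it (`n_inc > n_dec`).

## Read processing

`process_fastq()` converts raw amplicon reads to counts under the QC rules
the scoring model assumes:

* **Flank trimming**: the 5′ (25 nt) and 3′ (21 nt) constant regions are
  matched at fixed offsets (fixed-length amplicons; no indel alignment);
  a flank fails when its mismatch count exceeds `floor(0.20 * flank_len)`
  (5 mismatches on a 25-nt flank pass, 6 fail).
* **Quality**: a read fails when any base of its **variable region** has
  Phred < 30. The filter is scoped to the variable region because flank
  bases are already validated by the mismatch tolerance and do not
  determine variant identity.
* **Variant tallying**: designed mode discards interiors outside the
  design whitelist; random mode keeps every distinct interior of the
  expected length.
* **Input coverage**: variants below the input-read threshold (200 for
  designed, 100 for random libraries) in *every* replicate are removed.
  The threshold rule is ambiguous between "below in all replicates" and
  "below in any"; both are implemented (`min_input_mode = "all"/"any"`)
  with the permissive "all" reading as default.

Every read is accounted for exactly once in the QC report (accepted, or
rejected by reason), and with zero read corruption the chain is an exact
inverse of `emit_fastq()`.

## The synthetic experiment generator

`simulate_selection()` generates count tables with the structure the
pipeline assumes: per replicate, input frequencies are log-normal
(dispersion 1.0 by default, mimicking uneven library representation),
output frequencies are proportional to input × exp(true NS) — a
single-round selection multiplier matching the single input→output
log-ratio of the score definition — and counts are multinomial at the
configured depths. Dropout therefore emerges naturally from finite depth;
an optional hard-dropout rate additionally removes whole variants from all
outputs to stress the imputation path. True effects follow a two-component
model: a fraction `p_nucleator` (default 0.3) of variants draw scores from
gamma(shape 2, scale 1.5) on the natural-log scale, the rest are exact
nulls.

What the generator does **not** emulate: PCR amplification bias,
growth-time dynamics, position-dependent sequencing error, toxicity, or
prion-state co-factors. Passing the recovery tests therefore shows the
estimator is consistent for the assumed generative family, not that the
error model captures every feature of real selections.

One property of the default effect distribution deserves note: since the
gamma scale exceeds 1, the selection multiplier exp(NS) has infinite mean.
Most simulated libraries behave well, but occasionally a realization
contains a variant with NS above ~12 whose multiplier monopolises the
output multinomial, causing mass dropout of moderate variants and
depressing the recovered nucleator fraction. The score *ranking* (Pearson
correlation with truth among nucleators) is robust to this; the recovered
class fraction is not always. This is an inherent feature of heavy-tailed
effects under competitive selection, not an estimator defect, and is the
reason real experiments bottleneck library complexity against depth.

### Problem sizes used in the test suite

The simulation-based tests use 200–2,000 variants at depths of $10^5$ to
$2\times10^6$ reads with 3 replicates (about 1,000× coverage, matching
well-designed experiments), 20 null libraries for the FDR study, $10^5$
draws for the NNK law, and ~50-variant libraries for the FASTQ round trip.
All simulations are seeded; the whole suite runs in well under a minute.

## Enrichment analyses

Composition comparisons operate on per-sequence percent vectors (summing
to 100 over the 20 residues), by default over the extension region
(positions 23+), with Welch's unequal-variance t-test and Cohen's d using
the pooled SD. Position-wise tests use the 2×2 chi-square (group ×
class membership) without Yates continuity correction — group sizes are in
the thousands — skipping cells with expected count below 1. The default
physicochemical grouping (aliphatic A/V/L/I/M, aromatic F/W/Y, polar
S/T/N/Q, positive K/R/H, negative D/E, special C/G/P) is an explicit,
overridable argument because no single convention is universal; Cys and
Gly are often worth reporting individually. Residue scales (Kyte–Doolittle
hydropathy, Kanehisa–Tsong β-sheet propensity) ship as editable TSV files
with citations.

Cross-peptide comparisons pair per-position mean scores under N-terminal
or C-terminal anchoring (offset `L_b - L_a`) or an externally supplied
alignment map; multiple-sequence alignment itself is out of scope. The
predictor harness computes the rank-based (Mann–Whitney) AUC with ties
counted ½ and a seeded bootstrap SD; AUC is invariant under strictly
monotone transforms of the predictor.

## Numerical choices and degenerate inputs

* Pseudocount 0.5 on every count (configurable, 0 allowed) prevents
  $-\infty$ scores for partial dropouts; the scoring oracle tests use 0.
* KDE mode: Gaussian kernel, `bw.nrd0`, 512 grid points over the data
  range.
* Enumeration order is position-major, residue-alphabetical, stop last, so
  variant tables diff stably; the position-1 truncation (empty peptide) is
  a valid record.
* A variant's SNV-reachability flag is `FALSE` when the target equals the
  wild-type residue (synonymous changes are tracked separately).
* Zero-total samples, missing references, sub-50 mode-centering sets,
  zero IQR, p-values outside [0, 1], and single-class AUC labels all fail
  fast with informative errors rather than producing silent nonsense.

## Limitations

* The error model is unregularised Poisson; replicate-to-replicate
  overdispersion (bottlenecking, jackpot colonies) is not shrunk away.
* Paired-end merging, adapter discovery and demultiplexing are out of
  scope; the FASTQ entry point expects merged, fixed-length amplicons.
* The generator's parameters are plausibility choices, not calibrated fits
  to any deposited dataset.
* Designed-library nucleotide-level degeneracy (several codons per protein
  variant) is not modelled; protein-level counts are the unit of analysis.
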