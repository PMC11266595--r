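---
title: "Modelling antisense ORF existence, gain and loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling antisense ORF existence, gain and loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asorf)
```

## The model and its assumptions

A locus of `k` codons is an ORF when it starts with `ATG`, ends with a stop
codon, and carries no internal stop. With position-wise independent
composition this gives the stationary probability

$$P_{ORF}(k) = P_{ATG} \cdot P_{stop} \cdot (1 - P_{stop})^{k-2},$$

where `k` counts codons *including* the start and the terminal stop (3k nt).
For an ORF antisense to a coding gene, `P_stop` depends on the codon register
of the overlap. In frame 0 an antisense codon pairs exactly with one sense
codon; an antisense stop requires the sense codon to read `TTA`, `CTA` or
`TCA`, all of which are valid sense codons, so the overlap imposes no
constraint. In frames 1 and 2 an antisense codon spans two consecutive sense
codons. Enumerating all 4096 dicodons:

```{r}
lengths(enumerate_stop_dicodons("as1"))
lengths(enumerate_stop_dicodons("as2"))
```

Of the 192 dicodons that overlap an antisense stop, 64 contain a sense stop
and cannot occur inside a coding gene — but only in frame 1. Frame-1
antisense stop codons are therefore systematically rarer, which favours long
frame-1 asORFs.

The transition (per-generation) probabilities build on stop/start *events* —
gain, loss and stay — computed by exhaustive enumeration of every codon or
dicodon state and its 9 (trimers) or 18 (dicodons) single-nucleotide
neighbours. A substitution has probability $m(a \to b) = u \cdot \mu_{a\to
b}$ with `u` the per-site per-generation rate and $\mu$ the six-class,
strand-symmetric bias spectrum; no per-source renormalization is applied.
Because every gain/loss quantity is linear in `u`, all probability *ratios*
and crossover lengths are invariant to the overall rate scale (this is
asserted in the test suite), which insulates the headline results from the
uncertainty in how the bias weights translate into absolute per-path rates.

Key simplifying assumptions, all deliberate:

* **Independence across codon positions.** Adjacent antisense codons in
  frames 1/2 share a sense codon, but the interior factor is still the
  single-position probability raised to `k - 2`.
* **Single-mutation neighbourhoods.** Multi-hit events per generation are
  ignored (they are $O(u^2)$).
* **Start codons are unconstrained by the overlap.** `P_ATG` and its events
  are computed on the plain trimer measure in every frame. This is the
  approximation with the largest measurable consequence; it is quantified
  below.

## The unnormalized-measure convention

Under the GC model (`gc_model(g)`; per-base probabilities
$p_G = p_C = g/2$), frame-specific stop probabilities are the *plain product
measure mass* of the allowed state set — they are **not** renormalized by the
probability that the sense reading is stop-free. Renormalizing by
$(1 - P_{stop,sense})^2$ would break the exact equality of frames 0 and 2
with intergenic loci, which the enumeration shows must hold (all 192
dicodons are available in frame 2). The test suite pins this equality to
machine precision across the GC and length grid.

The empirical mode (`oligomer_model()`) behaves differently by construction:
codon and dicodon tables are estimated from stop-free ORF interiors and are
therefore intrinsically conditioned on sense stop-freeness. The two modes
are *intended* to differ; the GC mode is the organism-independent idealized
model, the oligomer mode reflects a particular genome's composition,
including its codon usage.

For mutation events, the gain sum runs over source states that carry no
antisense-frame stop at all (for frame 1 this excludes the 64
sense-stop-containing dicodons, which carry an antisense stop even though
they are outside the allowed set), and the loss sum is conditional on the
allowed stop set, per state mass.

## Selection levels

Selection on the sense gene filters which single-nucleotide sense-codon
changes are tolerated:

* `none` — everything except a nonsense mutation (no sense stop may appear);
* `weak` — additionally the amino acid must be conserved or replaced by a
  chemically similar one (`amino_acid_similarity()`; symmetric sets, with
  C, G, N and Q having no partner);
* `strong` — synonymous changes only.

For dicodon states the filter acts on whichever sense codon contains the
mutated position. Intergenic loci have no sense reading; the level is
ignored there.

## The gain equation's third term

The ORF-gain probability sums three configurations: start missing, terminal
stop missing, and exactly one internal stop present. For the third term two
readings exist, kept behind `orf_gain_probability(..., third_term = )`:

* `"joint"` (default): the term carries a factor $P_{stop}$, making it the
  joint probability that an internal position holds a stop *and* loses it.
  This is the probabilistically coherent reading: the stratified forward
  simulation in the test suite (loci drawn from the exactly-one-defect
  stationary classes, one generation of mutation at an inflated rate)
  reproduces it within three standard errors, and the class-mass algebra
  collapses exactly onto this form for intergenic loci.
* `"printed"`: the term uses the conditional loss probability alone, so it
  is larger by a factor $1/P_{stop}$.

The choice moves the gain crossover lengths substantially:

```{r, eval = FALSE}
sp <- mutation_spec()
for (tt in c("joint", "printed")) {
  cat(tt,
      gain_crossover_length(gc_model(0.4), sp, "as1", "none",  third_term = tt),
      gain_crossover_length(gc_model(0.6), sp, "as1", "none",  third_term = tt),
      gain_crossover_length(gc_model(0.6), sp, "as1", "strong", third_term = tt),
      "\n")
}
#> joint 27 46 125
#> printed 21 39 176
```

Two numerical notes on the joint-reading scan. The 40%-GC no-selection
crossover is nearly degenerate: the gain ratio at `k = 26` is 0.9944, so any
hairline difference in conventions moves the threshold between 26 and 27.
And the strong-selection threshold is very sensitive to the tolerance
filter: relaxing it from synonymous-only to the chemically-similar set moves
the 60%-GC crossover from 125 down to 109.

## The synthetic-data generator

`generate_genome()` emulates the inputs of a real analysis: one contig of
intergenic background (i.i.d. bases at the model's GC content), stop-free
sense CDSs on the plus strand, antisense transcript annotations covering
them, and optionally asORFs planted at known frames. A planted asORF is
drawn codon-wise (interior conditioned non-stop), embedded at an offset with
the required codon phase, and guarded by an antisense stop codon immediately
5' of its start so that the longest-ORF-per-stop scanner recovers exactly
the planted interval; whole-window rejection guarantees the sense reading
stays stop-free. The generator reproduces byte-identical output for a fixed
spec.

What it does **not** emulate: introns and splicing, UTR and Kozak context,
codon usage bias (interior codons are i.i.d. from the composition model),
mutation-rate heterogeneity, and linkage. Passing tests therefore show the
pipeline is correct *under the model's own assumptions*; they do not show
the model fits any particular genome.

Desk-scale problem sizes are used throughout the test suite as a deliberate
design choice: genomes of 3–9 CDSs of 60–100 codons, 200 replicates for the
expected-count consistency check, and $10^5$–$4\times10^5$ loci per class
for the forward-simulation oracle, with the mutation rate inflated so that
the probability of two hits in one codon stays below $10^{-3}$ (preserving
the single-mutation regime the analytics assume).

## Accuracy of the expected-count equations

The expected-count check compares scanner output on unplanted synthetic
genomes against the expected-ORF sums, using an oligomer model whose tables
are the generator's *true* conditional measures (the GC mode's unnormalized
convention would be systematically off here, by construction). Two residual
model approximations remain and were quantified analytically and by pilot
simulation at 40% GC:

* the start-codon approximation: the true antisense `ATG` probability is
  frame-dependent (about +7% in frame 0, +14% in frame 1 and −10% in frame 2
  relative to the model's frame-independent value, because the `CAT` sense
  pattern interacts with sense stop-freeness differently per register);
* the interior-independence approximation: shared sense codons induce a
  negative correlation between adjacent no-stop events in frames 1/2, worth
  a few percent on the interior product.

Observed/expected ratios per frame come out near 1.01/1.07/0.94
(frames 0/1/2) at the test's problem size. The consistency test is sized so
that its three-standard-deviation band (roughly ±10% at ~400 expected ORFs
per frame) is sensitive to implementation errors — a wrong locus formula,
frame misclassification, or an off-by-one in the length convention shifts
counts by far more — while the documented approximations stay inside it.

## Numerical and interface conventions

* Coordinates are 0-based half-open on the plus strand internally; GFF3 is
  converted at the import boundary, BED is native.
* `min_len = 30` nt counts the ORF *including* its terminal stop (30 nt = 10
  codons), aligning the scanner with the `k >= 10` bound of the expected
  count sums.
* Locus counts $(l_A - 3k + 1)/3$ are kept real-valued; no flooring.
* Crossover scans use strict inequality and return `NA` when no length in
  range qualifies (e.g. frame 2 under the GC model, where the ratio is
  identically 1).
* "Wholly contained" overlap means `min_overlap = 1.0`; the ≥50% variant is
  an option.
* Degenerate inputs fail loudly: a zero-mass stop set with loss requested,
  empty exon sets, all-ambiguous sequence, region sets with duplicate
  identifiers.
* "FDR corrected" means Benjamini–Hochberg throughout; one-tailed test
  directions are recorded in the output rows.

## Known limitations

Partial overlaps are classified but the probability model assumes complete
overlap; asORFs spanning multiple sense genes are reported but excluded from
per-frame statistics; spliced antisense transcripts are out of scope (each
annotation range is treated as unspliced). The model is a null model: its
value is in exposing where real genomes deviate from it, not in fitting
them.
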