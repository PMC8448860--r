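---
title: "Models and methods: dissecting incipient diploidization with polyforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dissecting incipient diploidization with polyforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyforge)
```

## The biological system and its observables

polyforge models a very young allotetraploid: two diploid genomes (AA and
BB) merged by hybridization and doubling so recently that the tetraploid's
AA subgenome is nearly identical to extant AA diploids, while the BB donor
is unsampled. Four observables carry the signal of incipient
diploidization, and the package implements one module for each:

1. **Depth dichotomy** of an AA diploid mapped onto the tetraploid assembly
   separates the subgenomes (reads pile on AA-derived windows only).
2. **Four-way orthologous alignments** (tetraploid PFA + PFB, diploids PC02
   + PC99) expose de novo mutations as 1:3 genotype columns: three
   sequences retain the ancestral base, one carries the derived base.
3. **Depth ratios between homeologous intervals** expose homeologous
   exchanges: a 4:0 exchange duplicates the donor (≈2× the sample mean) and
   deletes the recipient (≈0×); 3:1 gene-conversion-like events sit at 1.5×
   and 0.5×; balanced 2:2 swaps are dosage-neutral and only visible as
   origin islands in the diploid-coverage partition.
4. **Coding-sequence comparison** across the four copies quantifies
   fractionation (pseudogenes, deletions), synonymous divergence, and —
   through TPM ratios — homeolog expression dominance.

## Decision rules and their parameters

All thresholds default to the working values of the analysis the package
re-implements; each is a plain argument.

| parameter | default | role |
|---|---|---|
| window size | 5 kb | depth windows for partition and HE detection |
| origin threshold | 0.5 × peak depth, strict `>` | AA vs BB window call |
| confident block | ≥ 5 contiguous windows | shorter runs flipped to the opposite origin |
| block cut | gap run ≥ 100 bp in any row | alignment segmentation |
| conserved interval | > 500 bp per row, identity ≥ 0.80 | mutation-calling substrate |
| mutation call | 1:3 column + 5 identical flanks/side | de novo mutation |
| duplication band | ratio ∈ (1.5, 3), open | HE donor candidate |
| deletion bound | ratio < 0.5 | HE recipient |
| segmental minimum | 20 kb | below it, gene-pair resolution |
| 3:1 bands | (1.25, 1.75) and (0.25, 0.75) | nonreciprocal events |
| telomere window | 2 Mb (0.4 × length on short chromosomes) | enrichment test |
| deletion threshold | alignable CDS fraction < 0.2 | deleted vs pseudogene |
| pseudo-count | +1 to both TPMs when min < 1 | finite expression ratios |
| neutral rate *r* | 7.1e-9 /site/year | `t = dS / 2r` |

Design choices where the underlying procedure was open:

- **Peak-depth estimator**: the mode of the integer-binned positive-depth
  histogram, ties toward the larger depth. The published procedure names
  only "genome peak depth"; an integer mode is the simplest estimator that
  is exact on the bimodal diploid-onto-tetraploid track.
- **Run flipping** is applied iteratively, left-to-right, to a fixed point.
  The five-window rule does not specify an order; left-to-right makes
  alternating pathological inputs converge deterministically (covered by
  tests).
- **Four-way identity** = fraction of gap-free columns where all four rows
  carry the same base; `N` is gap-free but never agrees. This is the
  simplest monotone generalization of pairwise identity; a mean-pairwise
  variant would only be laxer. The 80% threshold is applied inclusively.
- **NG86 instead of an ML codon model** for dS: self-contained and
  path-enumerable, and at dS ≤ 0.05 — the regime of this system — counting
  and ML estimates nearly coincide. Site fractions count changes-to-stop as
  nonsynonymous so that S + N = 3 × codons exactly; multi-hit codons are
  averaged over all orderings of the differing positions with equal
  weights, excluding paths through stops (with an unfiltered fallback if
  every path is blocked). Jukes–Cantor correction is undefined at p ≥ 3/4;
  such pairs are flagged saturated rather than extrapolated.
- **Pseudo-count trigger**: "paired TPM values of < 1" is read as *either*
  value below 1 (then both are incremented), which keeps the transform
  exactly antisymmetric under swapping the pair.
- **Pairing unit** for the tetraploid-vs-diploid burden test defaults to
  the chromosome (block-level pairing available); the published test's unit
  is unstated.
- **Cross-sample event identity** for exchanges = reciprocal overlap ≥ 0.8
  of both intervals; the direction-bias chi-squared on occurrence totals is
  emitted with an explicit ambiguity note, since occurrence totals conflate
  event multiplicity with sharing.
- **Heterozygous-variant rescue** in gene curation is out of scope: inputs
  are haploid consensus rows, so roughly the fraction of pseudogene calls
  that genome-scale data attribute to heterozygous variants will be called
  pseudogene here; reports state this.

## The synthetic generator: what it emulates, and what not

`simulate_system()` builds the full system from one seeded configuration:

- **Progenitors** — a random ancestor; AA and BB derived by independent
  per-site substitution at `progenitor_divergence/2` each (default total
  0.034, the synonymous-scale split of the two diploids ≈ 2.4 Mya at
  r = 7.1e-9). A second AA accession (PC99) diverges by 0.011 entirely on
  its own branch, so the reference diploid retains the ancestral state —
  the configuration the 1:3 caller assumes.
- **De novo mutations** — Poisson counts at the diploid rate (default
  1.5e-3/bp, matching the genome-scale density of ~190k calls over 124 Mb)
  with a tetraploid excess of ×1.10; classes drawn from the six-class
  spectrum (default 40% C>T, Ts/Tv 1.8; optional 16-context weights per
  class); sites chosen ≥ 6 bp from every other variant so each planted
  mutation is callable under the flank rule (a flag disables spacing to
  exercise the filter's rejection path).
- **Exchanges** — 4:0 segmental events in sample subsets, 2:2 balanced
  swaps in all samples, 3:1 nonreciprocal copies; positions telomere-biased
  (default 0.6 of events within the window); one planted segmental event is
  forced below the caller minimum as a built-in negative control.
- **Gene fates** — per-subgenome pseudogene/deletion fractions default to
  the strongly asymmetric regime of a fractionating BB subgenome
  (2.9%/3.1% on A vs 6.6%/19.6% on B); pseudogene defects are a premature
  TAA or a 1-bp frameshift, and 2% of intact copies carry a 6-bp in-frame
  deletion (the classifier must call these intact).
- **Depth** — window depth ~ Poisson(depth_mean × copy/2), default 28×;
  negative-binomial overdispersion is a config option, default off; a
  noise-free mode returns exact expectations for recovery proofs.
- **Expression** — log2 ratio mixture: conserved N(0, 0.03) (weight 0.55),
  divergent background N(0, 0.6), dominance component N(shift, 0.03)
  (defaults shift 0.2, weight 0.08). The component widths are chosen so the
  dominance peak is resolvable at the 0.05 histogram bin — emulating a
  clearly visible minor peak at +0.2 (TPM ratio 1.149) over a sharp central
  mode. Pseudogene/deleted copies get TPM near zero.

Not emulated: read-level artefacts (mapping bias, GC bias), indels in the
genome-scale mutation channel (the caller scores substitutions only), TE
and repeat structure, heterozygosity, aneuploidy, and assembly error.
Passing recovery tests therefore demonstrates correctness of the decision
rules under their stated noise models — not robustness to alignment or
mapping artefacts in real data.

## Numerical and degenerate-input conventions

- Coordinates are 0-based half-open internally and in BED/bedGraph output;
  GFF3 is written 1-based inclusive.
- p-values below 2.2e-16 are reported with a floor display string plus an
  exact log-p computed on the log scale (no underflow).
- A paired *t* test on zero-variance differences is an error ("degenerate
  differences"), not p = 0: the statistic is undefined.
- Depth ratio bands are open intervals; values exactly on a boundary are
  excluded, matching the strict wording of the rules ("higher than",
  "less than").
- An all-zero depth track is an error for peak estimation ("no coverage");
  a chromosome shorter than the confident-run minimum collapses to its
  majority origin.
- Ties in the peak-depth histogram go to the larger depth; ties in the
  majority-origin fallback go to the first window's label.

## Problem sizes used by the test and acceptance runs

Unit and property tests run on 2 × 150–600 kb genomes with 2-kb or 5-kb
windows (seconds each). The spectrum-recovery run uses 2 × 2.5 Mb with the
de novo rate raised to 5e-3/bp, yielding ≈ 52,000 recoverable PFA/PC02
calls — enough that three binomial standard errors around Ts/Tv 1.8 and
40% G:C→A:T are a fraction of a percent. The exchange-recovery suite uses
20 seeded replicates at 16× Poisson depth; the NG86 oracle check is
exhaustive over all 2- and 3-difference sense codon pairs. These sizes are
the package's chosen desk-scale study conditions and are fixed in the test
code.

## Known limitations

- Junction refinement of partition and exchange breakpoints to base-pair
  resolution (alignment of junction intervals) is exposed only as
  window-grid output; calls are window-quantized.
- Balanced-exchange detection needs the island and both flanks to survive
  the five-window merge, so events under ~5 windows are invisible by
  construction.
- NG86 dS saturates near p = 3/4 and the package refuses to extrapolate;
  deep divergences need an ML codon model, which is out of scope.
- The direction-bias test for exchange sharing is a labelled approximation
  (see above), not a calibrated inference.
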