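---
title: "Locating a duplication-based Y region: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating a duplication-based Y region: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexhap)
```

# The problem

In many fish, sex is determined by a young, homomorphic XY pair whose
male-specific region is small — sometimes a single tandem duplication
carrying an extra copy of a sex-pathway gene such as *amh*. Two
complementary kinds of evidence locate (or reject) such a region in a
population:

1. **A pooled sex scan.** Whole-genome sequencing of a male pool and a
   female pool, compared site by site. In an XX/XY system, an X-linked
   allele in the differentiated region is fixed in females and near 50%
   in males, so sex-patterned SNPs cluster in the sex-determining window.
2. **A Y-haplotype route.** A reference-guided "expected Y" is built by
   editing the X reference with known duplication/deletion breakpoints.
   Long reads are then classified as Y-origin or not by a *diagnostic
   indel* — here a 275 bp deletion carried only by the truncated gene
   copy on the duplication — and the Y-specific subset is condensed into
   a consensus.

`sexhap` implements both routes end to end, together with a
synthetic-data generator that produces references, structural variants,
pooled counts and error-modelled long reads with full ground truth, so
the whole pipeline is testable without any external data.

# The pooled scan

## Allele frequencies and pool-Fst

Counts come in per site and pool over A/C/G/T (plus N and deletion
columns, which the scan ignores — it targets SNPs). Alleles supported by
fewer than `min_read_count` reads (default 2) are discarded as
sequencing error; frequencies are renormalised over the retained counts.

Differentiation is measured with the classical pi-based pool estimator:

$$F_{ST} = \frac{\pi_T - \pi_W}{\pi_T}, \qquad \pi = 1 - \sum_i p_i^2,$$

with $\pi_W$ the unweighted mean of the two pool diversities and
$\pi_T$ computed from the summed retained counts. No unbiasedness
correction is applied, so identical pools give exactly 0 and pools fixed
for different alleles give exactly 1; $\pi_T = 0$ returns 0 by
convention. Because the pooled total weights pools by depth while
$\pi_W$ does not, strongly unequal depths can push the raw value
slightly negative; such values are truncated to 0, the convention of
sex-scan tools. The estimator is deliberately simple and is isolated in
`site_fst()` so it can be swapped.

## The sex-pattern filter

A site is a candidate when

* both effective depths lie in `[min_depth, max_depth]` (default
  `[10, 100]`),
* one pool's major allele reaches `fixed_threshold` (default 0.9), and
* **that same allele** sits in `[min_polymorphic_freq,
  max_polymorphic_freq]` (default `[0.3, 0.7]`) in the other pool.

The third rule checks the fixed allele's frequency in the opposite pool,
not the opposite pool's own major allele — the XY expectation is that
males carry the female-fixed X allele at about 0.5. Both directions are
tested, so an X0-like or ZW-like pattern is also caught.

Candidates and Fst are summarised in non-overlapping windows anchored at
position 1 (default 10 kb, the conventional scan window). A window is
reported as *enriched* when its candidate count exceeds the 95th
percentile of per-window candidate counts **and** reaches an absolute
floor of 3 co-localised candidates. The floor exists because binomial
sampling noise produces scattered single-candidate windows at a few
percent of sites even without any sex linkage; requiring three
co-localised candidates keeps a no-GSD simulation clean without touching
a genuinely differentiated window, which carries tens. Both knobs are
arguments of `enriched_windows()`.

# The expected Y haplotype

`build_expected_y()` edits the X with a structural-variant description:
the duplicated interval is copied and inserted at its breakpoint, then
the copy receives deletions, insertions and SNVs. Deletion handling
follows the reconstruction rule for long-read mapping targets:

* deletions **< 500 bp** are *kept* (the sequence is retained) — long
  reads cross them, and keeping the sequence preserves mappability;
* deletions **≥ 5 kb** are *applied* (the sequence is removed);
* the **diagnostic deletion is always applied**, whatever its size — it
  is what defines the Y;
* deletions between the two thresholds are refused unless the spec
  carries an explicit per-deletion `apply` flag. No published rule
  covers that range, and guessing silently would corrupt the haplotype,
  so the package demands an explicit decision.

The builder maintains a run-length coordinate map tagging every Y base
`original`, `duplicate` or `insertion` with its X origin; `y_to_x()`
inverts it, and the map makes the construction checkable: the length
identity $|Y| = |X| + |dup| - \sum \text{applied deletions} + \sum
\text{insertions}$ holds exactly, and concatenating the
`original`-tagged segments reproduces the X byte for byte.

`liftover_annotations()` projects X features onto the Y: features
overlapping the duplication source appear twice (`_dup`-suffixed),
truncation by applied deletions is flagged, and when one deletion
removes the tail of one copy gene, the head of the next and the whole
interval between them, the two are emitted as a single
`geneA-geneB_chimera` feature, upstream gene first.

All user-facing coordinates are 1-based inclusive; BED output is
0-based half-open.

# Long reads: bait filter, alignment, classification

## Baits

Reads are first subset by similarity to the genes of interest. Each gene
contributes one bait per maximal unmasked run of its span; masking
exists because some intervals (e.g. a *dot1l* intron resembling the
unrelated *vasa* gene) would recruit off-target reads, and a gene with
one masked intron therefore yields exactly two baits. A read is retained
when any bait, in either orientation, anchors at least `min_hit_score`
exact-match bases through the seed-and-chain kernel (default 60 bp —
a calibrated default playing the role of a BLAST cutoff, with a
measured false-positive rate below 1% on composition-matched random
reads). An optional `margin` argument additionally requires the best
gene to beat the second best, for paralog disambiguation. Filtering
happens on raw reads; the 23 bp end trimming (a fixed allowance for
low-quality read ends) follows it, preserving the conventional order.

## The alignment kernel

The same compiled kernel backs the bait filter, the classifier and the
consensus stacker: exact k-mer seeding (k = 15), co-linear chaining with
a maximum diagonal jump of 20 kb (so structural deletions are crossed by
the chain), then banded affine-gap alignment (match +2, mismatch −4,
gap open 4, gap extend 2; a gap of length $g$ costs $4 + 2g$) in a band
spanning the chained diagonals plus 200 bp of pad, with free end gaps on
the target. The band keeps a 10 kb read's alignment in the
tens-of-milliseconds range while tolerating several percent error and
the diagnostic-scale indels. The reverse complement is tried when the
forward chain fails. On small sequences the kernel reproduces the
optimal scores of a classical quadratic global-in-query aligner
(`Biostrings::pairwiseAlignment`, `type = "global-local"`), which the
test suite uses as an independent oracle.

One consequence of free target end gaps matters for indel measurement:
a deletion sitting within a few bases of the target's end can be
absorbed into the free end gap instead of being reported. Alignments
used to read off indel lengths therefore include flanking context
(500 bp in the packaged analyses) so every planted indel is interior.

## Diagnostic classification

`classify_read()` aligns the read to the **X** haplotype around the
diagnostic locus: a Y-origin read crossing the deleted region shows a
deletion-shaped gap against the X, which gives a crisper length readout
than mapping to the expected Y (where the same evidence appears as an
absence). The decision rule:

* the alignment must span the diagnostic interval with at least `flank`
  anchored bases on both sides (default 200 bp);
* deletion gaps are clustered, merging runs separated by at most 10
  aligned bases (noisy reads split long gaps);
* if the clustered deletion overlapping the diagnostic interval has
  length within `tol` of the expected length (default 30 bp ≈ 6.44%
  error over 275 bp plus alignment wobble), the read is **Y-specific**;
  spanning without such a deletion is **non-Y**; anything else —
  no bait hit, no alignment, or not spanning — is **unassigned**.

Retained reads partition exactly into the three labels, and each read's
label is independent of the rest of the batch. Note the biology the
truth tables encode: a Y *chromosome* also carries the conserved
original region, so only reads crossing the diagnostic junction inside
the duplicated copy carry the deletion; Y-origin reads from conserved
regions are correctly non-Y under the diagnostic definition.

# Backbone consensus

The Y-specific subset is condensed by star alignment: each read is
aligned independently to a backbone (typically the expected Y) and
stacked column-wise — no multiple alignment is attempted, because a
backbone exists by construction and star alignment against it is both
simpler and order-independent. Per column:

* depth below `min_depth` (default 2) gives `N`;
* a gap-majority column is deleted from the consensus;
* otherwise the majority base is called if its agreement reaches 0.6,
  else the IUPAC code of all bases with ≥ 25% support;
* insertions relative to the backbone are emitted when at least half of
  the covering reads carry one, with the plurality sequence.

Depth failure is always `N`, never a partial code. At the coverages a
handful of Y-specific reads provide, runs of ambiguity codes are the
expected and honest output — exactly the behaviour reported for
low-coverage consensus work — and error-free coverage at depth
reproduces the truth exactly.

# The synthetic-data generator

The generator emulates the study conditions the pipeline targets:

* **Reference and genes.** A random sequence at GC 0.41 (tilapia-like)
  with non-overlapping gene models. The full-scale layout mirrors the
  studied system: a 60 kb X region whose 51 kb duplication source
  carries *dot1l* (with a masked vasa-like intron), *oaz1*, a linked
  gene and a 7-exon *amh*; the copy carries two applied > 5 kb deletions
  (one fusing the *dot1l* and *oaz1* copies into a chimera), the 275 bp
  diagnostic deletion in the truncated *oaz1* copy, and the *amh*-copy
  edits (5 bp exon-6 insertion, 233 bp exon-7 deletion — both below the
  500 bp keep threshold, hence present on the true Y but retained in
  the expected Y). A desk-scale layout (20 kb / 12 kb) has the same
  qualitative structure for fast tests.
* **Pooled counts.** Pools of 10 per sex; depth Poisson with mean 170
  per pool (10 samples at ~17×), thinned to a 20% subsample (≈ 34×
  realised, inside the scan's depth window). Thinning is applied
  independently per pool; whether a real subsample was drawn before or
  after pooling is not derivable from the design, and per-pool thinning
  is the variant that keeps pools independent. Background polymorphic
  sites (1/kb) share a population frequency between sexes, sampled
  through 2n chromosomes per pool and then through reads; fully
  sex-linked sites (5/kb inside the sex region — a differentiated
  region accumulates fixed differences) put the Y allele at exactly 0.5
  among male chromosomes and 0 in females. Sequencing error flips each
  sampled base uniformly at rate 0.002. Only polymorphic sites are
  emitted; monomorphic sites carry no scan information. The simulated
  chromosome (260 kb desk / 1.3 Mb full in the presets) is much longer
  than the sex region so that truly sex-linked windows stay a small
  fraction of all windows and the empirical enrichment null is
  meaningful.
* **Long reads.** Lognormal lengths truncated below at 1 kb; errors
  injected in one pass over the template at total rate 0.0644 — the
  nanopore-scale figure the classifier must tolerate — split
  0.4/0.3/0.3 into substitutions, insertions and deletions as a generic
  nanopore-like profile. Reads are forward-strand (a generator
  simplification; the aligner itself handles both orientations), ids
  encode nothing about origin, and the truth table carries provenance.
  FASTQ output gets a constant quality derived from the error rate;
  nothing downstream uses base qualities.

When the injected reads are realigned to their source, the measured
per-base error (edit operations per aligned target base) comes out
slightly below the injected rate (≈ 6.3% for 6.44% injected): optimal
realignment occasionally explains two adjacent planted events with one
cheaper edit. This is a property of any alignment-derived error
estimate, including the published ones the figure is compared against.

What the generator does **not** emulate: read-level short-read
artifacts (duplicates, adapters, insert sizes — counts are simulated at
pileup level), reference mis-assembly, paralogous mismapping,
non-uniform long-read error (homopolymer bias), or B-chromosome
coverage effects. Passing tests therefore demonstrate the pipeline's
logic and calibration under a clean generative model, not robustness to
every artifact of real data.

# Presets and reproducibility

`run_pipeline()` ties the stages together under one seed, with three
presets mirroring the study designs this package addresses:
`"koka-like"` and `"kpandu-like"` (XY: planted sex-linked window,
reads from both haplotypes) and `"hora-like"` (no GSD on the scanned
chromosome: shared allele frequencies, no Y reads). Long reads in the
presets are drawn locus-proximal — in a real dataset the genome-wide
winnowing has already happened upstream of the classifier, and
simulating reads the bait filter would discard wholesale only burns
time. Seeds are mandatory (no wall-clock default); every output is
reproducible bit for bit from (config, seed), and the YAML config
round-trips losslessly with unknown keys rejected.

Problem sizes in the packaged tests — 20 kb desk regions, tens of
reads, 5 kb consensus backbones, 500-site power checks — were chosen as
the smallest scales at which every property is still measured with
comfortable Monte-Carlo margins.

# Known limitations

* The Fst estimator is the plain pi-based pool estimator; tools built
  around other estimators will differ in value (not, at these
  thresholds, in candidate calls on clear XY patterns).
* The classifier keys on a single diagnostic indel. A Y lacking that
  indel (as in divergent populations) yields no Y-specific reads — by
  design, that is the assay's negative result, not a failure mode.
* Star consensus cannot recover insertions supported by fewer than half
  of the covering reads, and at depth < `min_depth` it reports `N`
  rather than guessing.
* The expected-Y builder supports tandem, same-orientation duplications
  only; inversions and translocations are out of scope, as is inferring
  breakpoints from read data — breakpoints are inputs here.
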