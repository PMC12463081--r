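---
title: "Classifying Polycomb H2Aub loops from capture Hi-C"
author: "pcgloop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Polycomb H2Aub loops from capture Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgloop)
```

## The problem

Polycomb group complexes silence developmental genes through two
chromatin marks: PRC1 deposits H2A monoubiquitination (H2Aub) and
PRC2 deposits H3K27me3. In *Arabidopsis* the two marks only partially
co-localize, so PcG targets split into only-H2Aub, only-H3K27me3 and
co-marked regions. Capture Hi-C with probes tiled over H2Aub peaks
enriches exactly the chromatin contacts anchored at H2Aub regions and
asks how these regions are organized in space: do only-H2Aub regions
stay apart from H3K27me3 chromatin, or do they cluster with it into
PcG hubs, and what does either arrangement do to transcription?

`pcgloop` implements the downstream analysis of such an experiment:
probe design over peaks, in-silico DpnII digestion and bait mapping,
the five-way loop taxonomy with hub detection, wild-type versus
PRC1-mutant loop-fate analysis, occupancy enrichment against random
regions, and expression linkage. A seeded generator produces complete
toy datasets with planted ground truth, so the whole pipeline is
testable offline.

## Coordinates and the interval model

All coordinates are 0-based half-open (BED convention), everywhere.
GFF3 input is shifted on read (start − 1). Two intervals overlap when
they share at least one base on the same chromosome
(`a$start < b$end && b$start < a$end`); overlap queries ignore
strand. Strand matters in exactly one place: promoter construction,
where the promoter is the 1000 bp window immediately upstream of the
strand-aware gene start. A configurable `min_overlap` is exposed on
the overlap engine, but every published-style rule in this package
uses the plain at-least-one-base reading.

## Restriction fragments

`digest_genome()` cuts immediately 5′ of every GATC occurrence. DpnII
leaves a 5′ overhang in vitro, but for fragment bookkeeping only the
cut position matters, and placing it at the site start matches the
fragment maps that Hi-C digestion tools produce. Fragments tile each
chromosome exactly — sorted, gap-free, summing to the chromosome
length — and this invariant is asserted in the test suite against a
naive text-scan oracle. Ambiguity codes (N) never match the site.
Fragment ids are assigned in chromosome-then-start order, so id order
is genomic order; loop identity is the unordered pair of anchor
fragment ids stored with the smaller id first.

## Probe design

Capture probes are 100 bp and placed by a length-conditional rule on
each peak region of length L:

* L < 300: one probe centered at the midpoint;
* 300 ≤ L ≤ 500: two probes, centered at ⌊L/3⌋ and ⌊2L/3⌋;
* L > 500: three probes, centered at ⌊L/4⌋, ⌊L/2⌋ and ⌊3L/4⌋.

The three clauses must partition all lengths, so the boundaries are
read inclusively for the middle clause. Fractional offsets are
floored; the probe interval is `[center − 50, center + 50)`. A probe
that would overhang its region (possible only for regions shorter
than the probe) is clipped and flagged rather than discarded — every
region is entitled to its probe. Bait chemistry (biotinylated RNA,
complementarity) is irrelevant downstream; probes are genomic
intervals plus an optional extracted sequence.

```{r probes}
design_probes(regions("chr1", 1000, 1250))
```

## The five-way loop taxonomy

Bait fragments are the restriction fragments overlapping at least one
H2Aub peak; those also overlapping an H3K27me3 peak are
H2Aub/H3K27me3 baits, the rest only-H2Aub baits. By the capture
principle a loop must have at least one bait anchor; loops without
one are dropped with a logged count. Two bait anchors make a
Bait-Bait loop, exactly one a Bait-Nonbait loop.

The PcG class follows from the anchor bait classes:

* **Both-loop** — one only-H2Aub bait anchor and one H2Aub/H3K27me3
  bait anchor;
* **only-H2Aub loop** — every bait anchor only-H2Aub, no
  H2Aub/H3K27me3 bait anchor;
* **H2Aub/H3K27me3 loop** — at least one H2Aub/H3K27me3 bait anchor
  and no only-H2Aub bait anchor.

One corner case is not covered by that wording: a Bait-Nonbait loop
whose only bait is only-H2Aub but whose non-bait anchor overlaps an
H3K27me3 peak. When fragment map and H3K27me3 peaks are supplied,
such loops are reclassified H2Aub/H3K27me3 — the literal
"at least one anchor is H3K27me3-enriched" reading — and flagged in
the `nonbait_k27` column for transparency. Without peak information
the bait-anchor rule stands.

**Hub detection.** The anchors of Both-loops seed the PcG hub. A
non-Both loop is a hub member iff it shares at least one anchor
fragment with that seed set — one-step sharing, which is the literal
reading of a hub "started with" the Both-loop anchors. Two options
widen or narrow this: `transitive = TRUE` grows the hub to the full
anchor-sharing connected component, and `share_anchors = "bait"`
consults only bait anchors when testing sharing. Both are exposed
because the narrative does not pin either choice down; the defaults
are the literal reading. The five final classes (PcG hub Both /
only-H2Aub / H2Aub-H3K27me3, Pure only-H2Aub / H2Aub-H3K27me3)
partition every retained loop, and hub membership is verified in the
tests against a brute-force oracle on random loop sets.

**Geometry.** Loop length is the distance between anchor-fragment
midpoints — symmetric and robust to fragment size, since no
convention is stated for the published analysis. Trans-chromosomal
pairs have no length and are flagged. The per-gene loop span splits a
gene's partner anchors by genomic side (left/right of the gene) and
reports the maximum pairwise midpoint distance per side; a
`from_gene` mode measuring the maximum distance from the gene
boundary is available because the phrase "maximum distance between
other same-direction anchors" admits both readings. Anchor feature
annotation uses the precedence exon > intron > promoter > intergenic
on one-base overlap; a precedence is required because anchors
routinely span feature boundaries.

## Wild-type versus mutant

Loops are matched across genotypes on canonical fragment-pair
identity: disappeared (WT only), maintained (both), new (mutant
only). The histone-modification fate of a WT loop is read off its
bait anchors: the mutant/WT ratio of length-weighted mean occupancy
over the anchor fragment, with a decrease called when
log2(ratio) < −0.2 — the differential-binding fold-change threshold
used with such data — or, alternatively, from a supplied
differential-region list. A loop is Hl when at least one bait anchor
lost a relevant mark, Hm otherwise. Mark relevance follows the loop
class (only an H2Aub decrease counts for only-H2Aub loops; either
mark for H3K27me3-involved loops), restricted at each anchor to the
marks that anchor carries — an only-H2Aub bait has no H3K27me3 to
lose, so its missing H3K27me3 record is not "missing data". Whether
one or both anchors must lose the mark is genuinely open; the default
is at-least-one (`anchors_mode = "both"` for the strict reading).
Anchors with no HM data default to maintained, with a warning.

Crossing loop fate with HM fate gives the four cells Ll/Hl, Ll/Hm,
Lm/Hl, Lm/Hm, which partition the WT loops. Association between the
two fates is tested with Pearson's chi-squared without continuity
correction (counts at this scale make Yates immaterial; it is
configurable), and the odds ratio uses the Haldane 0.5 correction
when a cell is empty.

New loops are typed against the WT bait set (the capture design is
fixed); anchors of new loops that are neither WT baits nor WT loop
anchors are the "new Nonbait anchors", reported with their partner's
bait class and fed to the enrichment module.

## Occupancy enrichment

`mean_occupancy()` computes per-region length-weighted mean signal.
Uncovered bases count as zero by default — dividing by the full
region length — because a region half-covered by strong signal is
not as occupied as a fully covered one; the covered-bases dialect
(what `bedmap --wmean` does) is available as `mode = "covered"` since
the exact upstream dialect is not verifiable from a methods section.
Random regions are count- and length-matched to the targets and
placed uniformly in an explicit genome space, one draw per
invocation, mirroring the single-random-set design; the draw is
reproducible under a seed. Per-mark two-sided Mann-Whitney U tests
are corrected across the marks tested in one invocation by
Bonferroni-Holm, and the enrichment score is log2(target mean /
random mean) with a pseudocount of 1e-3 of the genome-wide track
mean so that empty random sets at toy scale keep the score finite.

## The synthetic-data generator

The generator emulates the statistical structure the analysis is
built to detect; its defaults are fixed study conditions, not tuning
knobs.

* **Genome** — two chromosomes of 1.5 Mb. GATC sites are planted at
  geometric gaps with mean 260 bp, the genome-average DpnII spacing,
  by scrubbing accidental GATC from the filler sequence; planted
  sites are therefore the exact cut set, and mean fragment length is
  the mean gap plus the 4 bp site.
* **Peaks** — 1000 H2Aub peaks on distinct fragments, each spanning
  60–85% of its fragment; 45% of baits co-marked with H3K27me3, plus
  200 H3K27me3-only peaks elsewhere. Peaks covering most of their
  fragment guarantee that a planted occupancy loss is visible at
  fragment resolution (see below).
* **Loops** — 300 Both-loops seeding hubs, 250 + 200 hub-attached
  only-H2Aub and H2Aub/H3K27me3 loops sharing an anchor with a
  Both-loop, and 40 + 25 Pure loops drawn from bait pools reserved
  disjoint from all hub seeds. A 32% Bait-Nonbait fraction applies to
  the non-Both loops (Both-loops are Bait-Bait by definition), with
  peak-free partner fragments. Anchor distances are log-normal with
  median 25 kb, echoing the reported scale of Bait-Bait loops. The
  resulting set is ~92% hub loops.
* **Mutant** — each bait fragment loses its marks with probability
  0.5 at a planted log2 fold change of −1; a WT loop disappears with
  probability 0.8 if its HM fate is Hl and 0.2 if Hm. HM loss is
  planted at fragment level (not per loop) because hub loops share
  anchors: per-loop HM fates are then *derived* by the same anchor
  rule the pipeline applies, which is what makes zero-noise recovery
  exact. 80 new loops appear in the mutant, half recruiting fresh
  peak-free fragments; those fragments carry an elevated
  heterochromatin-like track (H3K27me1) so the enrichment module has
  a planted positive.
* **Expression** — log-normal baseline multiplied by 0.4 at
  H3K27me3-marked regions and 0.6 at loop anchors; up-regulation
  probabilities per fate cell of 0.5 / 0.3 / 0.3 / 0.05
  (Ll/Hl, Ll/Hm, Lm/Hl, Lm/Hm), so the combined loss of loop and mark
  is the strongest activator.

The signal tracks are noise-free step functions (baseline 1, peaks
8). With peaks covering ≥60% of their fragment and boost 7, a lost
peak moves the fragment-level log2 ratio to at most −0.7, safely past
the −0.2 threshold, while maintained fragments sit exactly at 0; this
detection margin is what makes the planted HM-fate confusion matrix
exactly diagonal. Real ChIP-seq tracks are noisy, peaks do not align
with fragment boundaries, and loop calling is itself statistical —
so passing the zero-noise recovery tests demonstrates correctness of
the classification logic, not robustness to measurement noise.

Truth tables (bait classes, per-loop classes, per-loop fates,
per-fragment HM changes, per-gene labels) are first-class outputs;
tests never re-derive truth from the generated files.

```{r sim, eval = FALSE}
ds <- simulate_dataset(sim_config(seed = 1))
cl <- classify_loops(ds$loops_wt, ds$baits, ds$fragments, ds$peaks_k27)
planted_truth_compare(ds$truth$loop_class, cl,
                      truth_col = "final_class",
                      pred_col = "final_class")$accuracy
```

## Numerical and design choices

* Expression bins default to a zero bin plus quartiles of the
  nonzero values, since the published proportional-expression bins
  are unstated; `bin_edges` overrides them.
* A gene overlapping several bait-region groups is assigned once by
  precedence PcG hub > Pure > Nonloop, then H2Aub/H3K27me3 before
  only-H2Aub — a fixed tie-break that keeps the six groups disjoint.
* Differential-expression labels are inputs, never fitted here.
* The statistical loop calling that produces input loop tables is
  out of scope; `chicago_weights()` records the upstream caller's
  weight settings as passthrough metadata only.
* `run_pipeline()` is the single chained entry point (YAML-style
  config, JSON manifest with config hash and input checksums); the
  exported functions and `scripts/acceptance.R` are the command-line
  surface.
* Problem sizes in the test suite (toy genomes of a few kb for
  digestion oracles, loop sets up to 5000 for the hub oracle, 100–200
  seeded replicates for the statistical properties, the default
  3 Mb / 815-loop dataset for end-to-end recovery) were chosen so the
  whole suite characterizes each property tightly at desk scale.

## Limitations

The package consumes called peaks, called loops and precomputed
differential-expression labels; it does not align reads, call
interactions, or fit differential models. Genome-scale headline
counts from a real experiment (tens of thousands of loops) depend on
those upstream callers and on deposited raw data, and are therefore
out of reach of the bundled generator, which targets the *structure*
of the analysis — class partitions, hub logic, fate coupling,
enrichment arithmetic — at a size where exact oracles are feasible.
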