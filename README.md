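# pcgloop

Downstream analysis of capture Hi-C experiments targeting
H2Aub-marked (Polycomb PRC1) chromatin in plants.

## What it is for

Polycomb complexes silence genes through two histone marks — H2Aub
(PRC1) and H3K27me3 (PRC2) — which in *Arabidopsis* only partially
co-localize. Capture Hi-C with probes tiled over H2Aub peaks enriches
the chromatin loops anchored at H2Aub regions and asks how those
regions are arranged in space and what that arrangement does to
transcription. `pcgloop` is for analysts holding the called outputs
of such an experiment (peaks, loop tables, signal tracks, expression
tables) who need the downstream classification and comparison logic:

* **in-silico digestion & bait mapping** — DpnII (GATC) fragment maps
  with an exact tiling invariant; fragments overlapping H2Aub peaks
  become baits, subtyped *only-H2Aub* vs *H2Aub/H3K27me3* by
  H3K27me3 overlap;
* **probe design** — the length-conditional rule: 1 centered probe
  for regions < 300 bp, 2 probes at 1/3 and 2/3 for 300–500 bp,
  3 probes at 1/4, 1/2, 3/4 beyond 500 bp, each 100 bp;
* **five-way loop classification** — Both-loops (one bait of each
  subtype) seed PcG hubs; loops sharing an anchor with a Both-loop
  are hub members, the rest are Pure; crossed with baitness
  (Bait-Bait / Bait-Nonbait), loop length and anchor feature
  annotation;
* **wild-type vs mutant comparison** — disappeared / maintained / new
  loops, histone-modification fate at bait anchors
  (|log2 mutant/WT| > 0.2 with the decreasing sign), the
  Ll/Lm x Hl/Hm cross-classification, chi-squared association with
  odds ratio, and characterization of newly formed loops;
* **occupancy enrichment** — log2(target/random) of length-weighted
  mean occupancy against count- and length-matched random regions,
  Mann-Whitney tested and Holm-corrected across marks;
* **expression linkage** — expression-bin proportions across
  PcG hub / Pure / Nonloop bait regions and up-regulated-gene
  fractions per loop-fate cell;
* **synthetic data** — a seeded generator with planted ground truth
  (classes, fates, HM changes, DE labels) so every stage is testable
  offline.

Coordinates are 0-based half-open (BED) throughout; standard formats
(FASTA, BED, bedGraph, BEDPE-like loop tables, GFF3, TSV) are read
and written by the package.

## Worked example

Simulate the default dataset, classify its wild-type loops and cross
the loop fates with the histone-modification fates in the mutant:

```r
library(pcgloop)

ds    <- simulate_dataset(sim_config(seed = 1))
baits <- type_baits(map_regions_to_fragments(ds$peaks_h2aub, ds$fragments),
                    ds$fragments, ds$peaks_k27)
cl    <- classify_loops(ds$loops_wt, baits, ds$fragments, ds$peaks_k27)
table(cl$final_class)
#>           PCGHUB_BOTH PCGHUB_H2AUB_H3K27ME3     PCGHUB_ONLY_H2AUB
#>                   300                   200                   250
#>   PURE_H2AUB_H3K27ME3       PURE_ONLY_H2AUB
#>                    25                    40

m  <- match_loops(cl, ds$loops_mut)
cl <- loop_fates(cl, m)
hm <- rbind(hm_change(baits$fragment_id, ds$fragments,
                      ds$tracks$h2aub_wt, ds$tracks$h2aub_mut, "H2Aub"),
            hm_change(baits$fragment_id, ds$fragments,
                      ds$tracks$k27_wt, ds$tracks$k27_mut, "H3K27me3"))
cl <- hm_fate_at_anchors(cl, hm, baits)
cc <- cross_classify(cl)
cc$cells
#>    cell   n proportion
#> 1 Ll/Hl 435 0.53374233
#> 2 Ll/Hm  50 0.06134969
#> 3 Lm/Hl 126 0.15460123
#> 4 Lm/Hm 204 0.25030675
association_test(cc$counts)[c("statistic", "p_value", "odds_ratio")]
#> chi-squared = 242.9, p = 9.29e-55, OR = 14.1
```

Of the 815 loops, 750 (92%) belong to PcG hubs. Loops that lose their
anchor marks in the mutant are strongly over-represented among
disappeared loops (Ll/Hl is the modal cell; odds ratio ≈ 14),
mirroring the coupling the generator plants (loss probability 0.8
with HM loss vs 0.2 without). `planted_truth_compare()` confirms that
every planted class and fate is recovered exactly on this noise-free
dataset.

`run_pipeline(list(simulate = list(seed = 1)), out_dir)` chains all
stages and writes result tables plus a JSON run manifest.

## Documentation

The methods vignette (`vignettes/h2aub-loop-analysis.Rmd`) describes
the model, every tunable parameter with its default and rationale,
the generator's design and what passing its tests does and does not
show about real data.
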