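# epidyn

Integrative epigenome-dynamics analysis for staged differentiation time
courses — built for the hPSC → vascular mesoderm (VME) → endothelial
progenitor (EPC) → hematopoietic progenitor (HPC) design, applicable to
any short multi-stage series with two histone marks, chromatin
accessibility, and expression.

Hematopoietic specification is driven by *bivalent* promoters — regions
carrying both H3K4me3 and H3K27me3 that hold developmental genes poised —
resolving stage by stage, while waves of chromatin accessibility open and
close the binding sites of lineage transcription factors. epidyn turns
that picture into one seeded pipeline:

1. **Chromatin states.** Mark signal is binned (200 bp), binarized
   against a Poisson background (bin is "on" when
   P(X ≥ count | λ = genome mean) < 10⁻⁴), and segmented with a 4-state
   multivariate Bernoulli hidden Markov model fit by Baum–Welch EM and
   decoded by Viterbi. States are labeled H3K4me3-only / bivalent /
   H3K27me3-only / unmarked from their emission probabilities.
2. **Bivalent promoter fates.** A gene is bivalent when its promoter
   (TSS ± 2.5 kb) overlaps bivalent segments by > 200 bp in total. Each
   bivalent promoter takes one of four modes between successive stages:
   stable, **activated** (→ H3K4me3-only), repressed (→ H3K27me3-only),
   or resolved-unmarked.
3. **Accessibility dynamics.** Per-stage peaks are merged (≤ 100 bp) into
   a consensus set; counts → RPKM → presence filter (RPKM > 5 in ≥ 2
   stages) → quantile normalization → CV filter (CV ≥ 10%) → quantile
   normalization → z-score; then fuzzy c-means (c = 6, m = 1.25) groups
   temporal profiles, and clusters map to categories I/II/III (open
   early / mid / late) by their centroid's best consecutive stage pair.
4. **Motifs and candidates.** PWM scanning (log₂-odds, both strands,
   ≥ 80% of maximum score) feeds a one-sided Fisher exact test of
   motif-bearing peak proportions per category; factors enriched in
   categories II/III that are themselves activated bivalent genes become
   the **candidate regulators**.
5. **Footprints.** Base-resolution cut counts are averaged over
   motif-centered windows; depth = 1 − mean(core)/mean(flank) quantifies
   the protection dip.
6. **Knockout contrast.** Peaks are classified by the stabilized fold
   change r = (WT + 0.5)/(KO + 0.5): dependent (r ≥ 2), independent
   (1/r ≥ 2), or unchanged, with percentages printed half-up at one
   decimal.

A bundled synthetic-data generator (`synthetic_config()`,
`simulate_all()`) plants ground truth for every one of these readouts —
promoter states and transition modes, six accessibility archetypes in
three categories, category-specific motifs, footprint dips of known
depth, and a WT/KO pair with planted fractions — so the entire pipeline
is testable offline and end to end.

## Worked example

```r
library(epidyn)

cfg    <- synthetic_config(seed = 1)   # 150 genes, 450 peaks, 4 stages
report <- run_all(cfg)

report$transitions[["hPSC->VME"]]$ratios
#>   stable_bivalent         activated         repressed resolved_unmarked
#>             0.710             0.188             0.058             0.043

report$candidates
#>   tf_name       best_q
#> 2    JUNB 1.838854e-11
#> 3   RUNX1 1.838854e-11
#> 1   GATA2 3.109987e-11

report$ko[, c("label", "count", "total", "percent_string")]
#>         label count total percent_string
#> 1   dependent   152   450          33.8%
#> 2 independent    60   450          13.3%
#> 3   unchanged   238   450          52.9%

round(report$footprints$JUNB$depth_by_stage, 2)
#>  hPSC   VME   EPC   HPC
#> -0.01  0.09 -0.11  0.47
```

Reading the numbers: 18.8% of the 69 promoters bivalent in hPSC resolve
to H3K4me3-only at the first transition (the generator plants 20%); the
candidate list is exactly the planted regulator set {GATA2, RUNX1, JUNB}
— the decoys SOX17 (enriched, never activated) and POU5F1 (activated,
enriched only in category I) are correctly excluded; the knockout
recovers the planted 34.1%/13.3% dependent/gained fractions at this
sample size; and JUNB's footprint is deep only at HPC, the stage where
its category-III peaks are open.

The same run is available from a shell:

```sh
Rscript inst/cli/epidyn.R simulate --seed 1 --outdir data/
Rscript inst/cli/epidyn.R run-all  --seed 1 --input-dir data/ --outdir out/
```

Real datasets enter through the same door: a directory of per-stage
bedGraphs, peak BEDs, a chromosome-sizes table, an annotation TSV and
count matrices, loaded with `load_dataset()` / `run_config(input_dir =
...)` (see `?run_all`).

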