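# tivscan

Detection of **signal-induced transcript isoform variation (TIV)** from
exon-array-style probe-set time courses, plus quantification of
wound-healing (scratch) assays for isoform-specific siRNA screens.

## The problem

When cells respond to a stimulus such as EGF, many genes do not simply go
up or down: they switch which transcript isoform they make — alternative
promoters, cassette exons, alternative 5'/3' splice sites, retained
introns, alternative last exons. On an exon array each short genomic
region is measured by a probe set (PS). If a gene's isoform composition is
stable, all of its exonic probe sets share one fold change; if isoform
usage shifts, the probe sets specific to the affected region deviate from
the rest. `tivscan` turns that observation into a calibrated statistical
pipeline:

1. **Region annotation** (`gene_model`, `annotate_probesets`,
   `region_classes`): probe sets are labelled as interrogating
   constitutive introns or putative exons, and each base of a gene is
   assigned to an alternative-transcript region class.
2. **Exon refinement** (`intron_background`, `refine_exons`): the pooled
   signal of constitutive-intron probe sets defines an empirical
   background; a putative exon is kept only if its replicate-mean signal
   exceeds the background's `q_int` quantile (default 0.95) at one or
   more time points.
3. **Noise model** (`fit_noise`): replicate standard deviation as a
   monotone non-increasing function of mean log2 intensity (binned
   median-of-SDs, consistency-corrected, isotonic regression).
4. **Fold changes and calls** (`fold_changes`, `gene_fc`,
   `call_de_genes`, `deviation_stats`, `call_tiv`): per probe set
   `FC_ps(t) = mean log2 signal(t) − mean log2 signal(0)`; the gene-level
   fold change is the median over its true-exonic probe sets. The TIV
   statistic is the deviation `Δ_ps(t) = FC_ps(t) − FC_gene(t)` with
   `z = Δ/sd(Δ)`, two-sided normal p-values and Benjamini–Hochberg FDR
   across all (PS, time) tests. An event needs `q < 0.05` at **two or
   more adjacent time points** with a consistent sign. Differential
   expression additionally requires a linear fold change ≥ 1.5.
5. **Event typing** (`classify_events`, `rank_events`,
   `isoform_ratio`): deviating probe sets vote with the region class they
   occupy; events map to the canonical taxonomy (alternative first/last
   exon, cassette exon, alt 5'/3' splice site, intron retention).
6. **Migration screen** (`merge_tiles`, `segment_gap`, `amd_trace`,
   `screen_statistics`, `isoform_hit_call`): scratch-assay tiles are
   mosaicked, segmented (Otsu threshold + morphological closing, top and
   bottom 15% of rows discarded), and summarized as the average migration
   distance `AMD(t) = (width(0) − width(t)) / 2`. Relative AMD per siRNA
   oligo is tested against control wells (Welch t, BH-FDR, q < 0.01); an
   isoform is a hit only if **both** of its oligos are significant in the
   same direction while neither the alternate isoforms nor the gene-level
   pool are.
7. **Synthetic data** (`simulation_spec`, `simulate_gene_models`,
   `simulate_timecourse`, `simulate_scratch`, `simulate_screen`):
   ground-truthed generators for every stage — triplicates at seven time
   points, intronic background 3 log2 below exons, intensity-dependent
   noise, injected DE/TIV, closing-gap image series, 11-replicate screen
   plates.

## Worked example

```r
library(tivscan)
spec <- simulation_spec(seed = 42, n_genes = 300)
gm   <- simulate_gene_models(spec)
tc   <- simulate_timecourse(gm, spec)
res  <- tiv_pipeline(tc$signal, gm$models, gm$ps)
ev   <- classify_events(res$events, gm$models, res$annot)
rank_events(ev)[1:5, c("gene_id", "ps_ids", "sign", "time_start",
                       "time_end", "q_min", "event_type")]
```

```
  gene_id     ps_ids sign time_start time_end    q_min     event_type
1   g0096 g0096_ps02    1        120      480 2.38e-12 alt_first_exon
2   g0113 g0113_ps08    1         60      240 2.67e-10        alt_3ss
3   g0033 g0033_ps08    1        120      480 3.22e-10        alt_5ss
4   g0050 g0050_ps02   -1        120      480 1.62e-08 alt_first_exon
5   g0132 g0132_ps04   -1         60      240 2.43e-07  cassette_exon
```

Each row is one TIV event: the probe set(s) whose fold change departed
from the gene median, the deviation sign, the supporting run of adjacent
time points (minutes), the minimal FDR q-value, and the inferred event
type. On this seed 30 of 300 genes are called differentially expressed
and 87% of the injected TIV genes are recovered.

The scratch-assay arm, on the same seed (gap closing at 3 px/h per
front):

```r
sc <- simulate_scratch(spec)
w  <- sapply(sc$grids, function(g) segment_gap(merge_tiles(g))$width)
amd_trace(w, sc$times_h)
```

```
      0h   4h   8h  12h  16h  20h
width 160  136  112   88   64   40
amd     0   12   24   36   48   60
```

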