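---
title: "Methods: detecting signal-induced transcript isoform variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting signal-induced transcript isoform variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tivscan)
```

## The model

A stimulated cell population is profiled in biological triplicate at
seven time points (0, 20, 40, 60, 120, 240, 480 minutes by default), each
sample hybridized to an exon-array-like platform in which every short
genomic region is measured by one probe set (PS). Two facts drive the
design:

* Probe sets inside **constitutive introns** — regions intronic in every
  annotated isoform — track pre-mRNA and background, not mature message.
  Their pooled signal defines an empirical background distribution.
* If a gene's isoform composition is stable over the time course, all of
  its truly exonic probe sets share one fold change; a **transcript
  isoform variation (TIV) event** is a probe set (or group) whose fold
  change departs from the gene-level fold change.

The pipeline therefore separates three questions: *is this probe set
exonic at all* (background exceedance), *did the gene move* (gene-level
fold change with an FDR and fold-change threshold), and *did its isoform
composition move* (deviation statistics with an FDR and adjacency
threshold).

### Statistics

For probe set $p$ at time $t$ with $R$ replicates,
$FC_p(t) = \bar{x}_p(t) - \bar{x}_p(0)$ in log2 units, defined only where
the detection call is "present" (detection $p < \alpha_{det}$ in **all**
replicates) at both $t$ and 0. The replicate noise is modeled as a
monotone non-increasing function $\sigma(I)$ of mean intensity: per
(PS, time) pair the replicate SD is computed, pairs are pooled into
equal-count intensity bins, the per-bin **median** of SDs (robust to the
minority of truly changing probe sets) is rescaled by
$1/\sqrt{\chi^2_{0.5,R-1}/(R-1)}$ — the median of a sample SD at small
$R$ underestimates $\sigma$ by ~17% at $R=3$, and without this correction
null z-scores have SD ≈ 1.2 — and a decreasing isotonic regression
enforces monotonicity. Then
$\mathrm{var}(FC_p(t)) = \sigma^2(I_t)/R + \sigma^2(I_0)/R$.

The gene-level fold change is the **median** over the gene's true-exonic
probe sets (cells with fewer than 3 contributing probe sets are masked);
its variance uses the asymptotic median approximation
$1.57\,\overline{\sigma^2_{FC}}/m$. The TIV statistic is
$\Delta_p(t) = FC_p(t) - FC_g(t)$ with
$\mathrm{var}(\Delta) = \mathrm{var}(FC_p) + \mathrm{var}(FC_g)$,
$z = \Delta/\mathrm{sd}(\Delta)$, two-sided normal $p$, and
Benjamini–Hochberg FDR pooled across all (PS, $t>0$) tests. The positive
correlation between a probe set and a median that contains it is
ignored, which overstates $\mathrm{var}(\Delta)$ and is therefore
conservative for FDR control (the $m \ge 3$ masking limits the worst
case).

An event is a maximal run of $\ge$ 2 **adjacent** time points with
$q < \alpha$ and a consistent deviation sign; flagged probe sets of the
same gene and sign with overlapping runs merge into one event. Because a
run needs its predecessor, the last time point alone can never seed an
event. Events supported by $\ge$ 3 adjacent points are flagged
"switch-like" (sustained rather than transient), the criterion used to
shortlist screen candidates.

## Region classes and event typing

`region_classes()` partitions every base of a gene span by the membership
pattern across isoforms. The taxonomy names are standard; the exact rules
are this package's design (the categories alone do not determine them):

* *alt_first_exon_region* — exonic in a subset of isoforms and either
  upstream of every other isoform's transcription start, or inside the
  first exon of every isoform that carries it. The first/last rules take
  precedence over the splicing rules so promoter regions are never typed
  as cassettes. *alt_last_exon_region* is the 3' mirror.
* *retained_intron* — the carrier's exon strictly spans a complete intron
  of every non-carrier.
* *cassette_exon* — exactly a complete internal exon of the carriers,
  intronic in the rest.
* *alt_5ss/alt_3ss_extension* — exonic bases extending a shared exon past
  its donor/acceptor boundary (strand decides which side is the donor).
* Remaining alternative exonic bases fall back to *constitutive_exon*;
  bases exonic in no isoform are *constitutive_intron* for the partition
  (the `constitutive_introns()` accessor is stricter: it also requires
  the base to lie inside every isoform's span).

An event is typed by majority vote of its deviating probe sets; each
probe set votes with the **alternative** class covering the largest part
of its interval (constitutive bases are uninformative for typing), ties
broken by taxonomy order at the probe-set level and reported as
`unclassified` at the event level. All of this is verified base-by-base
against brute-force reimplementations on random models.

Alternative transcription starts *within* one first exon are structurally
invisible to this representation: they surface only if the annotation
encodes distinct first exons. This is a documented limitation, not a
bug.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha_detect` | 0.05 | – | present/absent call per replicate |
| `q_int` | 0.95 | quantile | background exceedance for true exons |
| `n_bins` | 50 | bins | intensity bins for the noise fit |
| `fc_min` | 1.5 | linear FC | effect-size floor for DE calls |
| `alpha` | 0.05 | FDR | DE and TIV significance |
| `min_adjacent` | 2 | time points | TIV adjacency rule (3 = switch-like) |
| `fdr_scope` | pooled | – | BH across all gene/PS×time tests; per-time optional |
| `crop_frac` | 0.15 | fraction | image rows discarded top and bottom |
| `close_r` | 5 | px | closing disk radius in segmentation |
| `alpha_q` | 0.01 | FDR | screen hit threshold |

Raising `q_int` can only shrink the true-exon set (tested property).
Pooled FDR was chosen over per-time FDR because the per-time variant
re-ranks small test families and is noisier at seven time points; the
flag exposes both.

## What the generator emulates — and what it does not

`simulation_spec()` states the world: triplicates at
0/20/40/60/120/240/480 min; each gene built from a canonical one- or
two-isoform template with 8 exonic probe-set regions, 3 constitutive-
intron probe sets, and (for TIV genes) one region of the required class;
intron signal offset −3 log2 below the exon baseline; replicate noise
Gaussian with $\sigma(I)$ falling linearly from 0.6 at $I=3$ to 0.2 at
$I=8$ (the displayed intensity–noise shape, with no distributional claim
beyond Gaussian); injected DE of ±1 log2 with a ramp saturating at
60 min; injected TIV of ±1 log2 over 3 adjacent points placed uniformly;
detection p-values by a logistic link in the true signal
(`detect_mid = 5`, `detect_k = 4`, jitter 0.15), so that signals ≳0.7
log2 above the intron mode are reliably "present". Decoy "putative exon"
probe sets emitting intron-level signal exercise the refinement filter.

Choices a reader should know about:

* **Narrow baselines.** Exon baselines are $N(8, 0.15)$ with 0.1 per-PS
  jitter. Real arrays span several log2 units of expression; a single
  global background quantile cannot separate exon from intron across
  such a range. The generator keeps baselines narrow so that the
  background-exceedance filter is a meaningful test of the *filter*, not
  of an expression-level confounder. Green refinement tests therefore do
  not establish performance on the full dynamic range of a real array.
* **Statuses are disjoint.** A gene is null, DE, or TIV — never both DE
  and TIV — so that recall and empirical FDR attribute cleanly. The
  caller statistics themselves allow a gene to be both (tested via the
  translation-invariance property: adding a constant to all probe sets
  of a gene shifts its gene-level FC but no deviation).
* **Scratch scenes** are two textured sheets (smoothed uniform texture on
  a bright base, additive Gaussian pixel noise) flanking a vertical gap
  whose half-width decreases linearly; the texture field is reseeded
  identically at every acquisition, so a zero-speed well yields
  byte-identical images and only the fronts move. No cell migration
  dynamics, drift, or illumination gradients are simulated.
* **Screen plates** draw well AMDs $N(150 \cdot e_o, 15)$ px with 11
  replicates per oligo and one 11-well negative control; effects are
  multiplicative. The 35-gene design (29/5/1 genes with 2/3/4 isoforms,
  two oligos per isoform) yields 154 isoform-specific oligos and 35
  gene-level pools.

## Numerical choices

* SD estimates are floored at $10^{-3}$ so degenerate constant inputs
  yield huge-but-finite z rather than division by zero.
* Even-count medians average the two central values everywhere (gene FC,
  isoform ratios).
* BH is the standard step-up on the pooled p-vector; ties keep
  `p.adjust`'s behavior.
* Event ranking is fully deterministic: minimal q, then largest |Δ|,
  then gene id.
* `segment_gap` measures, per row, the longest background run
  intersecting the central column band (middle 50%), averaged over rows
  — but only after confirming a vertically coherent gap (some column
  background in ≥50% of rows). Without that gate, Otsu thresholding of a
  fully confluent textured sheet hallucinates a gap from texture holes;
  with it, a closed well reports width 0. Foreground below 5% of pixels
  raises "no cells detected".
* AMD uses the per-front convention $(w_0 - w_t)/2$, floored at 0; the
  wording "relating the gap width to the initial width" admits a ratio
  reading, exposed as `amd_mode = "fraction_closed"`.
* Images interchange as ASCII PGM (P2): the simplest standard grayscale
  text format, chosen because no binary TIFF/PNG reader is part of this
  package's dependency footprint and all fixtures stay text.

## Known limitations

* The deviation variance ignores PS–median correlation (conservative)
  and the median approximation is asymptotic; both are stand-ins for an
  exact statistic that would require the platform's full covariance.
* Isoform abundances are never deconvolved; the package detects and
  types *variation*, it does not quantify transcripts.
* The exon-refinement filter assumes a comparable background level
  across genes (see "narrow baselines" above).
* Welch's t against control wells assumes approximately continuous AMD;
  a rank-based alternative is exposed via `test = "wilcoxon"`.
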