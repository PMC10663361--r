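---
title: "Classifying primed enhancer elements across developmental transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying primed enhancer elements across developmental transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primescan)
```

## The problem

During in vitro differentiation of embryonic stem cells to blood —
through the hemangioblast (HB), hemogenic endothelium (HE) and
hematopoietic progenitor (HP) stages — many cis-regulatory elements
become nuclease-accessible and reporter-active *before* the gene they
regulate is transcribed.  Such **primed enhancers** are a molecular
anticipation of the next developmental stage: the chromatin opens one
stage early, and the linked gene switches on at the following
transition.  `primescan` implements the complete analysis that
identifies these elements from a genome-integrated enhancer-reporter
screen plus ATAC peaks, expression tables, promoter-capture Hi-C
(CHi-C) links, and motif annotation, and builds the motif-based gene
regulatory network (GRN) that connects expressed transcription-factor
(TF) families to the still-silent genes their motifs point at.

## The classification rule

A reference element $e$ paired with gene $g$ is **primed** for the
transition $S_1 \rightarrow S_2$ iff all four gates hold:

1. **Distal**: the distance from the element edge to the nearest TSS
   exceeds 1,500 bp (promoter-proximal elements are excluded).
2. **Active at both stages**: $e$ is enhancer-positive — overlapped by
   at least one retained screen fragment — at $S_1$ *and* $S_2$.
3. **Silent target**: $g$ is not expressed at $S_1$, i.e. mean CPM
   across replicates is below 9.
4. **Activated target**: differential expression $S_1 \rightarrow S_2$
   shows at least twofold up-regulation ($\log_2 \mathrm{FC} \ge 1$)
   with adjusted $P < 0.05$.

Element–gene pairing prefers CHi-C: if any interaction other-end
overlaps the element, the bait gene of the highest-scoring interaction
is taken (ties to the lexicographically smallest gene id); otherwise
the nearest gene by TSS distance.  Each positive element also carries a
High/Low activity state from the normalized ratio of high- to
low-fluorescence sorted fragments, yielding the 2×2 dynamics classes
(High>High, Low>Low, Low>High, High>Low) across a transition.

### Screen fragment filtering

Sorted screen libraries are filtered in a fixed order before any
calling: (i) drop fragments coordinate-identical to a negative-control
fragment (PCR artefacts), (ii) keep only fragments coordinate-identical
to a plasmid-library fragment, (iii) keep only fragments overlapping an
ATAC peak.  "Identical" is exact chrom/start/end equality (a `slop`
parameter exists, default 0).  Duplicate fragments within a library are
removed at read time.  An empty plasmid library is a hard error rather
than a silent wipe-out.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `distal_min_bp` | 1500 | minimum TSS distance (bp), strict inequality |
| `expr_threshold` | 9 | CPM below which a gene counts as not expressed |
| `lfc_min` | 1 | log2 fold-change gate, inclusive (twofold) |
| `padj_max` | 0.05 | adjusted-P gate, strict |
| `activity_ratio` | 1.0 | normalized high:low ratio separating High from Low |
| PWM threshold | 0.8 × max | fraction of the maximum achievable log-odds score |

Decisions where the underlying procedure is genuinely open, and how we
resolved them:

* **TSS distance** is measured from the nearest element edge (0 when a
  TSS falls inside the element), the conservative convention of common
  peak annotators; a summit convention is not offered.
* **"Not expressed"** aggregates replicates by the mean CPM; an
  `all_below` mode is available since per-replicate logic is an equally
  defensible reading.
* **Element identity across stages**: stage-specific peaks are merged
  by single-linkage at ≥1 bp overlap into reference elements before
  classification, making "occurring at both stages" well defined
  without requiring identical peak calls.
* **Twofold** is inclusive ($\log_2 \mathrm{FC} \ge 1$).
* **Activity ties** (norm high = norm low) are called Low, biasing
  against over-calling strong enhancers.
* **High/Low cutoff**: the ratio boundary is exposed as
  `activity_ratio` rather than hard-coded, since only the use of the
  ratio — not its cutoff — is fixed by the assay description.
* **Expressed TF** for network membership uses the same CPM ≥ 9 rule
  as the gene gate, harmonizing the two thresholds.
* **HE means HE1**: stage-specific priming differs little between the
  two hemogenic-endothelium sub-stages, so a single HE stage is used.

## Motif scanning and the priming GRN

Position weight matrices are scanned as log2-odds against a background
(uniform by default) on both strands; probabilities are floored at
10⁻³ before the log so empty counts cannot give $-\infty$; `N` bases
contribute 0 (i.e. score as background).  A motif's default threshold
is 0.8 of its maximum achievable score — an explicit, reproducible
stand-in for scanner-internal thresholds that are not published.
Reverse-strand hits are reported at the forward coordinate of the
window start.

The priming network for a transition has TF-family nodes and primed
target-gene nodes.  An edge family → gene requires (a) a motif of the
family hitting a primed element linked to the gene and (b) at least
one member gene of the family expressed at $S_1$.  Rebuilding the same
elements with $S_2$ expression and diffing the edge sets
(`network_delta()`) shows how activation rewires incoming links.
Exports are SIF + node-attribute TSV + GraphML, byte-stable (sorted,
6 significant digits).

## The internal DE stand-in

External DE tables (e.g. from limma-voom) are accepted and take
precedence.  When none is supplied, `simple_de()` runs a per-gene
Welch t-test on log2(CPM + 0.5) with BH adjustment — a deliberately
plain, fully documented substitute, not a re-implementation of
moderated-variance methods.  Degenerate zero-variance genes: equal
means give $P = 1$; unequal means with zero variance give $P = 0$.
The pseudo-CPM for all log transforms is 0.5.

## What the synthetic study emulates

`simulate_bundle()` generates the whole input bundle with ground
truth.  Defaults (the study conditions; `sim_config()`):

* four ordered stages (ES, HB, HE, HP), 400 candidate elements on four
  4.4-Mb chromosomes, one gene per 40-kb slot so every element has an
  unambiguous nearest gene;
* 40 planted primed element–gene pairs per transition over 32 genes
  (so some genes carry two primed elements), plus 120 active
  enhancers (gene already expressed), 20 promoter-proximal elements
  (caught by the distal filter), and reporter-negative background
  peaks;
* sorted high/low libraries drawing 20 distinct plasmid-pool
  fragments per positive element, split 4:1 for true-High and 1:4 for
  true-Low elements — reliable but not trivial state recovery at this
  depth; 5% of screen fragments are artefacts absent from the plasmid
  pool (length 97 bp, so never coordinate-identical to a real
  fragment) and 5% of plasmid fragments contaminate the negative
  library;
* negative-binomial counts (dispersion 0.02, a cell-line-scale
  biological CV of ~14%) at four replicates per stage and a 4-million
  library size, with 20 filler housekeeping genes absorbing the
  remaining library mass so every gene's realized CPM sits on its
  nominal scale: planted primed genes at CPM ≈ 2 before their
  transition and ≈ 80 after (≥ twofold by construction).  Four
  replicates are the study condition because the internal DE test is
  an unmoderated t-test whose degrees of freedom at n = 3 floor the
  attainable P-value;
* CHi-C links covering ~half the elements, a third of which designate
  a non-nearest bait gene — recoverable only through the link, which
  is why any element whose designated gene is not its nearest one is
  guaranteed a link;
* six TF-family PWMs (RUNX, GATA, ETS, SOX, SMAD, TEAD) with strong
  consensi planted into element sequences; RUNX members switch on only
  at HE and TEAD members switch off after HB, so the network rebuild
  changes across transitions;
* ±VEGF condition peak sets for HE and HP in which 30% of the
  HE→HP primed elements open only when VEGF is withdrawn, plus
  per-condition expression in which their genes respond;
* eRNA counts that rise only at and after the activation stage,
  mirroring the finding that enhancer transcription tracks gene
  activity, not priming.

Everything is drawn from one seeded RNG stream; the same seed yields a
byte-identical bundle.

### What it does *not* emulate

Real read-level noise (alignment, mapq, duplicates beyond exact
coordinate duplicates), peak-calling uncertainty, overlapping gene
models, distance-decaying CHi-C contact frequencies, single-cell
expression, and genome-scale motif false-positive structure.  Passing
the recovery tests therefore shows the *logic* of the cascade is
correct and well-calibrated under realistic count noise — it does not
certify performance on real sequencing data.  The dynamics-class split
in the generator is an independent 50/50 High/Low draw per stage
(≈25% per class); observed class fractions on real data are a result,
not a condition.  With only ~9 features and ~40 elements per class,
the primed-vs-active feature regression is much noisier (R² ≈
0.3–0.7) than with genome-scale feature sets — the generator plants no
class difference, but small-sample binomial noise dominates.

## Numerical conventions

Coordinates are 0-based half-open (BED) everywhere; readers convert,
writers emit BED.  Abutting intervals do not overlap.  Nearest-gene
and CHi-C score ties break by lexicographic gene id.  Z-scores across
stages use mean-0/sd-1 standardization of stage means of
log2(CPM + 0.5); genes or elements constant across stages contribute
all-zero profiles rather than NaN.  Percentages are plain 100 × mean.
Written numeric output is fixed at 6 significant digits so identical
runs are byte-identical.

## A small worked run

```{r run, eval = FALSE}
d <- tempfile("bundle"); o <- tempfile("out")
summary <- run_pipeline(list(seed = 7, simulate = TRUE,
                             data_dir = d, out_dir = o))
summary$transitions$`ES>HB`$n_primed_elements
summary$evaluation$primed$`ES>HB`
```

The pipeline writes per-transition primed-record TSVs, network exports
(SIF/GraphML/node attributes), a VEGF report, `summary.json` and a
`manifest.json` of input hashes and parameters.  The test suite and
the acceptance script run the same analysis at 60- and 400-element
scale respectively; these sizes keep the full suite near a minute
while leaving every gate statistically exercised.

## Known limitations

* The internal DE test is underpowered relative to
  moderated-variance methods at very low replicate counts; supply an
  external DE table for real data.
* Fragment identity is exact-coordinate by default; screens with
  slight trimming jitter need the `slop` parameter.
* Families are an input mapping (motif → family → members); no motif
  clustering is performed.
* Condition "presence" for VEGF responsiveness is a pure peak-overlap
  test; no signal-strength re-calling.
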