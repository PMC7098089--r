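---
title: "Modeling insulator loops from sequence: methods and design notes"
author: "insuloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling insulator loops from sequence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

CTCF/cohesin-mediated insulator loops shield genes from enhancers outside
the loop. Both anchors of such a loop are co-bound by CTCF and the cohesin
complex, and most loops place the two CTCF motifs in convergent
orientation, consistent with loop extrusion stopping at convergently
oriented bound CTCF. Motif presence and orientation alone, however, are
poor predictors: most CTCF-bound sites anchor no loop, roughly half of
anchors carry several motifs of mixed orientation, and tandem-motif loops
exist. `insuloop` models anchors and loops directly from DNA sequence, so
that the effect of a non-coding variant can be read off as the change in
predicted loop probability when the variant is applied to the anchor
sequence.

## The model stack

All models consume one-hot encoded sequence (5 channels: A, C, G, T, N;
anchors standardized to a fixed length, 4000 bases by default, centered on
their binding peak).

* **CNN anchor model** — a convolution of 256 filters of size 17 x 5
  (the kernel spans the full channel depth), then batch normalization,
  leaky ReLU (slope 0.2) and dropout 0.3; three parallel dilated
  convolutions (512 filters of size 5 x 1; dilation rates 1, 3 and 7)
  whose outputs are concatenated, again followed by batch normalization,
  leaky ReLU, global max pooling and dropout; then dense layers of 256 and
  128 units and a sigmoid output.
* **RNN anchor model** — two stacked bidirectional LSTM layers of 64
  units per direction with dropout 0.2 after each, applied to the central
  800 bases of the anchor (the LSTM is the expensive component; the
  central window carries the peak), a time-distributed linear map,
  flattening, and the same dense head.
* **Combined anchor model** — both trained trunks with their heads
  stripped; the pooled CNN features and the flattened RNN features are
  concatenated under a new dense head of 512 and 256 units. The trunks
  are frozen by default (`train_trunks = TRUE` fine-tunes them); freezing
  makes desk-scale training stable and cheap, and the combined head can
  only improve on either branch alone.
* **Anchor orientation model** — the anchor model's trunks with a fresh
  256/128 dense head, fine-tuned end to end to separate left anchors
  (negative class) from right anchors (positive class). Anchors that
  appear on both sides of loops are excluded from its training set.
* **Loop model** — for each side of a candidate pair, the anchor trunks
  and the orientation trunks produce feature vectors, and the two
  probability outputs are appended; the concatenation over both sides
  feeds a new 512/256 dense head with a sigmoid output interpreted as
  loop probability. The component models stay frozen.

Training minimizes binary cross-entropy with RMSprop. Epochs, batch size
and learning rate are not architectural constants; the package defaults
are RMSprop at 1e-3, batch 64, at most 50 epochs with early stopping on
validation loss (patience 5), all exposed in `model_config()`. The
parameters of the best-validation-loss epoch are kept.

The compute core (convolutions, BiLSTM, batch normalization, dropout,
RMSprop, and the full backward pass) is implemented in single-precision
C++ via Rcpp/RcppArmadillo and verified against finite-difference
gradients in the test suite.

### Numerical choices

* One convolution layer uses *same* padding at stride 1, so the final
  feature maps are at base resolution; this is what makes class
  activation maps length-exact.
* Batch-norm running statistics use momentum 0.9 and epsilon 1e-5;
  evaluation mode uses the running statistics, so saved models predict
  deterministically (bit-identical after save/load).
* Dropout is inverted dropout; all randomness (shuffling, masks,
  initialization) flows from explicit integer seeds through one RNG
  stream, so a fixed seed reproduces a training run exactly on a fixed
  thread policy.
* Ties in average precision share one threshold block, which gives the
  analytic identity AP = prevalence for a constant scorer; this identity
  is asserted in the acceptance suite at the printed prevalences 0.429
  and 0.073.
* Every percentile in the package (span caps, disruption cutoffs) uses
  the linear-interpolation convention (`quantile` type 7), pinned so
  oracle tests can reproduce it by hand.

## Dataset construction

Anchors whose overlap exceeds 0.9 of either length are merged (interval
union), iterated in coordinate order to a fixpoint; the merged peak
center is the summit of the longest contributing interval when summits
are available, otherwise the interval midpoint. Anchors are then trimmed
or expanded to the standardized length centered at the peak; windows
running off a contig are N-padded rather than shifted, so the peak stays
at the window center and positional interpretation (CAM positions, scan
coordinates) is preserved.

Negative anchor classes: type 1 = binding peaks containing a motif but
anchoring no loop (centered at summits); type 2 = motif occurrences not
covered by any peak; type 3 = fixed-length windows free of motifs,
sampled at a stride with a seeded RNG (exhaustive enumeration is
available for toy genomes). Motif occurrences come from FIMO-style
tables filtered at p < 5e-5, strictly — the boundary must be pinned
somewhere, and a cutoff reads most naturally as strict.

Negative loop classes pair anchors within a span cap, the 75th
percentile of positive loop spans: type 1 = two true anchors with
convergent motifs; type 2 = tandem; type 3 = divergent; type 4 = one
true anchor and one motif-bearing non-anchor, convergent; type 5 = one
true anchor and one non-anchor with neither motif nor peak. An anchor's
orientation for this taxonomy is the strand of its best-p-value
contained motif hit — multi-motif anchors are common and some rule must
be fixed; the best hit is reproducible.

Training and validation sets are balanced, with negatives mixed
50:30:20 (anchor types 1-3) or 50:10:10:20:10 (loop types 1-5),
subsampled with a seeded RNG; when a pool is too small the mix is
renormalized over the available pools and reported. Test sets keep all
negatives. Chromosomes 7 and 8 are held out for testing and chromosome
16 for validation, so no chromosome contributes to two partitions.
Optional augmentation adds each training record's reverse complement;
for loops the twin complements both windows and swaps left/right (the
same loop on the opposite strand), and for the orientation task a
strand flip exchanges left and right, so augmented twins there carry
flipped labels.

## Variant scoring

For each (loop, sample) pair the loop probability is computed on the
reference windows and on windows edited with the sample's variants;
`delta = p_ref - p_alt` is the probability reduction. Variants are
validated against the reference (REF mismatches rejected), overlapping
variants within a sample keep the leftmost, and edits are applied right
to left. After editing, the fixed-length window is re-extracted centered
on the image of the original window center: deletions pull in flanking
reference (symmetrically for deletions spanning the center), insertions
are trimmed about the center, and a deletion wider than the window
replaces it with distal reference. Center preservation is the package's
choice — the alternative (one-sided refill) would shift every
downstream position and make scan coordinates ambiguous. Samples with
no variant overlapping either window reuse `p_ref` bit for bit, so
their delta is exactly zero.

A reduction is called significant beyond the 90th percentile (linear
interpolation) of all positive reductions pooled over samples and
loops. A loop disrupted in at least 10% of samples is recurrent; the
minimum count uses floor by default (24 of 241 and 183 of 1834 both
round down) with a `ceiling` switch. A gene is inside a loop when its
interval is fully contained between the left anchor's start and the
right anchor's end.

The saturation deletion scan deletes one base at a time across a region
and records each delta, batching the re-scored side against cached
features of the unchanged side.

## Interpretation (CAM)

The raw class-activation score of base *i* is the class-weighted sum of
the final convolutional feature maps at position *i*. The classic CAM
construction assumes a single linear class layer over average-pooled
maps; this architecture max-pools and has a two-layer head, so the
class weights are taken as the gradient of the logit with respect to
the pooled features at the scored sample — exact for the
piecewise-linear head, and identical to the classic weights in the
single-layer case. Profiles are smoothed by LOESS (locally weighted
linear regression, span 0.4, evaluated at every base), and peaks are
called as bases that are maxima of their centered 40-base window and
strictly exceed a profile-height quantile (default 0.75); adjacent
qualifying bases collapse to the single highest. The window-maximum +
quantile rule is the package's own (the source method names only the
40-bp windows); both knobs are exposed.

## The synthetic grammar

The generator plants three learnable signals in anchor windows so that
every model's task is well-posed and its recovery measurable:

* a 19-base orientation-specific **core motif** at the window center
  (the CTCF-motif analogue), on + at left anchors and − at right
  anchors of convergent loops, same strand at both anchors of tandem
  loops (15% of loops by default);
* an 8-base **cofactor motif** 350 bases upstream, present only at true
  anchors (the cohesin-co-occupancy analogue) — anchor vs bound-decoy
  discrimination requires it;
* a 10-base **side signature** 350 bases downstream, a different string
  for left and right anchors — because tandem loops exist, left/right
  discrimination cannot rely on core-motif strand alone.

The offsets place both elements inside the RNN's central window (so the
BiLSTM's task is also well-posed) but outside the 400-base region used
by the saturation-scan analysis, which therefore contains only the core
motif.

True anchors and decoys additionally carry a secondary opposite-strand
core motif with probability 0.7, so the best-scoring motif hit reports
the anchor's true side only about half the time. This mirrors the
observations that roughly half of real anchors contain multiple motifs
and that orientation-only pairing performs near chance, and it is what
makes type-1 non-loops learnable: most candidate pairs classed
convergent by best motif are secretly wrong-side pairs that the
orientation model can reject. A quarter of neighboring loop pairs
interleave (loops crossing each other, as interconnecting insulator
loops do), which also creates a minority of genuinely convergent
left/right non-loop pairs — irreducible negatives, as in real data.

Planted motifs are degenerate (per-base mutation rate 0.05), so exact
string matching cannot solve any task and recovery is non-trivial.
Synthetic FIMO p-values are a deterministic function of each instance's
edit distance (1e-6 x 8^edits, with a tiny position-dependent
perturbation to break ties), which places 2-edit instances above the
5e-5 threshold and exercises the filter: a realistic fraction of
anchors consequently has no surviving motif hit.

Sites are placed left to right with log-uniform gaps (1.5-8 kb between
site centers), site types shuffled, and consecutive true anchors paired
into loops, so spans are sums of adjacent gaps and cross pairs of
neighboring loops fall inside the span cap. Background composition is
41% GC. None of this emulates repeat structure, chromatin context, or a
real CTCF position-weight matrix — passing the recovery benchmark shows
that the models, datasets and variant machinery work as designed, not
that real-genome performance is attained.

## The desk-scale recovery benchmark

`build_benchmark_data()` + `train_benchmark_models()` run the full
pipeline at reduced size: 16 chromosomes of 1.7 Mb, 1000 loops (2000
true anchors as positives of the anchor task), windows of 1000 bases,
model widths scaled by 1/8, and the RNN at its full-scale 800-base
central window. The CNN and orientation models train for 8 epochs at
batch 32 with RMSprop at 3e-3 (a small dataset needs larger steps and
more frequent updates than the full-scale defaults), the cheap BiLSTM
for 15; head-only fits (combined anchor, loop) run up to 40 cheap
epochs on precomputed frozen features, with dropout 0.2 on the head
input. Anchor-set augmentation is off here (the grammar is already
strand-balanced across sites and the twins would double training cost),
while the loop training set is augmented with reverse-complement
swapped-side twins, which symmetrizes the pair classifier.
Held-out evaluation uses chromosomes 7 and
8: anchor models against ChIP-only decoys (prevalence near 0.5),
orientation on left vs right, and the loop model against type-1
non-loops with its prevalence baseline. `scan_motif_recovery()` scans
400 single-base deletions around a strong test loop's left-anchor
center (a region containing only the planted core motif) and checks
that the largest deltas land in the motif; `cam_motif_recovery()`
tests CAM peak enrichment inside planted spans against uniform
placement, smoothing at a motif-commensurate LOESS span (0.08, about
four motif widths) because the published span of 0.4 would average
over 40% of the profile and erase all local structure at this window
size.

## Known limitations

* Reported full-scale performance of the original method is out of
  reach here by design: it requires real ChIA-PET/ChIP-seq training
  data and full-width models.
* The grammar's planted elements sit at fixed offsets (with small
  jitter); real anchors have no such layout, so positional regularity
  makes some sub-tasks easier than in real data.
* The loop head sees frozen component features; fine-tuning through the
  trunks might help on real data and is available via configuration.
* Strand averaging at prediction time is off by default (training uses
  both strands only when augmentation is on).
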