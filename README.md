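# insuloop

Sequence models of CTCF/cohesin insulator loops, and the impact of
non-coding variants on them.

## What this is for

Insulator loops are chromatin loops whose two anchors are co-bound by
CTCF and the cohesin complex; they shield genes from enhancers outside
the loop, and somatic non-coding variants that weaken an anchor can
rewire regulation of nearby genes. Predicting which variants matter
requires a model of the loop that reads the DNA sequence itself, because
a variant is nothing but a change in that sequence.

`insuloop` provides, for computational genomicists working on 3D genome
structure and non-coding variation:

* readers for the standard inputs — genome FASTA, loops as BEDPE,
  ChIP-seq peaks as BED/narrowPeak, FIMO motif tables, variants as VCF;
* a dataset builder that merges and standardizes loop anchors to
  fixed-length windows (4000 bases centered on the binding peak),
  constructs the three non-anchor and five non-loop negative classes,
  balances and augments training sets, and holds out whole chromosomes
  (test: chr7 + chr8; validation: chr16);
* a five-model stack trained by backpropagation in compiled code:
  a dilated-convolution anchor model (256 filters of 17 x 5, then three
  parallel dilated convolutions of 512 filters at rates 1, 3, 7), a
  two-layer bidirectional-LSTM anchor model over the central 800 bases,
  their combination under a new dense head, an anchor orientation model
  (left vs right), and a loop model over anchor pairs whose sigmoid
  output is the loop probability;
* class-activation-map interpretation: per-base attribution, LOESS
  smoothing (span 0.4), and peak calling in 40-bp windows;
* a variant engine that applies SNVs and indels to anchor windows
  (always restoring the fixed window length around the original
  center), scores loops with and without each sample's variants, calls
  recurrently disrupted loops (90th-percentile reduction cutoff, 10%
  recurrence), lists genes inside them, and runs single-base saturation
  deletion scans;
* a synthetic-grammar genome simulator that plants a learnable loop
  grammar (orientation-specific core motif, anchor-marking cofactor,
  left/right side signatures, degenerate instances, decoy sites,
  labeled variants) so the whole pipeline trains and tests at desk
  scale with no downloads.

## A worked example

Simulate a small labeled universe, train the stack, and score a variant:

```r
library(insuloop)

data <- build_benchmark_data(seed = 1)       # simulate + read + build datasets
fit  <- train_benchmark_models(data, seed = 1)
unlist(fit$metrics)
#>          anchor_ap_cnn          anchor_ap_rnn     anchor_ap_combined
#>              0.9721730              0.6733472              0.9718108
#> anchor_test_prevalence         orientation_ap          loop_ap_type1
#>              0.5373134              0.9775584              0.9019238
#>  loop_prevalence_type1
#>              0.6847826
```

The anchor models separate true anchors from CTCF-bound decoys with
average precision 0.97 against a 0.54 prevalence baseline — the decoys
carry the core motif, so the models must have learned the cofactor
signal; the orientation model separates left from right anchors from the
planted side signatures (0.98); and the loop model beats the type-1
non-loop prevalence baseline by 0.22, which requires rejecting
wrong-side anchor pairs that motif orientation alone mislabels as
convergent — close to the 0.90 ceiling set by the genuinely convergent
non-loop pairs in the held-out set.

```r
scan <- scan_motif_recovery(data, fit)       # 400 single-base deletions
scan$top10_in_motif
#> [1] 8
scan$ablation_delta
#> [1] 0.8389987
```

Eight of the ten largest loop-probability reductions fall inside the
planted 19-base core motif (± 5 bases) of the scanned anchor, and
deleting the whole motif collapses the loop probability by 0.84 — two
orders of magnitude above the 99th percentile of neutral single-base
effects (0.006). The in-silico mutagenesis recovers the causal bases.

On real data the same functions apply: `read_loops()` + `read_peaks()` +
`read_motif_hits()` feed `normalize_anchors()` /
`build_nonanchors()` / `build_nonloops()` / `assemble_and_split()`;
`train_model()` fits each stack component; `score_loops()` +
`disruption_threshold()` + `summarize_disruption()` run the cohort
variant analysis; `cam_profile()` exports attribution peaks for motif
enrichment tools. A thin command-line wrapper over these functions is
installed at `inst/cli/insuloop`.

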