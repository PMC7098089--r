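# Desk-scale recovery benchmark: simulate a grammar genome, build datasets
# through the standard-format pipeline, train the five-model stack, and
# measure how well each planted signal is recovered.

#' Build the full synthetic benchmark dataset bundle
#'
#' Simulates the grammar genome, writes loops/peaks/motifs through the
#' standard formats and re-reads them with the package readers, then runs
#' the dataset builder: anchor normalization, standardization, non-anchor
#' and non-loop construction, orientation labels, span cap, and
#' chromosome-held-out splits (test = chr7 + chr8, validation = chr16).
#'
#' @param seed master seed.
#' @param n_loops number of true loops (default 1000, i.e. 2000 true
#'   anchors as the positive class of the anchor task).
#' @param n_chrom chromosomes (default 16).
#' @param chrom_length chromosome length in bases.
#' @param window_length anchor window length (default 1000).
#' @param augment include reverse-complement twins in the anchor training
#'   set; off by default at desk scale (the planted grammar is already
#'   strand-balanced across sites, and the twins double training cost).
#' @param grammar optional [synthetic_grammar()] override.
#' @return list with the simulated `bundle`, re-read inputs, built
#'   datasets (`anchor_sets`, `orient_sets`, `loop_sets`), `anchors`,
#'   `loops`, `span_cap`, `split`.
#' @export
build_benchmark_data <- function(seed = 1L, n_loops = 1000L, n_chrom = 16L,
                                 chrom_length = 1.7e6, window_length = 1000L,
                                 augment = FALSE, grammar = NULL) {
  g <- grammar %||% synthetic_grammar(seed = seed)
  bundle <- simulate_genome_and_loops(g, n_chrom = n_chrom,
                                      chrom_length = chrom_length,
                                      n_loops = n_loops,
                                      window_length = window_length,
                                      seed = seed)
  dir <- file.path(tempdir(), paste0("insuloop_bench_", seed))
  paths <- write_fixture_bundle(bundle, dir)
  genome <- bundle$genome
  loops_raw <- read_loops(paths[["loops"]])
  peaks <- read_peaks(paths[["peaks"]])
  motif_hits <- read_motif_hits(paths[["motifs"]])

  raw_anchors <- data.table(
    chrom = c(loops_raw$chrom, loops_raw$chrom),
    start = c(loops_raw$start1, loops_raw$start2),
    end = c(loops_raw$end1, loops_raw$end2))
  anchors <- normalize_anchors(raw_anchors)
  loops <- map_loops_to_anchors(loops_raw, anchors)
  anchors_std <- standardize_anchor(anchors, window_length)
  span_cap <- compute_span_cap(loops)
  sided <- label_orientation(anchors_std, loops)

  nonanchors <- rbind(
    build_nonanchors("type1", peaks, motif_hits, anchors_std, genome,
                     window_length),
    build_nonanchors("type2", peaks, motif_hits, anchors_std, genome,
                     window_length),
    build_nonanchors("type3", peaks, motif_hits, anchors_std, genome,
                     window_length, n_type3 = 800L, seed = seed + 3L))

  split <- dataset_split()
  anchor_sets <- assemble_and_split(
    positives = anchors_std[, .(chrom, peak_center)],
    negatives_by_type = list(
      nonanchor_type1 = nonanchors[klass == "nonanchor_type1",
                                   .(chrom, peak_center)],
      nonanchor_type2 = nonanchors[klass == "nonanchor_type2",
                                   .(chrom, peak_center)],
      nonanchor_type3 = nonanchors[klass == "nonanchor_type3",
                                   .(chrom, peak_center)]),
    task = "anchor", split = split, augment = augment, seed = seed + 11L)

  # orientation task: right anchors are the positive class; the
  # reverse-complement twin of a window reads as the opposite side, so
  # augmentation would flip labels -- we train on the forward strand only
  orient <- sided[, .(chrom, peak_center, label = as.integer(side == "right"))]
  part <- ifelse(orient$chrom %in% split$test_chroms, "test",
                 ifelse(orient$chrom %in% split$val_chroms, "val", "train"))
  orient[, revcomp := FALSE]
  orient_sets <- list(train = orient[part == "train"],
                      val = orient[part == "val"],
                      test = orient[part == "test"])

  nonloops <- list(
    nonloop_type1 = build_nonloops("type1", anchors_std, nonanchors,
                                   motif_hits, span_cap, loops),
    nonloop_type2 = build_nonloops("type2", anchors_std, nonanchors,
                                   motif_hits, span_cap, loops),
    nonloop_type3 = build_nonloops("type3", anchors_std, nonanchors,
                                   motif_hits, span_cap, loops),
    nonloop_type4 = build_nonloops("type4", anchors_std, nonanchors,
                                   motif_hits, span_cap, loops),
    nonloop_type5 = build_nonloops("type5", anchors_std, nonanchors,
                                   motif_hits, span_cap, loops))
  loop_sets <- assemble_and_split(
    positives = loops[, .(chrom, center1, center2)],
    negatives_by_type = lapply(nonloops, function(d)
      d[, .(chrom, center1, center2)]),
    task = "loop", split = split, augment = TRUE, seed = seed + 13L)

  list(bundle = bundle, genome = genome, paths = paths, peaks = peaks,
       motif_hits = motif_hits, anchors = anchors_std, loops = loops,
       span_cap = span_cap, sided = sided, nonanchors = nonanchors,
       nonloops = nonloops, anchor_sets = anchor_sets,
       orient_sets = orient_sets, loop_sets = loop_sets, split = split,
       window_length = as.integer(window_length), seed = seed)
}

#' Train the five-model stack on the synthetic benchmark
#'
#' Trains the CNN and RNN anchor models, the combined anchor model (frozen
#' trunks, new head), the orientation model (fine-tuned from the anchor
#' trunks) and the loop model (head over frozen pair features), then
#' evaluates on the held-out chromosomes: average precision of each anchor
#' model against ChIP-only decoys (non-anchor type 1, prevalence about
#' 0.5), orientation AP (left vs right), and loop AP against type-1
#' non-loops together with its prevalence baseline.
#'
#' @param data from [build_benchmark_data()].
#' @param seed training seed.
#' @param scale width multiplier (default 1/8).
#' @param epochs_trunk epochs for trunk training (CNN, RNN, orientation).
#' @param epochs_head epochs for head-only training (combined, loop).
#' @param verbose print per-epoch progress.
#' @return list with `models`, `metrics`, and the evaluation tables.
#' @export
train_benchmark_models <- function(data, seed = 1L, scale = 1 / 8,
                                   epochs_trunk = 8L, epochs_head = 40L,
                                   epochs_rnn = 15L, rnn_window = 800L,
                                   head_dropout = 0.2, verbose = FALSE) {
  # The RNN keeps its full-scale 800-base central window (on 1000-base
  # anchors that is the central 80%, covering the planted cofactor and
  # side signature). Batch 32 and a 3x learning rate suit the small
  # desk-scale dataset: enough updates per epoch to converge within a
  # few passes; the cheap BiLSTM gets extra epochs.
  cfg <- model_config(anchor_length = data$window_length,
                      rnn_window = rnn_window, scale = scale, patience = 3L,
                      batch_size = 32L, lr = 3e-3)
  genome <- data$genome

  seqs_of <- function(records) anchor_sequences(records, genome,
                                                data$window_length)
  aset <- data$anchor_sets
  tr <- list(sequences = seqs_of(aset$train), labels = aset$train$label)
  vl <- list(sequences = seqs_of(aset$val), labels = aset$val$label)
  te_all <- aset$test
  te1 <- te_all[type %in% c("positive", "nonanchor_type1")]
  te1_seq <- seqs_of(te1)

  cnn <- build_model("cnn_anchor", cfg, seed = seed)
  cnn <- train_model(cnn, tr, vl, seed = seed + 1L, epochs = epochs_trunk,
                     verbose = verbose)
  rnn <- build_model("rnn_anchor", cfg, seed = seed)
  rnn <- train_model(rnn, tr, vl, seed = seed + 2L, epochs = epochs_rnn,
                     verbose = verbose)
  anchor <- build_model("anchor", cfg, components = list(cnn = cnn, rnn = rnn),
                        seed = seed)
  anchor <- train_model(anchor, tr, vl, seed = seed + 3L,
                        epochs = epochs_head, head_dropout = head_dropout,
                        verbose = verbose)

  oset <- data$orient_sets
  otr <- list(sequences = seqs_of(oset$train), labels = oset$train$label)
  ovl <- list(sequences = seqs_of(oset$val), labels = oset$val$label)
  orientation <- build_model("orientation", cfg,
                             components = list(anchor = anchor), seed = seed)
  orientation <- train_model(orientation, otr, ovl, seed = seed + 4L,
                             epochs = epochs_trunk, verbose = verbose)

  loop <- build_model("loop", cfg,
                      components = list(anchor = anchor,
                                        orientation = orientation),
                      seed = seed)
  lset <- data$loop_sets
  lf <- function(records) {
    sq <- loop_sequences(records, genome, data$window_length)
    loop_pair_features(list(anchor = anchor, orientation = orientation),
                       sq$left, sq$right)
  }
  te_loop <- lset$test[type %in% c("positive", "nonloop_type1")]
  loop <- train_model(loop,
                      list(features = lf(lset$train), labels = lset$train$label),
                      list(features = lf(lset$val), labels = lset$val$label),
                      seed = seed + 5L, epochs = epochs_head,
                      head_dropout = head_dropout, verbose = verbose)

  p_cnn <- predict(cnn, te1_seq)
  p_rnn <- predict(rnn, te1_seq)
  p_anchor <- predict(anchor, te1_seq)
  ote_seq <- seqs_of(oset$test)
  p_orient <- predict(orientation, ote_seq)
  p_loop <- predict(loop, list(features = lf(te_loop)))

  metrics <- list(
    anchor_ap_cnn = average_precision(te1$label, p_cnn),
    anchor_ap_rnn = average_precision(te1$label, p_rnn),
    anchor_ap_combined = average_precision(te1$label, p_anchor),
    anchor_test_prevalence = mean(te1$label),
    orientation_ap = average_precision(oset$test$label, p_orient),
    loop_ap_type1 = average_precision(te_loop$label, p_loop),
    loop_prevalence_type1 = mean(te_loop$label))

  list(models = list(cnn = cnn, rnn = rnn, anchor = anchor,
                     orientation = orientation, loop = loop),
       metrics = metrics, config = cfg,
       anchor_test = te1, anchor_scores = list(cnn = p_cnn, rnn = p_rnn,
                                               combined = p_anchor),
       orient_test = oset$test, orient_scores = p_orient,
       loop_test = te_loop, loop_scores = p_loop, seed = seed)
}

# pair features with per-window caching (anchors recur across many pairs)
loop_pair_features <- function(components, left, right) {
  keys <- c(left, right)
  uk <- unique(keys)
  feats <- side_features(components, uk)
  idx <- match(keys, uk)
  n <- length(left)
  unname(cbind(feats[idx[seq_len(n)], , drop = FALSE],
               feats[idx[n + seq_len(n)], , drop = FALSE]))
}

#' Saturation-scan recovery of the planted core motif
#'
#' Selects a validation-style loop the way the original experiment did —
#' a loop whose probability responds strongly to loss of its core motif:
#' among held-out convergent loops with unsaturated reference probability,
#' the one with the largest full-core-motif ablation effect. A 400-base
#' region centered on that loop's left anchor (containing only the planted
#' core motif) is then scanned with single-base deletions, and the result
#' reports how many of the ten largest effects fall inside the motif
#' plus/minus `slack` bases, together with the ablation delta and the
#' 99th percentile of the neutral (outside-motif) deletion effects.
#'
#' @param data from [build_benchmark_data()].
#' @param trained from [train_benchmark_models()].
#' @param slack tolerance around the motif span in bases (default 5).
#' @param p_range reference-probability band for candidate loops;
#'   saturated probabilities leave no gradient for single-base effects.
#' @return list with the `scan` table, `top10_in_motif`,
#'   `ablation_delta`, `neutral_q99`, and the selected loop.
#' @export
scan_motif_recovery <- function(data, trained, slack = 5L,
                                p_range = c(0.5, 0.97)) {
  bundle <- data$bundle
  loop_model <- trained$models$loop
  motif_len <- nchar(bundle$grammar$core_motif)

  # convergent held-out loops and their left-anchor core motif positions
  cand <- bundle$loops[class == "convergent" &
                         chrom %in% data$split$test_chroms]
  loops_t <- data.table(chrom = cand$chrom, center1 = cand$left_center,
                        center2 = cand$right_center)
  sites <- bundle$sites[type == "anchor"]
  setkey(sites, chrom, center)
  core_start <- sites[.(loops_t$chrom, loops_t$center1), core_start]

  sq <- loop_sequences(cbind(loops_t, revcomp = FALSE), data$genome,
                       data$window_length)
  comp <- loop_model$components
  f_left <- side_features(comp, sq$left)
  f_right <- side_features(comp, sq$right)
  p_ref <- predict(loop_model, list(features = cbind(f_left, f_right)))

  # full-core-motif ablation response of every candidate
  abl_left <- vapply(seq_len(nrow(loops_t)), function(i) {
    ref_abl <- region_sequence(data$genome, loops_t$chrom[i],
                               core_start[i] - 1L, core_start[i] + motif_len)
    abl <- data.table(chrom = loops_t$chrom[i], pos0 = core_start[i] - 1L,
                      ref = ref_abl, alt = substr(ref_abl, 1L, 1L))
    apply_variants_to_window(data$genome, loops_t$chrom[i],
                             loops_t$center1[i], data$window_length, abl)$seq
  }, character(1))
  p_abl <- predict(loop_model,
                   list(features = cbind(side_features(comp, abl_left),
                                         f_right)))
  abl_delta <- p_ref - p_abl

  eligible <- which(p_ref >= p_range[1] & p_ref <= p_range[2])
  if (length(eligible) == 0L) eligible <- seq_along(p_ref)
  best <- eligible[which.max(abl_delta[eligible])]
  loop <- loops_t[best]

  region <- list(chrom = loop$chrom, start = loop$center1 - 200L,
                 end = loop$center1 + 200L)
  scan <- saturation_deletion_scan(loop_model, loop, data$genome, region)

  motif_lo <- core_start[best] - slack
  motif_hi <- core_start[best] + motif_len + slack
  in_motif <- scan$pos0 >= motif_lo & scan$pos0 < motif_hi
  top10 <- order(scan$delta, decreasing = TRUE)[1:10]
  top10_in_motif <- sum(in_motif[top10])
  neutral_q99 <- percentile(scan$delta[!in_motif], 0.99)

  list(scan = scan, top10_in_motif = top10_in_motif,
       ablation_delta = abl_delta[best], neutral_q99 = neutral_q99,
       loop = loop, core_start = core_start[best], p_ref = p_ref[best])
}

#' CAM peak recovery of planted elements
#'
#' Computes CAM profiles for `n_anchors` held-out true anchors, calls
#' peaks, and tests whether the called peaks are enriched inside planted
#' element spans (core and secondary motifs, cofactor, side signature)
#' relative to uniform placement (one-sided binomial test).
#'
#' @param data from [build_benchmark_data()].
#' @param trained from [train_benchmark_models()].
#' @param n_anchors number of test anchors to profile.
#' @param slack tolerance around planted spans in bases.
#' @param alpha LOESS span for this analysis. The package default span of
#'   0.4 averages over 40% of the profile and cannot preserve motif-scale
#'   structure on short windows; the recovery analysis smooths over about
#'   four motif widths instead.
#' @return list with `n_peaks`, `n_in_spans`, `expected_fraction`,
#'   `p_value`, `profiles`.
#' @export
cam_motif_recovery <- function(data, trained, n_anchors = 50L, slack = 5L,
                               alpha = 0.08) {
  bundle <- data$bundle
  model <- trained$models$cnn
  g <- bundle$grammar
  half <- data$window_length %/% 2L
  sites <- bundle$sites[type == "anchor" & chrom %in% data$split$test_chroms]
  sites <- sites[seq_len(min(n_anchors, nrow(sites)))]

  motif_len <- nchar(g$core_motif)
  span_of <- function(s) {
    sp <- list(c(s$core_start, s$core_start + motif_len),
               c(s$cofactor_start, s$cofactor_start + nchar(g$cofactor_motif)),
               c(s$signature_start, s$signature_start + nchar(g$left_signature)))
    sec <- bundle$motif_table[site > 0 & role == "secondary" &
                                chrom == s$chrom &
                                start > s$center - half &
                                start < s$center + half]
    if (nrow(sec) > 0L)
      sp <- c(sp, lapply(seq_len(nrow(sec)),
                         function(i) c(sec$start[i], sec$end[i])))
    sp
  }

  n_peaks <- 0L; n_in <- 0L; total_span <- 0L
  profiles <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i]
    w <- extract_window(data$genome, s$chrom, s$center, data$window_length)
    pr <- cam_profile(model, w, alpha = alpha)
    profiles[[i]] <- pr
    spans <- span_of(s)
    w0 <- s$center - half  # genome coordinate of window position 1
    pos0 <- pr$peaks$position - 1L + w0
    inside <- rep(FALSE, length(pos0))
    span_len <- 0L
    for (sp in spans) {
      inside <- inside | (pos0 >= sp[1] - slack & pos0 < sp[2] + slack)
      span_len <- span_len + (sp[2] - sp[1]) + 2L * slack
    }
    n_peaks <- n_peaks + length(pos0)
    n_in <- n_in + sum(inside)
    total_span <- total_span + span_len
  }
  expected <- total_span / (nrow(sites) * data$window_length)
  pv <- if (n_peaks > 0L)
    stats::binom.test(n_in, n_peaks, p = expected,
                      alternative = "greater")$p.value else 1
  list(n_peaks = n_peaks, n_in_spans = n_in, expected_fraction = expected,
       observed_fraction = if (n_peaks > 0L) n_in / n_peaks else 0,
       p_value = pv, profiles = profiles)
}
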