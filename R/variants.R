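# variant_engine: apply variants to anchor windows, score reference vs
# alternate loop probabilities, saturation deletion scans, disruption calls

region_sequence <- function(genome, chrom, start, end) {
  contig <- genome[[chrom]]
  n <- nchar(contig)
  left_pad <- max(0L, -start)
  right_pad <- max(0L, end - n)
  core <- if (start < n && end > 0L)
    substr(contig, max(start, 0L) + 1L, min(end, n)) else ""
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

#' Apply variants to a fixed-length window
#'
#' Variants overlapping the window are validated against the reference
#' (mismatching REF alleles are rejected with a message; of overlapping
#' variants the leftmost is kept) and applied right to left on an extended
#' reference region. The output window is then re-extracted centered on
#' the image of the original window center, so net deletions pull in
#' flanking reference sequence, net insertions are trimmed about the
#' center, and deletions wider than the window (or spanning beyond it)
#' remove their overlapping portion and pull in distal reference — the
#' returned sequence always has exactly the window length with the
#' original center at its midpoint.
#'
#' @param genome named character vector from [read_fasta()].
#' @param chrom chromosome name.
#' @param center 0-based window center.
#' @param length window length in bases.
#' @param variants `data.table` with `chrom`, `pos0`, `ref`, `alt` (one
#'   sample's variants).
#' @return list with `seq` (character scalar of `length` bases),
#'   `n_applied` and `n_rejected`.
#' @export
apply_variants_to_window <- function(genome, chrom, center, length, variants) {
  length <- as.integer(length)
  half <- length %/% 2L
  start <- as.integer(center) - half
  end <- start + length
  v <- as.data.table(variants)
  sel <- v$chrom == chrom & v$pos0 < end & v$pos0 + nchar(v$ref) > start
  v <- v[which(sel)]
  if (nrow(v) == 0L)
    return(list(seq = extract_window(genome, chrom, center, length),
                n_applied = 0L, n_rejected = 0L))

  v <- v[order(pos0)]
  n_rejected <- 0L
  # reference check and leftmost-wins overlap resolution
  keep <- logical(nrow(v))
  last_end <- -Inf
  for (i in seq_len(nrow(v))) {
    rl <- nchar(v$ref[i])
    ref_here <- region_sequence(genome, chrom, v$pos0[i], v$pos0[i] + rl)
    if (ref_here != v$ref[i]) {
      message("apply_variants_to_window: REF mismatch at ", chrom, ":",
              v$pos0[i] + 1L, " (expected ", v$ref[i], ", genome has ",
              ref_here, "); variant rejected")
      n_rejected <- n_rejected + 1L
    } else if (v$pos0[i] < last_end) {
      message("apply_variants_to_window: overlapping variant at ", chrom, ":",
              v$pos0[i] + 1L, " rejected (leftmost kept)")
      n_rejected <- n_rejected + 1L
    } else {
      keep[i] <- TRUE
      last_end <- v$pos0[i] + rl
    }
  }
  v <- v[keep]
  if (nrow(v) == 0L)
    return(list(seq = extract_window(genome, chrom, center, length),
                n_applied = 0L, n_rejected = n_rejected))

  flank <- sum(nchar(v$ref)) + length
  rs <- start - flank
  re <- end + flank
  region <- region_sequence(genome, chrom, rs, re)

  # apply right to left so earlier coordinates stay valid
  for (i in rev(seq_len(nrow(v)))) {
    rel <- v$pos0[i] - rs
    substr_pre <- substr(region, 1L, rel)
    substr_post <- substr(region, rel + nchar(v$ref[i]) + 1L, nchar(region))
    region <- paste0(substr_pre, v$alt[i], substr_post)
  }

  # image of the original center after the edits
  cshift <- 0L
  center0 <- as.integer(center)
  for (i in seq_len(nrow(v))) {
    rl <- nchar(v$ref[i]); al <- nchar(v$alt[i])
    if (v$pos0[i] + rl <= center0) {
      cshift <- cshift + (al - rl)
    } else if (v$pos0[i] <= center0) {
      # center falls inside the replaced block: clamp into the alt allele
      cshift <- cshift + min(al - 1L, center0 - v$pos0[i]) - (center0 - v$pos0[i])
    }
  }
  cpos <- (center0 - rs) + cshift  # 0-based index into edited region
  ws <- cpos - half
  out <- substr(region, ws + 1L, ws + length)
  if (nchar(out) < length) {
    pad <- length - nchar(out)
    out <- if (ws < 0L) paste0(strrep("N", pad), out)
           else paste0(out, strrep("N", pad))
  }
  list(seq = out, n_applied = nrow(v), n_rejected = n_rejected)
}

#' Score loops with and without each sample's variants
#'
#' For every (loop, sample) pair this computes the loop probability on the
#' reference windows (`p_ref`, once per loop) and on the variant-edited
#' windows (`p_alt`), with `delta = p_ref - p_alt`. Samples with no
#' variants overlapping either anchor window reuse `p_ref` bit for bit, so
#' their delta is exactly zero.
#'
#' @param loop_model trained `insuloop_model` of kind `loop`.
#' @param loops `data.table` with `chrom`, `center1`, `center2` (one row
#'   per loop; row order defines `loop_id`).
#' @param genome named character vector.
#' @param variants `data.table` from [read_variants()] (all samples).
#' @param samples optional sample subset; default all in `variants`.
#' @return `data.table` with `loop_id`, `sample_id`, `p_ref`, `p_alt`,
#'   `delta`, `n_variants_applied`.
#' @export
score_loops <- function(loop_model, loops, genome, variants,
                        samples = NULL) {
  loops <- as.data.table(loops)
  L <- loop_model$config$anchor_length
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  n_loops <- nrow(loops)

  left_ref <- character(n_loops)
  right_ref <- character(n_loops)
  for (i in seq_len(n_loops)) {
    left_ref[i] <- extract_window(genome, loops$chrom[i], loops$center1[i], L)
    right_ref[i] <- extract_window(genome, loops$chrom[i], loops$center2[i], L)
  }
  p_ref <- predict(loop_model, list(left = left_ref, right = right_ref))

  recs <- list()
  alt_left <- character(0); alt_right <- character(0)
  alt_loop <- integer(0); alt_sample <- character(0); alt_n <- integer(0)
  for (s in samples) {
    vs <- variants[sample_id == s]
    for (i in seq_len(n_loops)) {
      a1 <- apply_variants_to_window(genome, loops$chrom[i], loops$center1[i], L, vs)
      a2 <- apply_variants_to_window(genome, loops$chrom[i], loops$center2[i], L, vs)
      n_app <- a1$n_applied + a2$n_applied
      if (n_app == 0L) {
        recs[[length(recs) + 1L]] <- data.table(
          loop_id = i, sample_id = s, p_ref = p_ref[i], p_alt = p_ref[i],
          delta = 0, n_variants_applied = 0L)
      } else {
        alt_left <- c(alt_left, a1$seq)
        alt_right <- c(alt_right, a2$seq)
        alt_loop <- c(alt_loop, i)
        alt_sample <- c(alt_sample, s)
        alt_n <- c(alt_n, n_app)
      }
    }
  }
  if (length(alt_loop) > 0L) {
    p_alt <- predict(loop_model, list(left = alt_left, right = alt_right))
    recs[[length(recs) + 1L]] <- data.table(
      loop_id = alt_loop, sample_id = alt_sample,
      p_ref = p_ref[alt_loop], p_alt = p_alt,
      delta = p_ref[alt_loop] - p_alt, n_variants_applied = alt_n)
  }
  rbindlist(recs)[order(loop_id, sample_id)][]
}

#' Single-base saturation deletion scan
#'
#' Deletes each base of `region` in turn and records the resulting drop in
#' loop probability. Positions outside both anchor windows produce an
#' empty result with a warning.
#'
#' @param loop_model trained loop model.
#' @param loop one-row `data.table` (or list) with `chrom`, `center1`,
#'   `center2`.
#' @param genome named character vector.
#' @param region list/`data.table` with `chrom`, `start`, `end` (0-based
#'   half-open) of positions to delete.
#' @return `data.table` with `pos0`, `delta` (one row per deleted base).
#' @export
saturation_deletion_scan <- function(loop_model, loop, genome, region) {
  L <- loop_model$config$anchor_length
  half <- L %/% 2L
  w1 <- c(loop$center1 - half, loop$center1 + half)
  w2 <- c(loop$center2 - half, loop$center2 + half)
  pos <- seq.int(region$start, region$end - 1L)
  in1 <- pos >= w1[1] & pos < w1[2]
  in2 <- pos >= w2[1] & pos < w2[2]
  if (region$chrom != loop$chrom || !any(in1 | in2)) {
    warning("saturation_deletion_scan: region overlaps neither anchor window")
    return(data.table(pos0 = integer(), delta = numeric()))
  }
  pos <- pos[in1 | in2]
  in1 <- pos >= w1[1] & pos < w1[2]

  left_ref <- extract_window(genome, loop$chrom, loop$center1, L)
  right_ref <- extract_window(genome, loop$chrom, loop$center2, L)
  comp <- loop_model$components
  fr_left <- side_features(comp, left_ref)
  fr_right <- side_features(comp, right_ref)
  p_ref <- predict(loop_model, list(features = cbind(fr_left, fr_right)))

  del_seq <- function(p0, center) {
    ref2 <- region_sequence(genome, loop$chrom, p0 - 1L, p0 + 1L)
    v <- data.table(chrom = loop$chrom, pos0 = p0 - 1L, ref = ref2,
                    alt = substr(ref2, 1L, 1L))
    apply_variants_to_window(genome, loop$chrom, center, L, v)$seq
  }
  edited <- character(length(pos))
  for (k in seq_along(pos))
    edited[k] <- del_seq(pos[k], if (in1[k]) loop$center1 else loop$center2)

  feats_edit <- side_features(comp, edited)
  feats <- matrix(0, nrow = length(pos), ncol = ncol(fr_left) + ncol(fr_right))
  for (k in seq_along(pos)) {
    if (in1[k]) feats[k, ] <- c(feats_edit[k, ], fr_right[1, ])
    else feats[k, ] <- c(fr_left[1, ], feats_edit[k, ])
  }
  p_alt <- predict(loop_model, list(features = feats))
  data.table(pos0 = pos, delta = p_ref - p_alt)
}


#' Disruption cutoff from pooled probability reductions
#'
#' The 90th percentile (linear interpolation) of all positive loop
#' probability reductions pooled across samples and loops; negative deltas
#' (probability gains) do not enter the pool.
#'
#' @param records `data.table` from [score_loops()].
#' @param probs percentile (default 0.90).
#' @return scalar delta cutoff.
#' @export
disruption_threshold <- function(records, probs = 0.90) {
  red <- records$delta[records$delta > 0]
  if (length(red) == 0L)
    stop("disruption_threshold: no positive probability reductions")
  percentile(red, probs)
}

#' Summarize disrupted loops across samples
#'
#' A loop is disrupted in a sample when `delta >= threshold`. Loops
#' disrupted in at least `recurrence_fraction` of samples (minimum count
#' `floor(fraction * n_samples)` by default, `ceiling` via `round_mode`)
#' are flagged recurrent. A gene lies inside a loop when its interval is
#' fully contained in `[left anchor start, right anchor end)`.
#'
#' @param records from [score_loops()].
#' @param threshold from [disruption_threshold()].
#' @param loops `data.table` with `chrom`, `center1`, `center2` (row order
#'   = `loop_id`) used for gene containment.
#' @param anchor_length window length defining loop extent.
#' @param genes optional `data.table` with `chrom`, `start`, `end`, `name`.
#' @param recurrence_fraction minimum fraction of samples (default 0.10).
#' @param round_mode `"floor"` (default) or `"ceiling"` for the minimum
#'   recurrence count.
#' @return list with `per_sample` (disrupted counts), `recurrent_loops`,
#'   `genes_in_recurrent_loops`, and `gene_sample_partition`.
#' @export
summarize_disruption <- function(records, threshold, loops, anchor_length,
                                 genes = NULL, recurrence_fraction = 0.10,
                                 round_mode = c("floor", "ceiling")) {
  round_mode <- match.arg(round_mode)
  records <- as.data.table(records)
  records[, disrupted := delta >= threshold]
  n_samples <- length(unique(records$sample_id))
  min_count <- if (round_mode == "floor")
    floor(recurrence_fraction * n_samples) else ceiling(recurrence_fraction * n_samples)
  min_count <- max(1L, as.integer(min_count))

  per_sample <- records[, .(n_disrupted = sum(disrupted)), by = sample_id]
  per_loop <- records[, .(n_samples_disrupted = sum(disrupted)), by = loop_id]
  recurrent <- per_loop[n_samples_disrupted >= min_count]

  genes_in <- NULL
  partition <- NULL
  if (!is.null(genes) && nrow(recurrent) > 0L) {
    loops <- as.data.table(loops)
    half <- as.integer(anchor_length) %/% 2L
    lt <- loops[recurrent$loop_id]
    lt[, loop_id := recurrent$loop_id]
    lt[, `:=`(lstart = center1 - half, lend = center2 + half)]
    g <- as.data.table(genes)
    hits <- list()
    for (i in seq_len(nrow(lt))) {
      inside <- g[chrom == lt$chrom[i] & start >= lt$lstart[i] & end <= lt$lend[i]]
      if (nrow(inside) > 0L)
        hits[[length(hits) + 1L]] <- data.table(gene = inside$name,
                                                loop_id = lt$loop_id[i])
    }
    if (length(hits) > 0L) {
      genes_in <- rbindlist(hits)
      partition <- lapply(split(genes_in, genes_in$gene), function(gl) {
        dis <- unique(records[loop_id %in% gl$loop_id & disrupted == TRUE,
                              sample_id])
        list(disrupted_samples = dis,
             other_samples = setdiff(unique(records$sample_id), dis))
      })
    }
  }
  list(per_sample = per_sample[], recurrent_loops = recurrent[],
       genes_in_recurrent_loops = genes_in,
       gene_sample_partition = partition,
       threshold = threshold, min_count = min_count, n_samples = n_samples)
}
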