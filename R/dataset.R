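# dataset_builder: anchors, negative classes, balancing, chromosome splits

#' Run an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so seeded dataset operations
#' do not disturb the caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# logical: does each query interval overlap any subject interval (same chrom)
interval_overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0L || nrow(query) == 0L)
    return(rep(FALSE, nrow(query)))
  q <- data.table(chrom = query$chrom, start = query$start, end = query$end,
                  qid = seq_len(nrow(query)))
  s <- data.table(chrom = subject$chrom, start = subject$start, end = subject$end)
  setkey(s, chrom, start, end)
  ov <- foverlaps(q, s, type = "any", nomatch = NULL, which = FALSE,
                  mult = "first")
  # half-open intervals: discard touching-only matches
  hit <- !is.na(ov$start) & ov$start < ov$i.end & ov$i.start < ov$end
  out <- rep(FALSE, nrow(query))
  out[ov$qid[hit]] <- TRUE
  out
}

#' Merge near-duplicate loop anchors
#'
#' Two anchors with lengths `l1` and `l2` are considered equal and merged
#' (interval union) when their overlap exceeds `0.9 x l1` or `0.9 x l2`.
#' Merging is repeated in coordinate order until a fixpoint is reached, so
#' the result does not depend on the input order. The merged anchor's peak
#' center is the summit of the longest contributing interval when summits
#' are available, otherwise the midpoint of the merged interval.
#'
#' @param raw_anchors `data.table` with `chrom`, `start`, `end` and
#'   optionally `summit`.
#' @param overlap_fraction merge threshold, default 0.9.
#' @return `data.table` of merged anchors with `chrom`, `start`, `end`,
#'   `peak_center`.
#' @export
normalize_anchors <- function(raw_anchors, overlap_fraction = 0.9) {
  dt <- as.data.table(raw_anchors)
  has_summit <- "summit" %in% names(dt)
  dt <- data.table(chrom = dt$chrom, start = as.integer(dt$start),
                   end = as.integer(dt$end),
                   summit = if (has_summit) as.integer(dt$summit) else NA_integer_,
                   src_len = as.integer(dt$end) - as.integer(dt$start))
  out_list <- list()
  for (cr in unique(dt$chrom)) {
    a <- dt[chrom == cr][order(start, end)]
    repeat {
      merged_any <- FALSE
      i <- 1L
      while (i < nrow(a)) {
        l1 <- a$end[i] - a$start[i]
        l2 <- a$end[i + 1L] - a$start[i + 1L]
        ov <- min(a$end[i], a$end[i + 1L]) - max(a$start[i], a$start[i + 1L])
        if (ov > overlap_fraction * l1 || ov > overlap_fraction * l2) {
          keep_first <- a$src_len[i] >= a$src_len[i + 1L]
          a$start[i] <- min(a$start[i], a$start[i + 1L])
          a$end[i] <- max(a$end[i], a$end[i + 1L])
          if (!keep_first) {
            a$summit[i] <- a$summit[i + 1L]
            a$src_len[i] <- a$src_len[i + 1L]
          }
          a <- a[-(i + 1L)]
          merged_any <- TRUE
        } else i <- i + 1L
      }
      if (!merged_any) break
      a <- a[order(start, end)]
    }
    out_list[[cr]] <- a
  }
  out <- rbindlist(out_list)
  out[, peak_center := ifelse(!is.na(summit), summit,
                              as.integer((start + end) %/% 2L))]
  out[, c("summit", "src_len") := NULL]
  out[]
}

#' Standardize anchors to a fixed length centered at their peaks
#'
#' Each anchor becomes `[peak_center - L/2, peak_center + L/2)`; contig-edge
#' handling is deferred to [extract_window()], which N-pads rather than
#' shifting, so the peak always sits at the window center.
#'
#' @param anchors `data.table` with `chrom` and `peak_center`.
#' @param target_length standardized length in bases (default 4000).
#' @return `data.table` with standardized `start`, `end` and unchanged
#'   `peak_center`.
#' @export
standardize_anchor <- function(anchors, target_length = 4000L) {
  dt <- as.data.table(anchors)
  half <- as.integer(target_length) %/% 2L
  dt[, start := as.integer(peak_center) - half]
  dt[, end := start + as.integer(target_length)]
  dt[]
}

#' Construct non-anchor negatives of a given class
#'
#' Type 1: binding peaks that contain a motif hit but overlap no true
#' anchor, centered at peak summits. Type 2: motif hits not covered by any
#' peak, centered at the motif. Type 3: fixed-length windows that overlap no
#' motif hit, enumerated at `stride` and (unless `exhaustive`) subsampled to
#' `n_type3` with a seeded RNG.
#'
#' @param klass `"type1"`, `"type2"` or `"type3"`.
#' @param peaks from [read_peaks()].
#' @param motif_hits from [read_motif_hits()].
#' @param true_anchors standardized true anchors.
#' @param genome named character vector (used for type 3 bounds).
#' @param target_length standardized window length.
#' @param stride type-3 enumeration stride (default `target_length`).
#' @param n_type3 number of type-3 windows to sample.
#' @param exhaustive keep all type-3 candidates (toy scales only).
#' @param seed RNG seed for type-3 sampling.
#' @return `data.table` of standardized anchors with a `klass` column.
#' @export
build_nonanchors <- function(klass, peaks, motif_hits, true_anchors, genome,
                             target_length = 4000L, stride = NULL,
                             n_type3 = 1000L, exhaustive = FALSE, seed = 1L) {
  klass <- match.arg(klass, c("type1", "type2", "type3"))
  if (klass == "type1") {
    has_motif <- interval_overlaps_any(peaks, motif_hits)
    in_anchor <- interval_overlaps_any(peaks, true_anchors)
    cand <- peaks[has_motif & !in_anchor]
    if (nrow(cand) == 0L) {
      warning("build_nonanchors: empty type1 candidate pool")
      return(empty_anchor_table("nonanchor_type1"))
    }
    out <- data.table(chrom = cand$chrom, peak_center = cand$summit)
  } else if (klass == "type2") {
    in_peak <- interval_overlaps_any(motif_hits, peaks)
    cand <- motif_hits[!in_peak]
    if (nrow(cand) == 0L) {
      warning("build_nonanchors: empty type2 candidate pool")
      return(empty_anchor_table("nonanchor_type2"))
    }
    out <- data.table(chrom = cand$chrom,
                      peak_center = as.integer((cand$start + cand$end) %/% 2L))
  } else {
    if (is.null(stride)) stride <- as.integer(target_length)
    half <- as.integer(target_length) %/% 2L
    cand_list <- lapply(names(genome), function(cr) {
      n <- nchar(genome[[cr]])
      centers <- seq.int(half, n - half, by = stride)
      if (length(centers) == 0L) return(NULL)
      data.table(chrom = cr, peak_center = as.integer(centers))
    })
    cand <- rbindlist(cand_list)
    if (nrow(cand) > 0L) {
      win <- data.table(chrom = cand$chrom, start = cand$peak_center - half,
                        end = cand$peak_center + half)
      cand <- cand[!interval_overlaps_any(win, motif_hits)]
    }
    if (nrow(cand) == 0L) {
      warning("build_nonanchors: empty type3 candidate pool")
      return(empty_anchor_table("nonanchor_type3"))
    }
    if (!exhaustive && nrow(cand) > n_type3)
      cand <- with_seed(seed, cand[sort(sample.int(nrow(cand), n_type3))])
    out <- cand[, .(chrom, peak_center)]
  }
  out <- standardize_anchor(out, target_length)
  out[, klass := paste0("nonanchor_", klass)]
  setcolorder(out, c("chrom", "start", "end", "peak_center", "klass"))
  out[]
}

empty_anchor_table <- function(klass) {
  data.table(chrom = character(), start = integer(), end = integer(),
             peak_center = integer(), klass = rep(klass, 0L))
}

#' Map loop anchor intervals onto normalized anchors
#'
#' Each side of each loop is assigned the normalized anchor with the largest
#' overlap; loops whose sides land on the same anchor are dropped.
#'
#' @param loops from [read_loops()].
#' @param anchors normalized anchors (with row order defining anchor ids).
#' @return `data.table` with `chrom`, `left_id`, `right_id`, `span`
#'   (distance between peak centers).
#' @export
map_loops_to_anchors <- function(loops, anchors) {
  a <- as.data.table(anchors)
  a[, id := .I]
  assign_side <- function(chr, s, e) {
    cand <- a[chrom == chr & start < e & end > s]
    if (nrow(cand) == 0L) return(NA_integer_)
    ov <- pmin(cand$end, e) - pmax(cand$start, s)
    cand$id[which.max(ov)]
  }
  n <- nrow(loops)
  left_id <- integer(n); right_id <- integer(n)
  for (i in seq_len(n)) {
    left_id[i] <- assign_side(loops$chrom[i], loops$start1[i], loops$end1[i])
    right_id[i] <- assign_side(loops$chrom[i], loops$start2[i], loops$end2[i])
  }
  out <- data.table(chrom = loops$chrom, left_id = left_id, right_id = right_id)
  out <- out[!is.na(left_id) & !is.na(right_id) & left_id != right_id]
  # reorder by peak center, then drop duplicate pairs
  pc <- a$peak_center
  swap <- pc[out$left_id] > pc[out$right_id]
  tmp <- out$left_id[swap]
  out$left_id[swap] <- out$right_id[swap]
  out$right_id[swap] <- tmp
  out <- unique(out, by = c("left_id", "right_id"))
  out[, center1 := pc[left_id]]
  out[, center2 := pc[right_id]]
  out[, span := center2 - center1]
  out[]
}

#' Span cap for negative loop pairs
#'
#' The 75th percentile (linear interpolation) of the distances between
#' paired anchor peak centers of the positive loops; negative pairs beyond
#' this span are not considered.
#'
#' @param positive_loops `data.table` with a `span` column.
#' @return scalar span cap in bases.
#' @export
compute_span_cap <- function(positive_loops) {
  if (nrow(positive_loops) == 0L) stop("compute_span_cap: no positive loops")
  percentile(positive_loops$span, 0.75)
}

#' Label anchors as left or right loop anchors
#'
#' Anchors appearing only on the left side of loops are labeled `left`
#' (negative class), only on the right side `right` (positive class);
#' anchors used on both sides are excluded.
#'
#' @param true_anchors normalized anchors (row order defines ids).
#' @param positive_loops from [map_loops_to_anchors()].
#' @return `data.table` of anchors with a `side` column.
#' @export
label_orientation <- function(true_anchors, positive_loops) {
  a <- as.data.table(true_anchors)
  a[, id := .I]
  lefts <- unique(positive_loops$left_id)
  rights <- unique(positive_loops$right_id)
  both <- intersect(lefts, rights)
  a[, side := "none"]
  a[id %in% setdiff(lefts, both), side := "left"]
  a[id %in% setdiff(rights, both), side := "right"]
  a[side %in% c("left", "right")][]
}

# best-p-value motif strand per anchor (NA when the anchor has no hit)
anchor_motif_strand <- function(anchors, motif_hits) {
  a <- as.data.table(anchors)
  strand <- rep(NA_character_, nrow(a))
  mh <- as.data.table(motif_hits)
  for (i in seq_len(nrow(a))) {
    hits <- mh[chrom == a$chrom[i] & start < a$end[i] & end > a$start[i]]
    if (nrow(hits) > 0L) strand[i] <- hits$strand[which.min(hits$pvalue)]
  }
  strand
}

#' Construct non-loop negatives of a given type
#'
#' Candidate pairs are ordered left/right by coordinate, restricted to the
#' span cap, and excluded if present in the positive loop set. An anchor's
#' orientation comes from its best-p-value contained motif hit; a pair is
#' convergent when the left anchor's motif is on `+` and the right anchor's
#' on `-`, divergent for the reverse, tandem for equal strands. Types:
#' 1 = two true anchors, convergent; 2 = two true anchors, tandem; 3 = two
#' true anchors, divergent; 4 = one true anchor plus one motif-containing
#' non-anchor (type-1 non-anchor), convergent; 5 = one true anchor plus one
#' non-anchor with neither motif nor peak (type-3 non-anchor).
#'
#' @param label `"type1"` .. `"type5"`.
#' @param true_anchors normalized true anchors (ids = row order).
#' @param nonanchors `data.table` of non-anchor negatives with `klass`.
#' @param motif_hits from [read_motif_hits()].
#' @param span_cap from [compute_span_cap()].
#' @param positive_loops from [map_loops_to_anchors()] (exclusion set).
#' @return `data.table` of pairs: `chrom`, `center1`, `center2`, `span`,
#'   `label`, plus anchor ids where applicable.
#' @export
build_nonloops <- function(label, true_anchors, nonanchors, motif_hits,
                           span_cap, positive_loops) {
  label <- match.arg(label, paste0("type", 1:5))
  a <- as.data.table(true_anchors)
  a[, id := .I]
  a[, mstrand := anchor_motif_strand(a, motif_hits)]
  pos_key <- paste(positive_loops$left_id, positive_loops$right_id)

  pair_true_anchors <- function(want) {
    res <- list()
    for (cr in unique(a$chrom)) {
      ac <- a[chrom == cr & !is.na(mstrand)][order(peak_center)]
      if (nrow(ac) < 2L) next
      for (i in seq_len(nrow(ac) - 1L)) {
        j <- i + 1L
        while (j <= nrow(ac) && ac$peak_center[j] - ac$peak_center[i] <= span_cap) {
          cls <- orientation_class(ac$mstrand[i], ac$mstrand[j])
          if (cls == want &&
              !(paste(ac$id[i], ac$id[j]) %in% pos_key)) {
            res[[length(res) + 1L]] <- data.table(
              chrom = cr, left_id = ac$id[i], right_id = ac$id[j],
              center1 = ac$peak_center[i], center2 = ac$peak_center[j])
          }
          j <- j + 1L
        }
      }
    }
    rbindlist_or_empty(res)
  }

  if (label %in% c("type1", "type2", "type3")) {
    want <- c(type1 = "convergent", type2 = "tandem", type3 = "divergent")[[label]]
    n_skip <- sum(is.na(a$mstrand))
    if (n_skip > 0L)
      message("build_nonloops: skipped ", n_skip, " anchor(s) without motif hits")
    out <- pair_true_anchors(want)
  } else if (label == "type4") {
    na1 <- nonanchors[klass == "nonanchor_type1"]
    if (nrow(na1) == 0L) return(empty_pair_table(label))
    na1 <- copy(na1)[, mstrand := anchor_motif_strand(na1, motif_hits)]
    n_skip <- sum(is.na(na1$mstrand))
    if (n_skip > 0L)
      message("build_nonloops: skipped ", n_skip, " non-anchor(s) without motif hits")
    out <- pair_mixed(a[!is.na(mstrand)], na1[!is.na(mstrand)], span_cap,
                      require_convergent = TRUE)
  } else {
    na3 <- nonanchors[klass == "nonanchor_type3"]
    if (nrow(na3) == 0L) return(empty_pair_table(label))
    na3 <- copy(na3)[, mstrand := NA_character_]
    out <- pair_mixed(a, na3, span_cap, require_convergent = FALSE)
  }
  if (nrow(out) == 0L) return(empty_pair_table(label))
  lab <- paste0("nonloop_", label)
  out[, span := center2 - center1]
  out[, label := lab]
  out[]
}

orientation_class <- function(strand_left, strand_right) {
  if (strand_left == "+" && strand_right == "-") "convergent"
  else if (strand_left == "-" && strand_right == "+") "divergent"
  else "tandem"
}

# pair each true anchor with non-anchors within the span cap
pair_mixed <- function(a, na, span_cap, require_convergent) {
  res <- list()
  for (cr in unique(a$chrom)) {
    ac <- a[chrom == cr]
    nc <- na[chrom == cr]
    if (nrow(ac) == 0L || nrow(nc) == 0L) next
    for (i in seq_len(nrow(ac))) {
      for (j in seq_len(nrow(nc))) {
        span <- abs(nc$peak_center[j] - ac$peak_center[i])
        if (span == 0L || span > span_cap) next
        if (ac$peak_center[i] < nc$peak_center[j]) {
          sl <- ac$mstrand[i]; sr <- nc$mstrand[j]
          c1 <- ac$peak_center[i]; c2 <- nc$peak_center[j]
        } else {
          sl <- nc$mstrand[j]; sr <- ac$mstrand[i]
          c1 <- nc$peak_center[j]; c2 <- ac$peak_center[i]
        }
        if (require_convergent &&
            orientation_class(sl, sr) != "convergent") next
        res[[length(res) + 1L]] <- data.table(chrom = cr, left_id = NA_integer_,
                                              right_id = NA_integer_,
                                              center1 = c1, center2 = c2)
      }
    }
  }
  rbindlist_or_empty(res)
}

rbindlist_or_empty <- function(res) {
  if (length(res) == 0L)
    data.table(chrom = character(), left_id = integer(), right_id = integer(),
               center1 = integer(), center2 = integer())
  else rbindlist(res)
}

empty_pair_table <- function(label) {
  data.table(chrom = character(), left_id = integer(), right_id = integer(),
             center1 = integer(), center2 = integer(), span = integer(),
             label = rep(paste0("nonloop_", label), 0L))
}

#' Chromosome-held-out dataset split definition
#'
#' @param test_chroms chromosomes held out for testing (default `chr7`,
#'   `chr8`).
#' @param val_chroms validation chromosomes (default `chr16`).
#' @return list with `test_chroms` and `val_chroms`.
#' @export
dataset_split <- function(test_chroms = c("chr7", "chr8"),
                          val_chroms = "chr16") {
  if (length(intersect(test_chroms, val_chroms)) > 0L)
    stop("test and validation chromosomes must be disjoint")
  list(test_chroms = test_chroms, val_chroms = val_chroms)
}

#' Assemble balanced, augmented, chromosome-split datasets
#'
#' Training and validation partitions have equal numbers of positives and
#' negatives, negatives composed at the configured per-type mix (anchor
#' default 50:30:20 over non-anchor types 1-3; loop default 50:10:10:20:10
#' over non-loop types 1-5) by seeded subsampling; the test partition keeps
#' all negatives. With `augment = TRUE` every training record gains a
#' reverse-complement twin (`revcomp = TRUE`); for loops the twin complements
#' both anchors and swaps left/right, and `flip_label_on_augment` (used for
#' the orientation task, where strand flips exchange left and right) flips
#' the twin's label.
#'
#' @param positives `data.table` of positive records carrying `chrom`.
#' @param negatives_by_type named list of `data.table`s, one per type, in
#'   mix order.
#' @param task `"anchor"` or `"loop"` (controls augmentation semantics
#'   downstream).
#' @param split from [dataset_split()].
#' @param augment add reverse-complement twins to the training partition.
#' @param ratios negative mix proportions (must sum to 1); defaults by task.
#' @param seed RNG seed for subsampling.
#' @param flip_label_on_augment flip labels of augmented records.
#' @return list with `train`, `val`, `test` `data.table`s (columns of the
#'   inputs plus `label` 1/0, `type`, `revcomp`) and the `split`.
#' @export
assemble_and_split <- function(positives, negatives_by_type,
                               task = c("anchor", "loop"), split,
                               augment = FALSE, ratios = NULL, seed = 1L,
                               flip_label_on_augment = FALSE) {
  task <- match.arg(task)
  if (is.null(ratios))
    ratios <- if (task == "anchor") c(0.5, 0.3, 0.2)
              else c(0.5, 0.1, 0.1, 0.2, 0.1)
  if (length(ratios) != length(negatives_by_type))
    stop("one ratio per negative type required")
  ratios <- ratios / sum(ratios)

  part_of <- function(chrom) {
    ifelse(chrom %in% split$test_chroms, "test",
           ifelse(chrom %in% split$val_chroms, "val", "train"))
  }
  pos <- copy(as.data.table(positives))[, `:=`(label = 1L, type = "positive")]
  pos[, part := part_of(chrom)]
  negs <- mapply(function(dt, nm) {
    d <- copy(as.data.table(dt))
    d[, `:=`(label = 0L, type = nm)]
    d[, part := part_of(chrom)]
    d
  }, negatives_by_type, names(negatives_by_type), SIMPLIFY = FALSE)

  build_part <- function(p, balanced, part_seed) {
    pp <- pos[part == p]
    if (balanced) {
      n_pos <- nrow(pp)
      want <- floor(ratios * n_pos)
      rem <- n_pos - sum(want)
      if (rem > 0L)
        want[order(ratios * n_pos - want, decreasing = TRUE)[seq_len(rem)]] <-
          want[order(ratios * n_pos - want, decreasing = TRUE)[seq_len(rem)]] + 1L
      avail <- vapply(negs, function(d) nrow(d[part == p]), integer(1))
      if (any(want > avail)) {
        message("assemble_and_split: renormalizing negative mix in '", p,
                "' (pool too small for requested ratios)")
        short <- pmin(want, avail)
        deficit <- n_pos - sum(short)
        # redistribute the deficit over types with spare capacity
        while (deficit > 0L) {
          spare <- avail - short
          if (all(spare == 0L)) break
          k <- which.max(spare)
          add <- min(deficit, spare[k])
          short[k] <- short[k] + add
          deficit <- deficit - add
        }
        want <- short
      }
      nn <- mapply(function(d, w, s2) {
        dp <- d[part == p]
        if (nrow(dp) <= w) dp
        else with_seed(s2, dp[sort(sample.int(nrow(dp), w))])
      }, negs, want, part_seed + seq_along(negs), SIMPLIFY = FALSE)
      out <- rbindlist(c(list(pp), nn), fill = TRUE)
    } else {
      out <- rbindlist(c(list(pp), lapply(negs, function(d) d[part == p])),
                       fill = TRUE)
    }
    out[, revcomp := FALSE]
    out[]
  }

  train <- build_part("train", TRUE, seed)
  val <- build_part("val", TRUE, seed + 1000L)
  test <- build_part("test", FALSE, seed + 2000L)

  if (augment && nrow(train) > 0L) {
    twin <- copy(train)
    twin[, revcomp := TRUE]
    if (flip_label_on_augment) twin[, label := 1L - label]
    train <- rbindlist(list(train, twin))
  }
  list(train = train[], val = val[], test = test[], split = split,
       task = task, seed = seed)
}

#' Materialize anchor window sequences for a dataset partition
#'
#' @param records `data.table` with `chrom`, `peak_center` and `revcomp`.
#' @param genome named character vector.
#' @param length window length in bases.
#' @return character vector of sequences.
#' @export
anchor_sequences <- function(records, genome, length) {
  n <- nrow(records)
  out <- character(n)
  for (i in seq_len(n)) {
    s <- extract_window(genome, records$chrom[i], records$peak_center[i], length)
    out[i] <- if (isTRUE(records$revcomp[i])) reverse_complement(s) else s
  }
  out
}

#' Materialize left/right window sequences for loop records
#'
#' For reverse-complement twins both windows are complemented and the sides
#' swapped, which is the same loop read on the opposite strand.
#'
#' @param records `data.table` with `chrom`, `center1`, `center2`, `revcomp`.
#' @param genome named character vector.
#' @param length window length in bases.
#' @return list with character vectors `left` and `right`.
#' @export
loop_sequences <- function(records, genome, length) {
  n <- nrow(records)
  left <- character(n); right <- character(n)
  for (i in seq_len(n)) {
    s1 <- extract_window(genome, records$chrom[i], records$center1[i], length)
    s2 <- extract_window(genome, records$chrom[i], records$center2[i], length)
    if (isTRUE(records$revcomp[i])) {
      left[i] <- reverse_complement(s2)
      right[i] <- reverse_complement(s1)
    } else {
      left[i] <- s1
      right[i] <- s2
    }
  }
  list(left = left, right = right)
}
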