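library(data.table)

test_that("anchor merging follows the 0.9-overlap rule to a fixpoint", {
  a <- data.table(chrom = "chr1", start = c(1000L, 1050L), end = c(2000L, 2050L))
  m <- normalize_anchors(a)                 # overlap 950 > 0.9 x 1000
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1000L, 2050L))
  expect_equal(m$peak_center, (1000L + 2050L) %/% 2L)

  d <- normalize_anchors(data.table(chrom = "chr1", start = c(0L, 5000L),
                                    end = c(1000L, 6000L)))
  expect_equal(nrow(d), 2L)
})

test_that("chained merging equals the transitive-closure oracle", {
  # brute force: merge any pair satisfying the rule until closure
  closure_merge <- function(iv) {
    iv <- iv[order(iv$start), ]
    repeat {
      done <- TRUE
      for (i in seq_len(nrow(iv))) {
        for (j in seq_len(nrow(iv))) {
          if (i >= j) next
          ov <- min(iv$end[i], iv$end[j]) - max(iv$start[i], iv$start[j])
          l1 <- iv$end[i] - iv$start[i]; l2 <- iv$end[j] - iv$start[j]
          if (ov > 0.9 * l1 || ov > 0.9 * l2) {
            iv$start[i] <- min(iv$start[i], iv$start[j])
            iv$end[i] <- max(iv$end[i], iv$end[j])
            iv <- iv[-j, ]
            done <- FALSE
            break
          }
        }
        if (!done) break
      }
      if (done) return(iv[order(iv$start), ])
    }
  }
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    start <- sort(sample(0:5000, n))
    len <- sample(200:1500, n, replace = TRUE)
    iv <- data.frame(chrom = "c", start = start, end = start + len)
    got <- normalize_anchors(as.data.table(iv))
    want <- closure_merge(iv)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("anchors standardize to exactly the target length about the peak", {
  a <- data.table(chrom = "chr1", start = 0L, end = 10000L, peak_center = 6000L)
  s <- standardize_anchor(a, 4000L)
  expect_equal(c(s$start, s$end), c(4000L, 8000L))
  # fixpoint: an already standardized anchor is unchanged
  expect_equal(standardize_anchor(s, 4000L)[, .(start, end)],
               s[, .(start, end)])
  set.seed(33)
  r <- data.table(chrom = "chr1", peak_center = sample(3000:50000, 100))
  ss <- standardize_anchor(r, 4000L)
  expect_true(all(ss$end - ss$start == 4000L))
})

test_that("non-anchor classes respect their exclusion contracts", {
  genome <- c(chr1 = strrep("A", 50000))
  peaks <- data.table(chrom = "chr1",
                      start = c(10000L, 20000L, 30000L),
                      end = c(10400L, 20400L, 30400L),
                      summit = c(10200L, 20200L, 30200L))
  motifs <- data.table(chrom = "chr1",
                       start = c(10190L, 20190L, 40000L),
                       end = c(10209L, 20209L, 40019L),
                       strand = c("+", "-", "+"), pvalue = 1e-6)
  true_anchors <- data.table(chrom = "chr1", start = 19000L, end = 23000L,
                             peak_center = 21000L)

  t1 <- build_nonanchors("type1", peaks, motifs, true_anchors, genome, 4000L)
  # peak at 20200 overlaps the true anchor -> excluded; peak at 30200 has no
  # motif -> excluded; only the 10200 peak qualifies
  expect_equal(t1$peak_center, 10200L)

  t2 <- build_nonanchors("type2", peaks, motifs, true_anchors, genome, 4000L)
  # motif covered by a peak -> excluded; only the bare motif remains
  expect_equal(t2$peak_center, (40000L + 40019L) %/% 2L)

  t3 <- build_nonanchors("type3", peaks, motifs, true_anchors, genome, 4000L,
                         stride = 1000L, exhaustive = TRUE)
  # oracle: enumerate stride windows and drop any overlapping a motif
  centers <- seq(2000L, 48000L, by = 1000L)
  keep <- vapply(centers, function(cc) {
    !any(motifs$start < cc + 2000L & motifs$end > cc - 2000L)
  }, TRUE)
  expect_equal(t3$peak_center, centers[keep])
})

test_that("span cap is the 75th percentile of positive loop spans", {
  expect_equal(compute_span_cap(data.table(span = rep(5e5, 7))), 5e5)
  expect_equal(compute_span_cap(data.table(span = 1234)), 1234)
  set.seed(35)
  spans <- sample.int(1e6, 1000)
  expect_equal(compute_span_cap(data.table(span = spans)),
               percentile_bruteforce(spans, 0.75))
  expect_error(compute_span_cap(data.table(span = numeric(0))), "no positive")
})

test_that("orientation labels exclude dual-role anchors", {
  anchors <- data.table(chrom = "chr1", start = c(0, 1, 2, 3) * 10000L,
                        end = c(0, 1, 2, 3) * 10000L + 4000L,
                        peak_center = c(0, 1, 2, 3) * 10000L + 2000L)
  loops <- data.table(chrom = "chr1", left_id = c(1L, 2L), right_id = c(2L, 3L),
                      span = c(10000L, 10000L))
  lab <- label_orientation(anchors, loops)
  # anchor 2 is left in one loop and right in another -> excluded
  expect_false(2L %in% lab$id)
  expect_identical(lab[id == 1L, side], "left")
  expect_identical(lab[id == 3L, side], "right")
  expect_equal(nrow(lab), 2L)
})

test_that("non-loop pairs obey the span cap, orientation class, and exclusions", {
  anchors <- data.table(chrom = "chr1",
                        start = c(10L, 30L, 50L, 90L) * 1000L,
                        end = c(10L, 30L, 50L, 90L) * 1000L + 4000L,
                        peak_center = c(12L, 32L, 52L, 92L) * 1000L)
  motifs <- data.table(chrom = "chr1",
                       start = anchors$peak_center - 10L,
                       end = anchors$peak_center + 9L,
                       strand = c("+", "-", "+", "-"), pvalue = 1e-6)
  pos <- data.table(chrom = "chr1", left_id = 1L, right_id = 2L, span = 20000L)
  cap <- 45000
  nl1 <- build_nonloops("type1", anchors, data.table(klass = character()),
                        motifs, cap, pos)
  # oracle: enumerate ordered pairs, class by strands, span <= cap, not pos
  strands <- c("+", "-", "+", "-")
  pc <- anchors$peak_center
  want <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    span <- pc[j] - pc[i]
    if (span > cap) next
    if (i == 1 && j == 2) next  # the positive loop
    cls <- if (strands[i] == "+" && strands[j] == "-") "convergent"
           else if (strands[i] == "-" && strands[j] == "+") "divergent"
           else "tandem"
    want[[length(want) + 1L]] <- data.frame(i = i, j = j, cls = cls)
  }
  want <- do.call(rbind, want)
  expect_equal(nrow(nl1), sum(want$cls == "convergent"))
  expect_true(all(nl1$span <= cap))
  nl2 <- build_nonloops("type2", anchors, data.table(klass = character()),
                        motifs, cap, pos)
  expect_equal(nrow(nl2), sum(want$cls == "tandem"))
  nl3 <- build_nonloops("type3", anchors, data.table(klass = character()),
                        motifs, cap, pos)
  expect_equal(nrow(nl3), sum(want$cls == "divergent"))
  # a (+,-) pair of true anchors is type-1 eligible, never type 2 or 3
  expect_true(all(paste(nl1$center1, nl1$center2) !=
                    paste(nl2$center1, nl2$center2)))
})

test_that("balanced assembly hits the negative mix and augments by strand", {
  set.seed(41)
  mk <- function(n, chrom) data.table(chrom = chrom,
                                      peak_center = sample.int(1e6, n))
  pos <- rbind(mk(100, "chr1"), mk(20, "chr7"), mk(15, "chr16"))
  negs <- list(nonanchor_type1 = rbind(mk(300, "chr1"), mk(40, "chr7")),
               nonanchor_type2 = rbind(mk(200, "chr1"), mk(30, "chr7")),
               nonanchor_type3 = rbind(mk(150, "chr1"), mk(20, "chr7")))
  ds <- assemble_and_split(pos, negs, task = "anchor", split = dataset_split(),
                           augment = FALSE, seed = 7L)
  tr <- ds$train
  expect_equal(sum(tr$label == 1), 100L)
  expect_equal(sum(tr$label == 0), 100L)
  expect_equal(unname(table(tr$type)[c("nonanchor_type1", "nonanchor_type2",
                                       "nonanchor_type3")]),
               c(50L, 30L, 20L), ignore_attr = TRUE)
  # test partition keeps all negatives
  expect_equal(sum(ds$test$label == 0), 90L)
  # no chromosome leakage
  expect_length(intersect(unique(ds$train$chrom), unique(ds$test$chrom)), 0)
  expect_length(intersect(unique(ds$train$chrom), unique(ds$val$chrom)), 0)

  dsa <- assemble_and_split(pos, negs, task = "anchor",
                            split = dataset_split(), augment = TRUE, seed = 7L)
  expect_equal(nrow(dsa$train), 2L * nrow(ds$train))
  expect_equal(sum(dsa$train$revcomp), nrow(ds$train))
  # the augmented twin of a record encodes to the reverse complement
  g <- toy_genome(c(chr1 = 1100000L))
  fwd <- dsa$train[revcomp == FALSE][1]
  twin <- dsa$train[revcomp == TRUE &
                      peak_center == fwd$peak_center & type == fwd$type][1]
  expect_identical(anchor_sequences(twin, g, 64L),
                   reverse_complement(anchor_sequences(fwd, g, 64L)))
})

test_that("loop mix follows 50:10:10:20:10 and the mix renormalizes when short", {
  set.seed(43)
  mkp <- function(n, chrom) data.table(chrom = chrom,
                                       center1 = sample.int(1e6, n),
                                       center2 = sample.int(1e6, n) + 1e6L)
  pos <- mkp(100, "chr1")
  negs <- lapply(c(200, 40, 40, 80, 40), function(n) mkp(n, "chr1"))
  names(negs) <- paste0("nonloop_type", 1:5)
  ds <- assemble_and_split(pos, negs, task = "loop", split = dataset_split(),
                           seed = 3L)
  expect_equal(unname(table(ds$train$type)[paste0("nonloop_type", 1:5)]),
               c(50L, 10L, 10L, 20L, 10L), ignore_attr = TRUE)

  negs$nonloop_type1 <- mkp(10, "chr1")  # starve type 1
  expect_message(ds2 <- assemble_and_split(pos, negs, task = "loop",
                                           split = dataset_split(), seed = 3L),
                 "renormalizing")
  expect_equal(sum(ds2$train$label == 0), 100L)
  expect_equal(sum(ds2$train$type == "nonloop_type1"), 10L)
})
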