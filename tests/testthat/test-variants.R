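library(data.table)

test_that("SNVs substitute in place and zero variants return the reference", {
  g <- toy_genome(c(chr1 = 6000L))
  ref <- extract_window(g, "chr1", 3000, 200)
  v <- data.table(chrom = "chr1", pos0 = 3010L,
                  ref = substr(g[["chr1"]], 3011, 3011), alt = "")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  out <- apply_variants_to_window(g, "chr1", 3000, 200, v)
  expect_equal(out$n_applied, 1L)
  expect_equal(nchar(out$seq), 200L)
  expect_equal(sum(strsplit(out$seq, "")[[1]] != strsplit(ref, "")[[1]]), 1L)
  # position 3010 sits at window offset 3010 - 2900 = 110 (0-based)
  expect_identical(substr(out$seq, 111, 111), v$alt)

  none <- apply_variants_to_window(g, "chr1", 3000, 200,
                                   data.table(chrom = character(),
                                              pos0 = integer(),
                                              ref = character(),
                                              alt = character()))
  expect_identical(none$seq, ref)
  expect_equal(none$n_applied, 0L)
})

test_that("a 400-base deletion keeps the 4000-base window, pulling in flanks", {
  set.seed(51)
  g <- c(chr1 = random_seq(20000))
  center <- 10000L
  # deletion centered on the window center: [9800, 10200) removed
  del_start <- 9800L
  ref_allele <- substr(g[["chr1"]], del_start, del_start + 400L)  # anchor + 400
  v <- data.table(chrom = "chr1", pos0 = del_start - 1L, ref = ref_allele,
                  alt = substr(ref_allele, 1, 1))
  out <- apply_variants_to_window(g, "chr1", center, 4000L, v)
  expect_equal(nchar(out$seq), 4000L)
  # expected: the edited chromosome around the deletion, re-centered; the
  # window pulls reference bases in from the flanks. The original center
  # (0-based 10000) lies inside the deleted block and clamps to the
  # anchor base, 0-based position 9799 of the edited chromosome.
  edited <- paste0(substr(g[["chr1"]], 1, del_start),
                   substr(g[["chr1"]], del_start + 401, 20000))
  expect_identical(out$seq, substr(edited, 9800 - 2000, 9800 + 2000 - 1))
})

test_that("deletions wider than the window still restore full length", {
  set.seed(52)
  g <- c(chr1 = random_seq(40000))
  ref_allele <- substr(g[["chr1"]], 9999, 9999 + 25000)
  v <- data.table(chrom = "chr1", pos0 = 9998L, ref = ref_allele,
                  alt = substr(ref_allele, 1, 1))
  out <- apply_variants_to_window(g, "chr1", 15000L, 4000L, v)
  expect_equal(nchar(out$seq), 4000L)
  expect_equal(out$n_applied, 1L)
  # all window content was deleted; the result is distal reference sequence
  expect_false(grepl("N", out$seq))
})

test_that("insertions re-trim about the center and edits are invertible", {
  set.seed(53)
  g <- c(chr1 = random_seq(5000))
  base <- substr(g[["chr1"]], 2501, 2501)
  ins <- data.table(chrom = "chr1", pos0 = 2500L, ref = base,
                    alt = paste0(base, "ACGTACGT"))
  out <- apply_variants_to_window(g, "chr1", 2500L, 500L, ins)
  expect_equal(nchar(out$seq), 500L)
  expect_true(grepl("ACGTACGT", out$seq))

  # applying a variant and then its exact inverse restores the window
  alt_genome <- g
  substr(alt_genome[["chr1"]], 2400, 2400) <- "A"
  fwd <- data.table(chrom = "chr1", pos0 = 2399L,
                    ref = substr(g[["chr1"]], 2400, 2400), alt = "A")
  inv <- data.table(chrom = "chr1", pos0 = 2399L, ref = "A",
                    alt = substr(g[["chr1"]], 2400, 2400))
  once <- apply_variants_to_window(g, "chr1", 2500L, 500L, fwd)$seq
  expect_identical(apply_variants_to_window(alt_genome, "chr1", 2500L, 500L,
                                            inv)$seq,
                   extract_window(g, "chr1", 2500L, 500L))
  expect_identical(once, extract_window(alt_genome, "chr1", 2500L, 500L))
})

test_that("REF mismatches and overlapping variants are rejected with messages", {
  g <- c(chr1 = strrep("ACGT", 1000))
  bad <- data.table(chrom = "chr1", pos0 = 180L, ref = "TTTT", alt = "T")
  expect_message(out <- apply_variants_to_window(g, "chr1", 200L, 100L, bad),
                 "REF mismatch")
  expect_equal(out$n_rejected, 1L)
  expect_identical(out$seq, extract_window(g, "chr1", 200L, 100L))

  ov <- data.table(chrom = "chr1", pos0 = c(200L, 202L),
                   ref = c(substr(g[["chr1"]], 201, 205),
                           substr(g[["chr1"]], 203, 203)),
                   alt = c(substr(g[["chr1"]], 201, 201), "A"))
  expect_message(out2 <- apply_variants_to_window(g, "chr1", 200L, 100L, ov),
                 "overlapping")
  expect_equal(out2$n_applied, 1L)   # leftmost kept
  expect_equal(out2$n_rejected, 1L)
})

test_that("loop scoring yields one record per pair with exact zero-variant deltas", {
  st <- tiny_stack()
  g <- toy_genome(c(chrA = 6000L, chrB = 4000L))
  loops <- data.table(chrom = c("chrA", "chrA"),
                      center1 = c(1500L, 2000L), center2 = c(4000L, 4500L))
  base <- substr(g[["chrA"]], 1501, 1501)
  variants <- data.table(
    chrom = "chrA", pos0 = 1500L, ref = base,
    alt = setdiff(c("A", "C", "G", "T"), base)[1],
    sample_id = c("s1"), vclass = "SNV")
  variants <- rbind(variants,
                    data.table(chrom = "chrB", pos0 = 100L,
                               ref = substr(g[["chrB"]], 101, 101),
                               alt = "N", sample_id = "s2", vclass = "SNV"))
  variants[2, alt := setdiff(c("A", "C", "G", "T"), ref)[1]]
  rec <- score_loops(st$loop, loops, g, variants)
  expect_equal(nrow(rec), 4L)  # 2 loops x 2 samples
  # s2's variant is on another chromosome: delta must be exactly 0
  s2 <- rec[sample_id == "s2"]
  expect_identical(s2$p_alt, s2$p_ref)
  expect_identical(s2$delta, c(0, 0))
  expect_equal(s2$n_variants_applied, c(0L, 0L))
  # s1's variant overlaps loop 1's left window only
  s1 <- rec[sample_id == "s1"]
  expect_equal(s1$n_variants_applied, c(1L, 0L))
  expect_true(all(rec$p_ref >= 0 & rec$p_ref <= 1))
  expect_true(all(rec$p_alt >= 0 & rec$p_alt <= 1))
})

test_that("saturation scan returns one delta per position and warns off-target", {
  st <- tiny_stack()
  g <- toy_genome(c(chrA = 6000L))
  loop <- list(chrom = "chrA", center1 = 1500L, center2 = 4000L)
  region <- list(chrom = "chrA", start = 1480L, end = 1520L)
  sc <- saturation_deletion_scan(st$loop, loop, g, region)
  expect_equal(nrow(sc), 40L)
  expect_equal(sc$pos0, 1480:1519)
  expect_true(all(is.finite(sc$delta)))
  expect_warning(
    empty <- saturation_deletion_scan(st$loop, loop, g,
                                      list(chrom = "chrA", start = 5500L,
                                           end = 5540L)),
    "neither anchor")
  expect_equal(nrow(empty), 0L)
})

test_that("disruption threshold pools only positive reductions", {
  rec <- data.table(delta = c(0.01 * (1:100)))
  expect_equal(disruption_threshold(rec),
               percentile_bruteforce(0.01 * (1:100), 0.9))
  expect_equal(disruption_threshold(data.table(delta = rep(0.3, 5))), 0.3)
  withneg <- data.table(delta = c(-0.5, -0.2, 0.1, 0.2))
  expect_equal(disruption_threshold(withneg),
               percentile_bruteforce(c(0.1, 0.2), 0.9))
  expect_error(disruption_threshold(data.table(delta = c(-1, 0))), "no positive")
})

test_that("disruption summary matches brute-force recurrence and containment", {
  set.seed(55)
  # toy matrix: 5 loops x 20 samples
  rec <- CJ(loop_id = 1:5, sample_id = sprintf("s%02d", 1:20))
  rec[, delta := round(runif(.N, -0.2, 0.6), 3)]
  rec[, `:=`(p_ref = 0.9, p_alt = 0.9 - delta, n_variants_applied = 1L)]
  thr <- 0.3
  loops <- data.table(chrom = "chr1", center1 = (1:5) * 50000L,
                      center2 = (1:5) * 50000L + 30000L)
  genes <- data.table(chrom = "chr1",
                      start = c(52000L, 40000L), end = c(60000L, 60000L),
                      name = c("inside1", "straddle"))
  sm <- summarize_disruption(rec, thr, loops, anchor_length = 4000L,
                             genes = genes, recurrence_fraction = 0.10)
  # brute force
  m <- matrix(rec$delta >= thr, nrow = 5, byrow = FALSE,
              dimnames = list(NULL, NULL))
  per_loop <- vapply(1:5, function(l) sum(rec[loop_id == l, delta >= thr]), 0L)
  expect_equal(sm$min_count, 2L)  # floor(0.10 * 20)
  expect_setequal(sm$recurrent_loops$loop_id, which(per_loop >= 2L))
  expect_equal(
    sm$per_sample[order(sample_id)]$n_disrupted,
    vapply(sprintf("s%02d", 1:20),
           function(s) sum(rec[sample_id == s, delta >= thr]), 0L),
    ignore_attr = TRUE)
  # gene fully inside loop 1 counted; boundary-straddling gene is not
  if (1 %in% sm$recurrent_loops$loop_id) {
    expect_true("inside1" %in% sm$genes_in_recurrent_loops$gene)
    expect_false("straddle" %in% sm$genes_in_recurrent_loops$gene)
  }
  # ceiling mode can only raise the recurrence bar
  smc <- summarize_disruption(rec, thr, loops, 4000L, genes = genes,
                              recurrence_fraction = 0.10,
                              round_mode = "ceiling")
  expect_true(smc$min_count >= sm$min_count)
  expect_true(all(smc$recurrent_loops$loop_id %in% sm$recurrent_loops$loop_id))
  # raising the percentile never increases the disrupted count
  thr2 <- 0.5
  sm2 <- summarize_disruption(rec, thr2, loops, 4000L)
  expect_true(sum(sm2$per_sample$n_disrupted) <= sum(sm$per_sample$n_disrupted))
})
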