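library(data.table)

grammar_small <- function(seed = 2L, ...) synthetic_grammar(seed = seed, ...)

bundle_small <- function(seed = 2L, n_loops = 80L, chrom_length = 1.2e6, ...) {
  simulate_genome_and_loops(grammar_small(seed), n_chrom = 4L,
                            chrom_length = chrom_length, n_loops = n_loops,
                            window_length = 1000L, seed = seed, ...)
}

test_that("a fixed seed reproduces the bundle byte for byte", {
  b1 <- bundle_small(seed = 7L)
  b2 <- bundle_small(seed = 7L)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$sites, b2$sites)
  expect_identical(b1$loops, b2$loops)
  expect_identical(b1$motif_table, b2$motif_table)
  b3 <- bundle_small(seed = 8L)
  expect_false(identical(b1$genome, b3$genome))
})

test_that("planted elements separate true anchors from decoys by construction", {
  g <- synthetic_grammar(seed = 3L, mutation_rate = 0)  # exact motifs
  b <- simulate_genome_and_loops(g, n_chrom = 2L, chrom_length = 8e5,
                                 n_loops = 40L, window_length = 1000L,
                                 seed = 3L)
  anchors <- b$sites[type == "anchor"]
  decoys <- b$sites[type == "chip_decoy"]
  a_hit <- vapply(seq_len(nrow(anchors)), function(i)
    grepl(g$cofactor_motif,
          extract_window(b$genome, anchors$chrom[i], anchors$center[i], 1000L),
          fixed = TRUE), TRUE)
  d_hit <- vapply(seq_len(nrow(decoys)), function(i)
    grepl(g$cofactor_motif,
          extract_window(b$genome, decoys$chrom[i], decoys$center[i], 1000L),
          fixed = TRUE), TRUE)
  expect_true(all(a_hit))
  expect_false(any(d_hit))
  # core motif present (on its recorded strand) at every site
  core <- vapply(seq_len(nrow(anchors)), function(i) {
    w <- extract_window(b$genome, anchors$chrom[i], anchors$center[i], 1000L)
    grepl(g$core_motif, w, fixed = TRUE) ||
      grepl(reverse_complement(g$core_motif), w, fixed = TRUE)
  }, TRUE)
  expect_true(all(core))
  # side signatures match the recorded side
  lefts <- anchors[side == "left"]
  sig <- vapply(seq_len(nrow(lefts)), function(i)
    grepl(g$left_signature,
          extract_window(b$genome, lefts$chrom[i], lefts$center[i], 1000L),
          fixed = TRUE), TRUE)
  expect_true(all(sig))
})

test_that("tandem loop fraction follows the grammar's convergent fraction", {
  b <- bundle_small(seed = 11L, n_loops = 400L, chrom_length = 2.6e6)
  frac_tandem <- mean(b$loops$class == "tandem")
  p <- 1 - b$grammar$convergent_fraction
  expect_lt(abs(frac_tandem - p), 3 * sqrt(p * (1 - p) / 400))
})

test_that("synthetic motif p-values straddle the FIMO threshold by edit distance", {
  b <- bundle_small(seed = 13L)
  expect_true(any(b$motif_table$pvalue < 5e-5))
  expect_true(any(b$motif_table$pvalue >= 5e-5))
  d <- tempfile()
  paths <- write_fixture_bundle(b, d)
  mh <- read_motif_hits(paths[["motifs"]])
  expect_equal(nrow(mh), sum(b$motif_table$pvalue < 5e-5))
})

test_that("fixture bundles round-trip through the package readers", {
  b <- bundle_small(seed = 17L)
  v <- simulate_variants(b$grammar, b, n_samples = 5L, seed = 18L)
  d <- tempfile()
  paths <- write_fixture_bundle(b, d, variants = v)
  expect_length(paths, 7L)

  genome <- read_fasta(paths[["genome"]])
  expect_identical(genome, b$genome)

  loops <- read_loops(paths[["loops"]])
  expect_equal(nrow(loops), nrow(b$loops))
  half <- b$window_length %/% 2L
  expect_equal(loops$start1, b$loops$left_center - half)
  expect_equal(loops$start2, b$loops$right_center - half)

  peaks <- read_peaks(paths[["peaks"]])
  expect_equal(peaks$summit, b$peaks$summit)

  vr <- read_variants(paths[["variants"]])
  expect_setequal(unique(vr$sample_id), unique(v$sample_id))
  # every REF allele matches the genome it was drawn from
  ok <- vapply(seq_len(nrow(vr)), function(i)
    substr(genome[[vr$chrom[i]]], vr$pos[i],
           vr$pos[i] + nchar(vr$ref[i]) - 1L) == vr$ref[i], TRUE)
  expect_true(all(ok))

  # same seed -> byte-identical files
  d2 <- tempfile()
  write_fixture_bundle(bundle_small(seed = 17L), d2,
                       variants = simulate_variants(b$grammar, b,
                                                    n_samples = 5L,
                                                    seed = 18L))
  for (f in list.files(d, full.names = FALSE))
    expect_identical(unname(tools::md5sum(file.path(d, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("simulated variants carry correct disruption labels and ratios", {
  b <- bundle_small(seed = 19L)
  v <- simulate_variants(b$grammar, b, n_samples = 8L,
                         disrupting_fraction = 0.5,
                         variants_per_sample = 10L, seed = 20L)
  expect_equal(nrow(v), 80L)
  per <- v[, .(n_dis = sum(disrupting)), by = sample_id]
  expect_true(all(abs(per$n_dis - 5L) <= 1L))
  # every disrupting variant overlaps a planted core or cofactor span
  anchors <- b$sites[type == "anchor"]
  motif_len <- nchar(b$grammar$core_motif)
  cof_len <- nchar(b$grammar$cofactor_motif)
  dis <- v[disrupting == TRUE]
  ok <- vapply(seq_len(nrow(dis)), function(i) {
    a <- anchors[chrom == dis$chrom[i]]
    any((dis$pos0[i] + nchar(dis$ref[i]) > a$core_start &
           dis$pos0[i] < a$core_start + motif_len) |
        (dis$pos0[i] + nchar(dis$ref[i]) > a$cofactor_start &
           dis$pos0[i] < a$cofactor_start + cof_len))
  }, TRUE)
  expect_true(all(ok))
  # neutral variants avoid all planted windows
  neu <- v[disrupting == FALSE]
  far <- vapply(seq_len(nrow(neu)), function(i) {
    s <- b$sites[chrom == neu$chrom[i]]
    all(abs(s$center - neu$pos0[i]) > 500L)
  }, TRUE)
  expect_true(all(far))
})
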