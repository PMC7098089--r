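test_that("read_fasta normalizes case, alphabet, and header names", {
  p <- write_tmp(c(">chr1 some description", "ACGT"), ".fa")
  expect_identical(read_fasta(p), c(chr1 = "ACGT"))

  p2 <- write_tmp(c(">chr1", "acgt"), ".fa")
  expect_identical(unname(read_fasta(p2)), "ACGT")

  p3 <- write_tmp(c(">chr1", "ACRYSWKN"), ".fa")
  expect_identical(unname(read_fasta(p3)), "ACNNNNNN")

  expect_error(read_fasta(write_tmp(character(0), ".fa")), "no records|parse")
})

test_that("multi-line FASTA records equal their single-line join", {
  set.seed(3)
  seq <- random_seq(257)
  chunks <- substring(seq, seq(1, 257, 60), pmin(seq(60, 320, 60), 257))
  p_multi <- write_tmp(c(">c", chunks), ".fa")
  p_single <- write_tmp(c(">c", paste(chunks, collapse = "")), ".fa")
  expect_identical(read_fasta(p_multi), read_fasta(p_single))
  expect_identical(unname(read_fasta(p_multi)), seq)
})

test_that("read_loops orders anchors, drops inter-chromosomal pairs", {
  p <- write_tmp(c(
    "chr1\t5000\t6000\tchr1\t1000\t2000",       # reversed pair
    "chr1\t100\t200\tchr2\t300\t400",           # inter-chromosomal
    "chr2\t10\t20\tchr2\t50\t60",
    "chr3\t7\t9\tchr3\t100\t120",
    "chr1\t1\t4\tchr1\t8\t12"), ".bedpe")
  expect_message(lp <- read_loops(p), "inter-chromosomal")
  expect_equal(nrow(lp), 4L)
  expect_true(all(lp$start1 < lp$start2))
  # manual enumeration of the retained set
  expect_setequal(paste(lp$chrom, lp$start1, lp$start2),
                  c("chr1 1000 5000", "chr2 10 50", "chr3 7 100", "chr1 1 8"))
  expect_error(read_loops(write_tmp("chr1\tx\t2\tchr1\t3\t4", ".bedpe")),
               "line 1")
})

test_that("read_peaks handles narrowPeak summits, BED midpoints, dialects", {
  np <- write_tmp("chr1\t1000\t1400\tp1\t0\t.\t5.0\t-1\t-1\t150", ".narrowPeak")
  expect_equal(read_peaks(np)$summit, 1150L)
  b3 <- write_tmp("chr1\t1000\t1400", ".bed")
  expect_equal(read_peaks(b3)$summit, 1200L)
  # negative summit offset falls back to the midpoint
  np2 <- write_tmp("chr1\t1000\t1400\tp1\t0\t.\t5.0\t-1\t-1\t-1", ".narrowPeak")
  expect_equal(read_peaks(np2)$summit, 1200L)
  mixed <- write_tmp(c("chr1\t1\t2\tx", "chr1\t1\t2"), ".bed")
  expect_error(read_peaks(mixed), "dialect")
  b7 <- write_tmp("chr1\t1\t2\ta\t0\t+\t9", ".bed")
  expect_error(read_peaks(b7), "dialect")
})

test_that("read_motif_hits applies a strictly-less p-value filter", {
  hdr <- "motif_id\tmotif_alt_id\tsequence_name\tstart\tstop\tstrand\tscore\tp-value\tq-value\tmatched_sequence"
  p <- write_tmp(c(hdr,
                   "m\t.\tchr1\t11\t29\t+\t1\t4e-5\t1\t.",
                   "m\t.\tchr1\t41\t59\t-\t1\t5e-5\t1\t."), ".tsv")
  mh <- read_motif_hits(p)
  expect_equal(nrow(mh), 1L)           # the boundary hit is excluded
  expect_equal(mh$start, 10L)          # 1-based inclusive -> 0-based
  expect_equal(mh$end, 29L)
  expect_identical(mh$strand, "+")

  # retained count equals a brute-force filter on random p-values
  set.seed(7)
  pv <- round(stats::runif(100, 1e-6, 1e-4), 8)
  rows <- sprintf("m\t.\tchr1\t%d\t%d\t+\t1\t%.8g\t1\t.",
                  seq(1, by = 50, length.out = 100),
                  seq(19, by = 50, length.out = 100), pv)
  mh2 <- read_motif_hits(write_tmp(c(hdr, rows), ".tsv"))
  expect_equal(nrow(mh2), sum(pv < 5e-5))
  expect_error(read_motif_hits(write_tmp("a\tb", ".tsv")), "parse|column")
})

test_that("read_variants splits alleles, classes, and groups by sample", {
  p <- write_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t200\t.\tACG\tA\t.\tPASS\t.\tGT\t0/0\t1/1",
    "chr1\t300\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2"), ".vcf")
  v <- read_variants(p)
  snv <- v[v$pos == 100, ]
  expect_identical(snv$vclass, "SNV")
  expect_identical(snv$sample_id, "s1")
  del <- v[v$pos == 200, ]
  expect_identical(del$vclass, "deletion")
  expect_equal(nchar(del$ref) - nchar(del$alt), 2L)
  multi <- v[v$pos == 300, ]
  expect_equal(nrow(multi), 2L)        # one record per alternate allele
  expect_setequal(multi$alt, c("G", "T"))
  expect_identical(multi[multi$alt == "T", ]$sample_id, "s2")
  expect_equal(unique(v$pos0), unique(v$pos) - 1L)
})

test_that("extract_window is total, centered, and N-padded at contig ends", {
  g <- c(chr1 = paste(rep("ACGTT", 2000), collapse = ""))  # 10 kb
  w <- extract_window(g, "chr1", 2000, 4000)
  expect_identical(w, substr(g[["chr1"]], 1, 4000))
  w2 <- extract_window(g, "chr1", 100, 4000)
  expect_equal(nchar(w2), 4000L)
  expect_equal(nchar(sub("[^N].*$", "", w2)), 1900L)  # leading N run
  expect_identical(extract_window(g, "chr1", 5, 0), "")
  expect_error(extract_window(g, "chrX", 5, 10), "chrX")
  set.seed(11)
  for (center in sample(-500:10500, 25))
    expect_equal(nchar(extract_window(g, "chr1", center, 321)), 321L)
})

test_that("one-hot encoding is the expected 5-channel matrix and round-trips", {
  m <- one_hot_encode("ACGTN")
  expect_equal(dim(m), c(5L, 5L))
  expect_equal(unname(diag(m)), rep(1L, 5))
  expect_true(all(rowSums(m) == 1L))

  long <- one_hot_encode(strrep("ACGT", 1000))
  expect_equal(dim(long), c(4000L, 5L))

  set.seed(13)
  s <- random_seq(1000, c("A", "C", "G", "T", "N"))
  enc <- one_hot_encode(s)
  expect_identical(decode_one_hot(enc), s)
  expect_equal(unname(colSums(enc)),
               unname(vapply(c("A", "C", "G", "T", "N"),
                             function(b) sum(strsplit(s, "")[[1]] == b), 0L)))
})

test_that("reverse_complement is the standard involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAC"), "GTTT")
  expect_identical(reverse_complement("AN"), "NT")
  set.seed(17)
  for (i in 1:10) {
    s <- random_seq(sample(1:200, 1), c("A", "C", "G", "T", "N"))
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_equal(nchar(reverse_complement(s)), nchar(s))
  }
})
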