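# synthetic_data: a fully labeled synthetic universe with a planted,
# learnable loop grammar (genome, anchors, loops, peaks, motif hits, variants)

#' Define a synthetic loop grammar
#'
#' The grammar plants three kinds of signal in anchor windows: an
#' orientation-specific core motif at the window center (the CTCF-motif
#' analogue), a cofactor motif upstream of the center that marks true
#' anchors only (the cohesin-co-occupancy analogue: anchor vs bound-decoy
#' discrimination requires it), and a side signature downstream that
#' distinguishes left from right anchors (needed because tandem loops make
#' core-motif orientation an unreliable side cue). True anchors and decoys
#' additionally carry a secondary core motif in opposite orientation with
#' probability `secondary_motif_prob`, so the best-scoring motif hit is only
#' weakly informative about the anchor's side — pairing anchors therefore
#' requires learned orientation, not motif orientation alone. Planted
#' motifs are degenerate: each base mutates with probability
#' `mutation_rate`, and synthetic FIMO p-values are a deterministic function
#' of the resulting edit distance, straddling the 5e-5 threshold.
#'
#' @param core_motif 19-base orientation-specific motif (must differ from
#'   its reverse complement).
#' @param cofactor_motif 8-base motif present only at true anchors.
#' @param left_signature,right_signature 10-base side signatures.
#' @param gc_background background GC fraction.
#' @param gap_min,gap_max log-uniform range (bases) for center-to-center
#'   gaps between consecutive planted sites; loop spans are sums of these
#'   gaps.
#' @param convergent_fraction probability a true loop is convergent (the
#'   remainder are tandem).
#' @param interleave_prob probability that a pair of neighboring loops
#'   interleaves (loops cross over each other, as interconnecting insulator
#'   loops do); interleaving creates non-loop anchor pairs of all
#'   orientation classes, including genuinely convergent ones.
#' @param chip_decoy_rate,motif_decoy_rate decoy counts as fractions of the
#'   true-anchor count.
#' @param secondary_motif_prob probability of a secondary opposite-strand
#'   core motif at anchors and decoys.
#' @param mutation_rate per-base mutation probability of planted motifs.
#' @param cofactor_offset,signature_offset,secondary_offset signed offsets
#'   (bases) of the planted elements from the window center.
#' @param seed generator seed.
#' @return a list of class `insuloop_grammar`.
#' @export
synthetic_grammar <- function(core_motif = "TTGCCACCAGGGGGCGCTA",
                              cofactor_motif = "GTACGCTG",
                              left_signature = "ATCGATACGG",
                              right_signature = "CCGTTAGCAC",
                              gc_background = 0.41,
                              gap_min = 1500L, gap_max = 8000L,
                              convergent_fraction = 0.85,
                              interleave_prob = 0.25,
                              chip_decoy_rate = 1.0, motif_decoy_rate = 0.6,
                              secondary_motif_prob = 0.7,
                              mutation_rate = 0.05,
                              cofactor_offset = -350L,
                              signature_offset = 350L,
                              secondary_offset = 230L,
                              seed = 1L) {
  if (core_motif == reverse_complement(core_motif))
    stop("core motif must be orientation-specific (differ from its reverse complement)")
  if (convergent_fraction < 0 || convergent_fraction > 1)
    stop("convergent_fraction must lie in [0, 1]")
  structure(as.list(environment()), class = "insuloop_grammar")
}

random_dna_chars <- function(n, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE, prob = probs)]
}

mutate_motif <- function(motif, rate) {
  ch <- strsplit(motif, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    for (i in which(hit)) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
  }
  list(seq = paste(ch, collapse = ""), edits = sum(hit))
}

# deterministic FIMO-style p-value from edit distance, with a small
# position-dependent perturbation to break ties reproducibly
synthetic_pvalue <- function(edits, pos) {
  1e-6 * 8^edits * (1 + (pos %% 97L) / 1000)
}


#' Simulate a genome with planted insulator loops
#'
#' Per chromosome, site centers are placed left to right with log-uniform
#' gaps and shuffled site types (true anchor / ChIP-only decoy / motif-only
#' decoy). True anchors are paired in order into loops, so loop spans are
#' sums of consecutive gaps; cross pairs of anchors from neighboring loops
#' fall inside the span cap and supply a rich non-loop candidate pool.
#' Convergent loops place the core motif on `+` at the left anchor and `-`
#' at the right; tandem loops use one strand for both.
#'
#' @param grammar from [synthetic_grammar()].
#' @param n_chrom number of chromosomes (named `chr1..chrN`).
#' @param chrom_length chromosome length in bases; sites that do not fit
#'   raise an error advising longer chromosomes.
#' @param n_loops total number of true loops across the genome.
#' @param window_length anchor window length the grammar is laid out for.
#' @param seed RNG seed; a fixed seed reproduces the bundle byte for byte.
#' @return a list of class `insuloop_bundle` with elements `genome`,
#'   `sites`, `loops`, `peaks`, `motif_table`, `grammar`, `window_length`.
#' @export
simulate_genome_and_loops <- function(grammar, n_chrom = 16L,
                                      chrom_length = 3e6, n_loops = 2000L,
                                      window_length = 1000L, seed = 1L) {
  g <- grammar
  loops_per_chrom <- rep(n_loops %/% n_chrom, n_chrom)
  extra <- n_loops %% n_chrom
  if (extra > 0L) loops_per_chrom[seq_len(extra)] <- loops_per_chrom[seq_len(extra)] + 1L
  half <- window_length %/% 2L
  motif_len <- nchar(g$core_motif)

  with_seed(seed, {
    genome <- character(n_chrom)
    names(genome) <- paste0("chr", seq_len(n_chrom))
    sites_list <- list()
    loops_list <- list()
    motif_list <- list()

    for (ci in seq_len(n_chrom)) {
      cr <- names(genome)[ci]
      n_anchor <- 2L * loops_per_chrom[ci]
      n_chip <- as.integer(round(g$chip_decoy_rate * n_anchor))
      n_modecoy <- as.integer(round(g$motif_decoy_rate * n_anchor))
      types <- sample(c(rep("anchor", n_anchor), rep("chip_decoy", n_chip),
                        rep("motif_decoy", n_modecoy)))
      n_sites <- length(types)
      gaps <- as.integer(round(exp(stats::runif(n_sites, log(g$gap_min),
                                                log(g$gap_max)))))
      centers <- window_length + cumsum(gaps)
      if (centers[n_sites] + window_length > chrom_length)
        stop("site placement failed on ", cr,
             ": increase chrom_length (need > ",
             centers[n_sites] + window_length, " bases)")
      seq <- random_dna_chars(chrom_length, g$gc_background)

      st <- data.table(chrom = cr, center = as.integer(centers), type = types,
                       side = NA_character_, strand = NA_character_,
                       loop_id = NA_integer_, core_start = NA_integer_,
                       cofactor_start = NA_integer_,
                       signature_start = NA_integer_)
      a_idx <- which(st$type == "anchor")
      # pair anchors in order; with probability interleave_prob two
      # neighboring loops cross over (i with i+2, i+1 with i+3)
      pair_list <- list()
      i <- 1L
      while (i + 1L <= n_anchor) {
        if (i + 3L <= n_anchor && stats::runif(1) < g$interleave_prob) {
          pair_list[[length(pair_list) + 1L]] <- c(i, i + 2L)
          pair_list[[length(pair_list) + 1L]] <- c(i + 1L, i + 3L)
          i <- i + 4L
        } else {
          pair_list[[length(pair_list) + 1L]] <- c(i, i + 1L)
          i <- i + 2L
        }
      }
      for (k in seq_along(pair_list)) {
        li <- a_idx[pair_list[[k]][1]]; ri <- a_idx[pair_list[[k]][2]]
        convergent <- stats::runif(1) < g$convergent_fraction
        if (convergent) {
          st$strand[li] <- "+"; st$strand[ri] <- "-"
        } else {
          s <- sample(c("+", "-"), 1L)
          st$strand[li] <- s; st$strand[ri] <- s
        }
        st$side[li] <- "left"; st$side[ri] <- "right"
        st$loop_id[c(li, ri)] <- k
        loops_list[[length(loops_list) + 1L]] <- data.table(
          chrom = cr, left_center = st$center[li], right_center = st$center[ri],
          class = if (convergent) "convergent" else "tandem")
      }
      st[type != "anchor", strand := sample(c("+", "-"), .N, replace = TRUE)]

      # decide all planted elements first, then write them into the
      # chromosome in one in-place pass
      plant_at <- integer(0)
      plant_seq <- character(0)
      core_start_v <- rep(NA_integer_, nrow(st))
      cof_start_v <- rep(NA_integer_, nrow(st))
      sig_start_v <- rep(NA_integer_, nrow(st))
      for (i in seq_len(nrow(st))) {
        cc <- st$center[i]
        core <- mutate_motif(g$core_motif, g$mutation_rate)
        core_seq <- if (st$strand[i] == "+") core$seq else reverse_complement(core$seq)
        core_start <- cc - motif_len %/% 2L
        plant_at <- c(plant_at, core_start)
        plant_seq <- c(plant_seq, core_seq)
        motif_list[[length(motif_list) + 1L]] <- data.table(
          chrom = cr, start = core_start, end = core_start + motif_len,
          strand = st$strand[i], pvalue = synthetic_pvalue(core$edits, core_start),
          site = i, role = "primary")
        core_start_v[i] <- core_start
        if (stats::runif(1) < g$secondary_motif_prob) {
          sec <- mutate_motif(g$core_motif, g$mutation_rate)
          sec_strand <- if (st$strand[i] == "+") "-" else "+"
          sec_seq <- if (sec_strand == "+") sec$seq else reverse_complement(sec$seq)
          sec_start <- cc + g$secondary_offset + sample(-10:10, 1L) - motif_len %/% 2L
          plant_at <- c(plant_at, sec_start)
          plant_seq <- c(plant_seq, sec_seq)
          motif_list[[length(motif_list) + 1L]] <- data.table(
            chrom = cr, start = sec_start, end = sec_start + motif_len,
            strand = sec_strand, pvalue = synthetic_pvalue(sec$edits, sec_start),
            site = i, role = "secondary")
        }
        if (st$type[i] == "anchor") {
          cof <- mutate_motif(g$cofactor_motif, g$mutation_rate)
          cof_start <- cc + g$cofactor_offset + sample(-25:25, 1L)
          plant_at <- c(plant_at, cof_start)
          plant_seq <- c(plant_seq, cof$seq)
          sig_motif <- if (st$side[i] == "left") g$left_signature else g$right_signature
          sig <- mutate_motif(sig_motif, g$mutation_rate)
          sig_start <- cc + g$signature_offset + sample(-25:25, 1L)
          plant_at <- c(plant_at, sig_start)
          plant_seq <- c(plant_seq, sig$seq)
          cof_start_v[i] <- cof_start
          sig_start_v[i] <- sig_start
        }
      }
      for (k in seq_along(plant_at)) {
        ins <- strsplit(plant_seq[k], "")[[1]]
        seq[(plant_at[k] + 1L):(plant_at[k] + length(ins))] <- ins
      }
      st[, core_start := core_start_v]
      st[, cofactor_start := cof_start_v]
      st[, signature_start := sig_start_v]
      genome[[cr]] <- paste(seq, collapse = "")
      sites_list[[ci]] <- st
    }

    sites <- rbindlist(sites_list, fill = TRUE)
    loops <- rbindlist(loops_list)
    motif_table <- rbindlist(motif_list)

    # ChIP peaks at true anchors and chip decoys, with summit at the center
    pk <- sites[type %in% c("anchor", "chip_decoy")]
    widths <- sample(250:400, nrow(pk), replace = TRUE)
    peaks <- data.table(chrom = pk$chrom,
                        start = pk$center - widths,
                        end = pk$center + widths,
                        summit = pk$center)

    structure(list(genome = genome, sites = sites, loops = loops,
                   peaks = peaks, motif_table = motif_table, grammar = g,
                   window_length = as.integer(window_length), seed = seed),
              class = "insuloop_bundle")
  })
}

#' Simulate per-sample variants with known disruption labels
#'
#' Each sample receives `n_disrupting` motif-ablating variants (SNVs or
#' short deletions inside planted core or cofactor motifs of true anchors)
#' and matched neutral variants at background positions away from any
#' planted site; `n_disrupting = round(disrupting_fraction * variants_per_sample)`.
#' Reference alleles are taken from the synthetic genome.
#'
#' @param grammar from [synthetic_grammar()].
#' @param bundle from [simulate_genome_and_loops()].
#' @param n_samples number of samples.
#' @param disrupting_fraction fraction of each sample's variants that
#'   ablate planted motifs.
#' @param variants_per_sample variants per sample.
#' @param seed RNG seed.
#' @return `data.table` with `chrom`, `pos` (1-based), `pos0`, `ref`,
#'   `alt`, `sample_id`, `vclass`, `disrupting`.
#' @export
simulate_variants <- function(grammar, bundle, n_samples = 20L,
                              disrupting_fraction = 0.5,
                              variants_per_sample = 10L, seed = 1L) {
  g <- grammar
  motif_len <- nchar(g$core_motif)
  anchors <- bundle$sites[type == "anchor"]
  half <- bundle$window_length %/% 2L
  with_seed(seed, {
    recs <- list()
    for (s in seq_len(n_samples)) {
      sid <- sprintf("sample_%02d", s)
      n_dis <- round(disrupting_fraction * variants_per_sample)
      n_neu <- variants_per_sample - n_dis
      rows <- anchors[sample.int(nrow(anchors), n_dis, replace = TRUE)]
      for (i in seq_len(n_dis)) {
        a <- rows[i]
        in_core <- stats::runif(1) < 0.5
        span_start <- if (in_core) a$core_start else a$cofactor_start
        span_len <- if (in_core) motif_len else nchar(g$cofactor_motif)
        p0 <- span_start + sample.int(span_len, 1L) - 1L
        base <- substr(bundle$genome[[a$chrom]], p0 + 1L, p0 + 1L)
        if (stats::runif(1) < 0.5) {
          alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
          recs[[length(recs) + 1L]] <- data.table(
            chrom = a$chrom, pos0 = p0, ref = base, alt = alt,
            sample_id = sid, vclass = "SNV", disrupting = TRUE)
        } else {
          dlen <- sample.int(3L, 1L)
          ref <- substr(bundle$genome[[a$chrom]], p0, p0 + dlen)
          recs[[length(recs) + 1L]] <- data.table(
            chrom = a$chrom, pos0 = p0 - 1L, ref = ref,
            alt = substr(ref, 1L, 1L),
            sample_id = sid, vclass = "deletion", disrupting = TRUE)
        }
      }
      for (i in seq_len(n_neu)) {
        repeat {
          cr <- sample(names(bundle$genome), 1L)
          p0 <- sample.int(nchar(bundle$genome[[cr]]) - 2L, 1L)
          near <- bundle$sites[chrom == cr &
                                 abs(center - p0) <= half + motif_len]
          if (nrow(near) == 0L) break
        }
        base <- substr(bundle$genome[[cr]], p0 + 1L, p0 + 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
        recs[[length(recs) + 1L]] <- data.table(
          chrom = cr, pos0 = p0, ref = base, alt = alt,
          sample_id = sid, vclass = "SNV", disrupting = FALSE)
      }
    }
    out <- rbindlist(recs)
    out[, pos := pos0 + 1L]
    setcolorder(out, c("chrom", "pos", "pos0", "ref", "alt", "sample_id",
                       "vclass", "disrupting"))
    out[order(chrom, pos0, sample_id)][]
  })
}

#' Write a fixture bundle as standard-format files
#'
#' Emits `genome.fa` (FASTA), `loops.bedpe` (BEDPE), `anchors.bed` (BED6,
#' name = side), `peaks.narrowPeak` (narrowPeak with summit offsets),
#' `motifs.tsv` (FIMO-style TSV including above-threshold hits),
#' `variants.vcf` (VCF 4.2 with per-sample genotype columns) and
#' `truth_sites.tsv` (site-level labels). Every file re-reads with the
#' package's own readers.
#'
#' @param bundle from [simulate_genome_and_loops()].
#' @param out_dir output directory.
#' @param variants optional table from [simulate_variants()].
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, out_dir, variants = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  half <- bundle$window_length %/% 2L
  paths <- c(genome = file.path(out_dir, "genome.fa"),
             loops = file.path(out_dir, "loops.bedpe"),
             anchors = file.path(out_dir, "anchors.bed"),
             peaks = file.path(out_dir, "peaks.narrowPeak"),
             motifs = file.path(out_dir, "motifs.tsv"),
             truth = file.path(out_dir, "truth_sites.tsv"))

  dna <- Biostrings::DNAStringSet(bundle$genome)
  Biostrings::writeXStringSet(dna, paths[["genome"]], width = 80L)

  loops <- bundle$loops
  fwrite(data.table(loops$chrom, loops$left_center - half,
                    loops$left_center + half, loops$chrom,
                    loops$right_center - half, loops$right_center + half),
         paths[["loops"]], sep = "\t", col.names = FALSE)

  anchors <- bundle$sites[type == "anchor"]
  fwrite(data.table(anchors$chrom, anchors$center - half,
                    anchors$center + half, anchors$side, 0L, anchors$strand),
         paths[["anchors"]], sep = "\t", col.names = FALSE)

  pk <- bundle$peaks
  fwrite(data.table(pk$chrom, pk$start, pk$end, ".", 0L, ".",
                    0, -1, -1, pk$summit - pk$start),
         paths[["peaks"]], sep = "\t", col.names = FALSE)

  mt <- bundle$motif_table
  fwrite(data.table(motif_id = "core_motif", motif_alt_id = mt$role,
                    sequence_name = mt$chrom, start = mt$start + 1L,
                    stop = mt$end, strand = mt$strand, score = 0,
                    `p-value` = mt$pvalue, `q-value` = mt$pvalue,
                    matched_sequence = "."),
         paths[["motifs"]], sep = "\t", col.names = TRUE)

  fwrite(bundle$sites, paths[["truth"]], sep = "\t", col.names = TRUE)

  if (!is.null(variants)) {
    paths[["variants"]] <- file.path(out_dir, "variants.vcf")
    write_vcf(variants, paths[["variants"]])
  }
  invisible(paths)
}

# minimal VCF 4.2 writer with one genotype column per sample
write_vcf <- function(variants, path) {
  v <- as.data.table(variants)
  samples <- sort(unique(v$sample_id))
  key <- paste(v$chrom, v$pos, v$ref, v$alt)
  uk <- unique(key)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (k in uk) {
    rows <- v[key == k]
    gt <- ifelse(samples %in% rows$sample_id, "0/1", "0/0")
    lines <- c(lines, paste(c(rows$chrom[1], rows$pos[1], ".", rows$ref[1],
                              rows$alt[1], ".", "PASS", ".", "GT", gt),
                            collapse = "\t"))
  }
  writeLines(lines, path)
}
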