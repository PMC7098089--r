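#' @useDynLib insuloop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Internal coordinate convention: 0-based half-open [start, end), BED native.
# VCF positions are converted on ingest (pos0 = POS - 1).

#' Construct a table of genomic intervals
#'
#' The universal positional unit of the package: a `data.table` with columns
#' `chrom`, `start`, `end` (0-based half-open) and `strand` (one of
#' `"+", "-", "*"`).
#'
#' @param chrom chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions.
#' @param strand strand; `"*"` means unknown.
#' @return a `data.table` with one row per interval.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval start must be < end")
  if (!all(strand %in% c("+", "-", "*"))) stop("strand must be one of +, -, *")
  data.table(chrom = as.character(chrom), start = start, end = end,
             strand = rep_len(as.character(strand), length(chrom)))
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased and every non-ACGT letter (IUPAC ambiguity codes
#' included) is mapped to `N`, so downstream code sees the 5-letter alphabet
#' only. Chromosome names are the FASTA headers up to the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one sequence per chromosome.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  seqs <- toupper(as.character(set))
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Read loops from a BEDPE-like file
#'
#' Columns: chrom1 start1 end1 chrom2 start2 end2 \[score\]. Only
#' intra-chromosomal records are kept (the count of dropped inter-chromosomal
#' records is reported via `message`), and the two anchors are reordered so
#' the left anchor starts first.
#'
#' @param path path to a BEDPE file (no header).
#' @return `data.table` with columns `chrom`, `start1`, `end1`, `start2`,
#'   `end2` and optional `score`.
#' @export
read_loops <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 6L) stop("BEDPE file '", path, "' needs at least 6 columns")
  for (j in c(2L, 3L, 5L, 6L)) {
    v <- suppressWarnings(as.numeric(dt[[j]]))
    if (anyNA(v))
      stop("non-numeric coordinate in '", path, "' at line ",
           which(is.na(v))[1], ", column ", j)
    set(dt, j = j, value = as.integer(v))
  }
  keep <- dt[[1]] == dt[[4]]
  if (any(!keep))
    message("read_loops: dropped ", sum(!keep), " inter-chromosomal record(s)")
  dt <- dt[keep]
  out <- data.table(chrom = as.character(dt[[1]]),
                    start1 = dt[[2]], end1 = dt[[3]],
                    start2 = dt[[5]], end2 = dt[[6]])
  if (ncol(dt) >= 7L) out[, score := suppressWarnings(as.numeric(dt[[7]]))]
  swap <- out$start2 < out$start1
  if (any(swap)) {
    s1 <- out$start1[swap]; e1 <- out$end1[swap]
    out[swap, `:=`(start1 = start2, end1 = end2)]
    out[swap, `:=`(start2 = s1, end2 = e1)]
  }
  out[]
}

#' Read binding peaks from BED or narrowPeak
#'
#' The dialect is auto-detected from the column count: 3-6 columns are BED,
#' 10 columns are narrowPeak. For narrowPeak rows with a non-negative summit
#' offset (column 10) the summit is `start + offset`; otherwise the summit is
#' the interval midpoint.
#'
#' @param path path to a BED3-6 or narrowPeak file.
#' @return `data.table` with columns `chrom`, `start`, `end`, `summit`.
#' @export
read_peaks <- function(path) {
  widths <- unique(utils::count.fields(path, sep = "\t", comment.char = ""))
  if (length(widths) != 1L)
    stop("peak dialect error in '", path, "': rows have mixed column counts (",
         paste(widths, collapse = ", "), ")")
  dt <- fread(path, header = FALSE, sep = "\t")
  nc <- ncol(dt)
  if (!(nc %in% c(3:6, 10)))
    stop("peak dialect error in '", path, "': ", nc,
         " columns (expected 3-6 for BED or 10 for narrowPeak)")
  start <- as.integer(dt[[2]]); end <- as.integer(dt[[3]])
  summit <- as.integer((start + end) %/% 2L)
  if (nc == 10L) {
    off <- as.integer(dt[[10]])
    use <- !is.na(off) & off >= 0L
    summit[use] <- start[use] + off[use]
  }
  data.table(chrom = as.character(dt[[1]]), start = start, end = end,
             summit = summit)
}

#' Read motif occurrences from a FIMO-style TSV
#'
#' Requires the FIMO columns `sequence_name`, `start`, `stop`, `strand` and
#' `p-value`. FIMO reports 1-based inclusive coordinates; these are converted
#' to the package's 0-based half-open convention. Only hits with
#' `p < p_threshold` (strictly) are retained.
#'
#' @param path path to a FIMO TSV (with header).
#' @param p_threshold strict upper bound on the hit p-value; default `5e-5`.
#' @return `data.table` with columns `chrom`, `start`, `end`, `strand`,
#'   `pvalue`.
#' @export
read_motif_hits <- function(path, p_threshold = 5e-5) {
  dt <- fread(path, header = TRUE, sep = "\t")
  nm <- tolower(gsub("[^a-z_]", "", tolower(names(dt))))
  names(dt) <- nm
  need <- c("sequence_name", "start", "stop", "strand")
  if (!all(need %in% nm) || !("pvalue" %in% nm))
    stop("FIMO parse error in '", path,
         "': need columns sequence_name, start, stop, strand, p-value")
  out <- data.table(chrom = as.character(dt$sequence_name),
                    start = as.integer(dt$start) - 1L,
                    end = as.integer(dt$stop),
                    strand = as.character(dt$strand),
                    pvalue = as.numeric(dt$pvalue))
  out[pvalue < p_threshold]
}

#' Read variants from a VCF, grouped by sample
#'
#' Multi-allelic records are split into one variant per alternate allele.
#' When genotype columns are present, a variant is assigned to every sample
#' whose genotype carries the corresponding allele index; without genotype
#' columns all variants are assigned to a single pseudo-sample `"sample_1"`.
#' Records whose REF allele contains characters outside `A/C/G/T/N` are
#' rejected with a message.
#'
#' @param path path to a VCF file.
#' @return `data.table` with columns `chrom`, `pos` (1-based, as in the
#'   source), `pos0` (0-based), `ref`, `alt`, `sample_id`, `vclass`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.table(chrom = character(), pos = integer(), pos0 = integer(),
                      ref = character(), alt = character(),
                      sample_id = character(), vclass = character()))
  gt <- if (ncol(v@gt) > 1L) v@gt[, -1L, drop = FALSE] else NULL
  recs <- vector("list", nrow(fix))
  n_bad <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix$REF[i])
    alts <- toupper(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    if (!grepl("^[ACGTN]+$", ref) || !all(grepl("^[ACGTN]+$", alts))) {
      n_bad <- n_bad + 1L
      next
    }
    pos <- as.integer(fix$POS[i])
    for (ai in seq_along(alts)) {
      if (is.null(gt)) {
        samples <- "sample_1"
      } else {
        g <- sub(":.*$", "", gt[i, ])
        carries <- vapply(strsplit(g, "[/|]"), function(a) any(a == as.character(ai)),
                          logical(1))
        samples <- colnames(gt)[which(carries)]
      }
      if (length(samples) == 0L) next
      alt <- alts[ai]
      vclass <- if (nchar(ref) == nchar(alt)) "SNV"
                else if (nchar(ref) > nchar(alt)) "deletion" else "insertion"
      recs[[length(recs) + 1L]] <- data.table(
        chrom = fix$CHROM[i], pos = pos, pos0 = pos - 1L,
        ref = ref, alt = alt, sample_id = samples, vclass = vclass)
    }
  }
  if (n_bad > 0L) message("read_variants: rejected ", n_bad, " malformed record(s)")
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L)
    return(data.table(chrom = character(), pos = integer(), pos0 = integer(),
                      ref = character(), alt = character(),
                      sample_id = character(), vclass = character()))
  rbindlist(recs)
}

#' Extract a fixed-length window around a center position
#'
#' The window is `[center - length/2, center + length/2)`. Positions beyond
#' the contig ends are filled with `N` so the returned string always has
#' exactly `length` characters and the center stays at the window center.
#'
#' @param genome named character vector from [read_fasta()].
#' @param chrom chromosome name.
#' @param center 0-based center position.
#' @param length window length in bases.
#' @return character scalar of `length` bases.
#' @export
extract_window <- function(genome, chrom, center, length) {
  if (!chrom %in% names(genome)) stop("chromosome '", chrom, "' not in genome")
  length <- as.integer(length)
  if (length <= 0L) return("")
  contig <- genome[[chrom]]
  n <- nchar(contig)
  s <- as.integer(center) - length %/% 2L
  e <- s + length
  # window positions split into: before the contig, on it, and beyond it
  left_pad <- max(0L, min(e, 0L) - s)
  core <- if (s < n && e > 0L) substr(contig, max(s, 0L) + 1L, min(e, n)) else ""
  right_pad <- length - left_pad - nchar(core)
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

#' One-hot encode a DNA sequence
#'
#' Returns an `m x 5` 0/1 matrix over channels `A, C, G, T, N`; each row has
#' exactly one 1. A 4000-base anchor therefore encodes to a 4000 x 5 matrix.
#'
#' @param seq character scalar over `A/C/G/T/N` (other letters are treated
#'   as `N`).
#' @return integer matrix with `nchar(seq)` rows and 5 columns.
#' @export
one_hot_encode <- function(seq) {
  codes <- as.integer(cpp_encode_strings(seq))
  m <- matrix(0L, nrow = length(codes), ncol = 5L,
              dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  if (length(codes)) m[cbind(seq_along(codes), codes)] <- 1L
  m
}

#' Decode a one-hot matrix back to a sequence string
#' @param mat matrix produced by [one_hot_encode()].
#' @return character scalar.
#' @export
decode_one_hot <- function(mat) {
  if (ncol(mat) != 5L) stop("encoded sequence must have 5 columns")
  paste(c("A", "C", "G", "T", "N")[max.col(mat, ties.method = "first")],
        collapse = "")
}

#' Reverse complement of a DNA sequence
#'
#' `A<->T`, `C<->G`, `N<->N`, order reversed; an involution.
#' @param seq character scalar over `A/C/G/T/N`.
#' @return character scalar.
#' @export
reverse_complement <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# integer codes 1..5 (A,C,G,T,N) for a vector of equal-length sequences
encode_codes <- function(seqs) cpp_encode_strings(seqs)
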