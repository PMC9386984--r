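#' Locate the forward primer in a read
#'
#' Slides the primer along the read (full overlap only) and reports the
#' leftmost window with the minimum Hamming distance. Reads whose best
#' window exceeds `max_distance` mismatches yield `NULL` (the read is
#' discarded by the pipeline).
#'
#' @param read uppercase DNA string (A/C/G/T/N).
#' @param primer uppercase DNA string, no longer than the read.
#' @param max_distance maximum tolerated Hamming distance (default 5).
#' @return `list(position = <0-based offset>, distance = <mismatches>)`, or
#'   `NULL` if no window is within `max_distance`.
#' @export
locate_primer <- function(read, primer, max_distance = 5) {
  if (!nzchar(read) || !nzchar(primer))
    stop("read and primer must be non-empty")
  if (nchar(primer) > nchar(read))
    stop("primer longer than read")
  hit <- primer_search_cpp(read, primer)
  if (hit[1, 2] < 0 || hit[1, 2] > max_distance) return(NULL)
  list(position = hit[1, 1], distance = hit[1, 2])
}

#' Trim a read after the primer
#'
#' Removes everything up to and including the primer and truncates the
#' remainder (sequence and qualities in step) to
#' `target_len - primer_len` bases. Reads with fewer remaining bases are
#' discarded (`NULL`).
#'
#' @param read list with `id`, `sequence`, `qualities` (integer Phred
#'   scores, one per base).
#' @param hit a [locate_primer()] result for this read.
#' @param primer_len primer length in bases.
#' @param target_len total pre-trim target (default 100), so the retained
#'   read length is `target_len - primer_len`.
#' @return the trimmed read record, or `NULL` if too short.
#' @export
trim_read <- function(read, hit, primer_len, target_len = 100) {
  stopifnot(is.list(read), nchar(read$sequence) == length(read$qualities),
            target_len > primer_len)
  keep <- target_len - primer_len
  from <- hit$position + primer_len + 1 # 1-based first retained base
  avail <- nchar(read$sequence) - from + 1
  if (avail < keep) return(NULL)
  list(id = read$id,
       sequence = substr(read$sequence, from, from + keep - 1),
       qualities = read$qualities[from:(from + keep - 1)])
}

#' Quality filter for a trimmed read
#'
#' A read passes iff every base has Phred quality >= `min_phred` and the
#' sequence contains no ambiguous base call (N).
#'
#' @param read a trimmed read record (see [trim_read()]).
#' @param min_phred minimum per-base Phred score (default 20).
#' @return logical.
#' @export
qc_filter <- function(read, min_phred = 20) {
  !grepl("N", read$sequence, fixed = TRUE) &&
    all(read$qualities >= min_phred)
}

#' Collapse trimmed reads to unique sequences with counts
#'
#' @param reads character vector of QC-passed trimmed sequences.
#' @return named integer vector: unique sequence -> fragment count. Counts
#'   sum to `length(reads)`.
#' @export
dedup_reads <- function(reads) {
  if (length(reads) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(reads)
  setNames(as.integer(tab), names(tab))
}

#' Process a FASTQ file to unique trimmed sequences
#'
#' Runs the full per-read pipeline: primer search (Hamming sliding window,
#' reads with best distance > `max_distance` discarded), trim to
#' `target_len - nchar(primer)` bases after the primer (too-short reads
#' discarded), per-base quality / ambiguity filter, then deduplication.
#'
#' @param fastq path to a single-end FASTQ file (Phred+33).
#' @param primer forward primer sequence.
#' @param max_distance maximum primer Hamming distance (default 5).
#' @param target_len pre-trim target length (default 100).
#' @param min_phred minimum per-base Phred score (default 20).
#' @return list with `unique` (named count vector as [dedup_reads()]) and
#'   `stats`, a named integer vector with `total`, `discarded_primer`,
#'   `discarded_length`, `discarded_qc` and `retained`
#'   (`retained + discards == total`).
#' @export
process_fastq <- function(fastq, primer, max_distance = 5, target_len = 100,
                          min_phred = 20) {
  if (!file.exists(fastq)) stop("FASTQ file not found: ", fastq)
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                        with.qualities = TRUE)
  seqs <- as.character(reads)
  quals <- as.character(S4Vectors_mcols_qualities(reads))
  total <- length(seqs)
  plen <- nchar(primer)
  keep_len <- target_len - plen
  if (keep_len < 1) stop("target_len must exceed the primer length")

  hits <- primer_search_cpp(seqs, primer)
  ok_primer <- hits[, 2] >= 0 & hits[, 2] <= max_distance
  n_primer <- sum(!ok_primer)

  from <- hits[, 1] + plen + 1 # 1-based first retained base
  avail <- nchar(seqs) - from + 1
  ok_len <- ok_primer & avail >= keep_len
  n_len <- sum(ok_primer & !ok_len)

  idx <- which(ok_len)
  trimmed <- substr(seqs[idx], from[idx], from[idx] + keep_len - 1)
  tqual <- substr(quals[idx], from[idx], from[idx] + keep_len - 1)
  minq <- vapply(tqual, function(q) min(utf8ToInt(q)) - 33L, integer(1),
                 USE.NAMES = FALSE)
  ok_qc <- minq >= min_phred & !grepl("N", trimmed, fixed = TRUE)
  n_qc <- sum(!ok_qc)

  retained <- trimmed[ok_qc]
  list(unique = dedup_reads(retained),
       stats = c(total = total, discarded_primer = n_primer,
                 discarded_length = n_len, discarded_qc = as.integer(n_qc),
                 retained = length(retained)))
}

# qualities live in the metadata columns of the DNAStringSet
S4Vectors_mcols_qualities <- function(reads) {
  q <- S4Vectors::mcols(reads)$qualities
  if (is.null(q)) stop("FASTQ qualities missing")
  q
}

#' Write unique sequences as FASTA for external alignment
#'
#' One record per unique sequence; the header encodes a stable sequence id
#' and the fragment count: `>seq000001;count=12`. Alignment itself is
#' delegated to an external aligner (unique-mapping alignments only); its
#' output is consumed by [read_alignment_table()] or [read_alignments_sam()].
#'
#' @param uniq named count vector from [dedup_reads()]/[process_fastq()].
#' @param path output FASTA path.
#' @return invisibly, a data.frame mapping `seq_id` to `count`.
#' @export
write_unique_fasta <- function(uniq, path) {
  ids <- sprintf("seq%06d", seq_along(uniq))
  x <- Biostrings::DNAStringSet(names(uniq))
  names(x) <- sprintf("%s;count=%d", ids, as.integer(uniq))
  Biostrings::writeXStringSet(x, path)
  invisible(data.frame(seq_id = ids, count = as.integer(uniq)))
}

#' Read a tab-delimited alignment table
#'
#' Four columns, no header: sequence id (matching the FASTA written by
#' [write_unique_fasta()]), chromosome, 1-based position, strand. One row
#' per uniquely-mapping sequence (multi-mappers are expected to have been
#' discarded by the aligner).
#'
#' @param path alignment TSV.
#' @return data.frame with `seq_id`, `chrom`, `pos`, `strand`.
#' @export
read_alignment_table <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  df <- read.delim(path, header = FALSE,
                   col.names = c("seq_id", "chrom", "pos", "strand"),
                   colClasses = c("character", "character", "integer",
                                  "character"))
  df
}

#' Read unique-sequence alignments from SAM/BAM
#'
#' Extracts (read name, chrom, 1-based pos, strand) for mapped primary
#' alignments. Requires the Rsamtools package.
#'
#' @param path SAM or BAM file.
#' @return data.frame as [read_alignment_table()].
#' @export
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("the Rsamtools package is required to read SAM/BAM alignments")
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "strand"),
                               flag = flag)
  a <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.frame(seq_id = a$qname, chrom = as.character(a$rname),
             pos = as.integer(a$pos), strand = as.character(a$strand))
}

#' Assemble the per-locus count matrix across samples
#'
#' Rows are the union of aligned genomic positions (chrom, pos, strand)
#' over all samples; a sample's count at a locus is the sum of the fragment
#' counts of its unique sequences aligning there (two unique sequences may
#' align to the same locus); loci absent from a sample get 0.
#'
#' @param per_sample named list (one element per sample id), each a list
#'   with `alignments` (data.frame `seq_id`, `chrom`, `pos`, `strand`) and
#'   `counts` (either the named unique-sequence count vector or a
#'   data.frame `seq_id`/`count` as returned by [write_unique_fasta()]).
#' @return an `rcn_count_matrix` over the union of loci.
#' @export
build_count_matrix <- function(per_sample) {
  stopifnot(is.list(per_sample), length(per_sample) > 0,
            !is.null(names(per_sample)))
  per_locus <- lapply(names(per_sample), function(id) {
    x <- per_sample[[id]]
    aln <- x$alignments
    cnt <- x$counts
    if (is.data.frame(cnt)) {
      cvec <- setNames(cnt$count, cnt$seq_id)
      n <- cvec[aln$seq_id]
    } else if (!is.null(names(cnt))) {
      n <- unname(cnt[aln$seq_id])
      if (anyNA(n)) { # counts keyed by sequence id table instead
        idmap <- setNames(as.integer(cnt), sprintf("seq%06d", seq_along(cnt)))
        n <- idmap[aln$seq_id]
      }
    } else stop("counts must be named or a seq_id/count data.frame")
    if (anyNA(n))
      stop("alignment of sample '", id, "' refers to unknown sequence ids")
    key <- paste(aln$chrom, aln$pos, aln$strand, sep = "\r")
    tapply(as.integer(n), key, sum)
  })
  names(per_locus) <- names(per_sample)
  keys <- sort(unique(unlist(lapply(per_locus, names))))
  counts <- vapply(per_locus, function(v) {
    out <- integer(length(keys))
    out[match(names(v), keys)] <- as.integer(v)
    out
  }, integer(length(keys)))
  counts <- matrix(counts, nrow = length(keys),
                   dimnames = list(NULL, names(per_sample)))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  loci <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                     strand = parts[, 3])
  rcn_count_matrix(loci, counts)
}
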