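#' Construct a per-locus count matrix
#'
#' The central data container: integer counts at L genomic loci (rows) by S
#' samples (columns), with locus coordinates, strand and (optionally)
#' chromosome-arm labels.
#'
#' @param loci data.frame with columns `chrom`, `pos` (1-based), `strand`
#'   (`+`/`-`) and optionally `arm`.
#' @param counts integer matrix, `nrow(loci)` x number of samples; column
#'   names are the sample ids.
#' @return An object of class `rcn_count_matrix`: a list with elements
#'   `loci`, `counts` and `samples`. Loci are sorted by (chrom, pos).
#' @export
rcn_count_matrix <- function(loci, counts) {
  counts <- as.matrix(counts)
  stopifnot(is.data.frame(loci),
            all(c("chrom", "pos", "strand") %in% names(loci)),
            nrow(loci) == nrow(counts))
  if (is.null(colnames(counts)))
    stop("counts must have sample ids as column names")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  loci$strand <- as.character(loci$strand)
  key <- paste(loci$chrom, loci$pos, loci$strand)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, strand) loci")
  ord <- order(chrom_order(loci$chrom), loci$pos)
  loci <- loci[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(loci = loci, counts = counts, samples = colnames(counts)),
            class = "rcn_count_matrix")
}

# sortable chromosome key: numeric autosomes first, then X, Y, others
chrom_order <- function(chrom) {
  c0 <- sub("^chr", "", chrom)
  n <- suppressWarnings(as.integer(c0))
  n[is.na(n) & c0 == "X"] <- 23L
  n[is.na(n) & c0 == "Y"] <- 24L
  n[is.na(n)] <- 25L
  n * 1e10 + as.integer(factor(chrom)) # stable within non-standard contigs
}

#' Per-sample totals over retained loci
#' @param cm an `rcn_count_matrix`.
#' @return named numeric vector of column sums.
#' @export
sample_totals <- function(cm) colSums(cm$counts)

#' @export
print.rcn_count_matrix <- function(x, ...) {
  cat(sprintf("rcn_count_matrix: %d loci x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

#' Write a count matrix as tab-delimited text
#'
#' Layout: header row, columns `chrom`, `pos`, `strand`, then one integer
#' column per sample.
#' @param cm an `rcn_count_matrix`.
#' @param path output file.
#' @export
write_count_matrix <- function(cm, path) {
  df <- cbind(cm$loci[c("chrom", "pos", "strand")],
              as.data.frame(cm$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited count matrix
#' @param path file written by [write_count_matrix()] (or assembled
#'   upstream): `chrom`, `pos`, `strand`, then one column per sample.
#' @return an `rcn_count_matrix`.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = NA)
  need <- c("chrom", "pos", "strand")
  if (!all(need %in% names(df)))
    stop("count matrix must have columns chrom, pos, strand")
  samp <- setdiff(names(df), c(need, "arm"))
  if (length(samp) == 0L) stop("count matrix has no sample columns")
  counts <- as.matrix(df[samp])
  storage.mode(counts) <- "integer"
  rcn_count_matrix(df[intersect(names(df), c(need, "arm"))], counts)
}

#' Default chromosome-arm boundary table (GRCh38)
#'
#' Half-open BED-like intervals (0-based `start`, exclusive `end`) splitting
#' each autosome at its approximate centromere midpoint. The table is a
#' packaged convenience; supply your own for a different assembly or a
#' cytoband-exact split.
#'
#' @return data.frame with columns `chrom`, `arm`, `start`, `end`.
#' @export
default_arm_boundaries <- function() {
  path <- system.file("extdata", "arm_boundaries_grch38.tsv",
                      package = "repeatcn")
  read.delim(path, colClasses = c("character", "character",
                                  "numeric", "numeric"))
}

#' Label loci with chromosome arms
#'
#' Each locus is assigned the unique arm whose half-open interval
#' `[start, end)` (0-based) contains `pos - 1`; a locus exactly at an arm's
#' start belongs to that arm. Output is sorted by (chrom, pos).
#'
#' @param loci data.frame with `chrom`, `pos` (1-based), `strand`.
#' @param arm_bounds data.frame like [default_arm_boundaries()].
#' @return `loci` with an `arm` column, sorted by (chrom, pos).
#' @export
assign_arms <- function(loci, arm_bounds = default_arm_boundaries()) {
  stopifnot(all(c("chrom", "arm", "start", "end") %in% names(arm_bounds)))
  strip <- function(x) sub("^chr", "", as.character(x))
  bounds <- GenomicRanges::GRanges(
    strip(arm_bounds$chrom),
    IRanges::IRanges(start = arm_bounds$start + 1, end = arm_bounds$end))
  gl <- GenomicRanges::GRanges(strip(loci$chrom),
                               IRanges::IRanges(loci$pos, width = 1))
  hit <- suppressWarnings(
    GenomicRanges::findOverlaps(gl, bounds, select = "first"))
  if (anyNA(hit)) {
    bad <- which(is.na(hit))
    stop("loci outside every arm interval: ",
         paste(utils::head(paste0(loci$chrom[bad], ":", loci$pos[bad]), 5),
               collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5))
  }
  loci$arm <- arm_bounds$arm[hit]
  ord <- order(chrom_order(loci$chrom), loci$pos)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Select loci for modelling
#'
#' Drops loci on chromosomes X and Y and on unplaced or unresolved contigs,
#' and drops any locus with a zero count in at least one control sample.
#' Totals are implicitly recomputed over the retained loci.
#'
#' @param cm an `rcn_count_matrix`.
#' @param control_ids character vector of control sample ids (non-empty,
#'   all present in `cm$samples`).
#' @return the filtered `rcn_count_matrix`.
#' @export
select_loci <- function(cm, control_ids) {
  stopifnot(inherits(cm, "rcn_count_matrix"))
  if (length(control_ids) == 0L)
    stop("at least one control sample is required to select loci")
  if (!all(control_ids %in% cm$samples))
    stop("unknown control ids: ",
         paste(setdiff(control_ids, cm$samples), collapse = ", "))
  c0 <- sub("^chr", "", cm$loci$chrom)
  autosomal <- c0 %in% as.character(1:22)
  positive <- rowSums(cm$counts[, control_ids, drop = FALSE] == 0) == 0
  keep <- autosomal & positive
  if (!any(keep)) stop("no loci retained after selection")
  rcn_count_matrix(cm$loci[keep, , drop = FALSE],
                   cm$counts[keep, , drop = FALSE])
}
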