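#' Convert total copy number segments to relative copy number
#'
#' `RCN_i = ((1 - normal) * TCN_i + normal * 2) / meanTCN`, where `normal`
#' is the estimated normal contamination and `meanTCN` is either the
#' segment-length weighted mean TCN (`weighting = "length"`) or the plain
#' mean over loci/fragments (`weighting = "loci"`).
#'
#' @param segs data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and `value` (TCN >= 0).
#' @param normal normal contamination fraction in [0, 1).
#' @param weighting `"length"` (contiguous regions) or `"loci"` (discrete
#'   loci/fragments).
#' @return `segs` with `value` replaced by RCN.
#' @export
tcn_to_rcn <- function(segs, normal, weighting = c("length", "loci")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(segs)),
            normal >= 0, normal < 1, all(segs$value >= 0))
  len <- segs$end - segs$start + 1
  stopifnot(all(len >= 1))
  mean_tcn <- if (weighting == "length") {
    sum(segs$value * len) / sum(len)
  } else {
    mean(segs$value)
  }
  if (mean_tcn == 0) stop("mean TCN is zero; cannot rescale")
  segs$value <- ((1 - normal) * segs$value + normal * 2) / mean_tcn
  segs
}

#' Convert log2 RCN calls to RCN
#'
#' Callers that report log2 relative copy number are exponentiated before
#' any averaging or comparison.
#'
#' @param x numeric vector (or a segment data.frame with a `value` column)
#'   of log2 RCN.
#' @return same shape, on the RCN scale.
#' @export
log2rcn_to_rcn <- function(x) {
  if (is.data.frame(x)) {
    x$value <- 2^x$value
    x
  } else 2^x
}

#' Rescale RCN values over a locus subset
#'
#' When comparing callers at the intersection of their genomic loci, each
#' caller's values are divided by its mean over that subset, so every
#' caller's subset mean is 1. Idempotent.
#'
#' @param values numeric vector, non-empty with positive mean.
#' @return rescaled vector.
#' @export
rescale_rcn <- function(values) {
  if (length(values) == 0L) stop("no values to rescale")
  mu <- mean(values)
  if (!is.finite(mu) || mu <= 0) stop("mean RCN must be positive")
  values / mu
}

#' Gene-level RCN from segment calls
#'
#' Length-weighted mean of the RCN of the called regions overlapping the
#' gene, weighted by the length of each overlapping portion.
#'
#' @param segs RCN segment data.frame (`chrom`, `start`, `end`, `value`,
#'   1-based inclusive).
#' @param gene list or one-row data.frame with `chrom`, `start`, `end`.
#' @return weighted mean RCN, or `NA` (with a warning) if nothing overlaps.
#' @export
gene_rcn_segments <- function(segs, gene) {
  gr_s <- GenomicRanges::GRanges(as.character(segs$chrom),
                                 IRanges::IRanges(segs$start, segs$end))
  gr_g <- GenomicRanges::GRanges(as.character(gene$chrom),
                                 IRanges::IRanges(gene$start, gene$end))
  # disjoint sequence levels are an expected no-overlap case, not an error
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_s, gr_g))
  i <- S4Vectors::queryHits(hits)
  if (length(i) == 0L) {
    warning("gene overlaps no called segment")
    return(NA_real_)
  }
  ov <- pmin(segs$end[i], gene$end) - pmax(segs$start[i], gene$start) + 1
  sum(segs$value[i] * ov) / sum(ov)
}

#' Gene-level RCN from a per-locus profile
#'
#' Mean of the per-locus RCN values inside the gene; if no locus falls
#' inside, the nearest flanking locus on each side (by genomic distance,
#' strand-agnostic) is used instead, one-sided at chromosome ends.
#'
#' @param profile an `rcn_profile`, or its `$profile` data.frame (`chrom`,
#'   `pos`, `map_rcn`).
#' @param gene list or one-row data.frame with `chrom`, `start`, `end`.
#' @return mean RCN, or `NA` (with a warning) if the chromosome is absent
#'   from the profile.
#' @export
gene_rcn_loci <- function(profile, gene) {
  df <- if (inherits(profile, "rcn_profile")) profile$profile else profile
  df <- df[as.character(df$chrom) == as.character(gene$chrom), ,
           drop = FALSE]
  if (nrow(df) == 0L) {
    warning("chromosome ", gene$chrom, " absent from the profile")
    return(NA_real_)
  }
  df <- df[order(df$pos), ]
  inside <- df$pos >= gene$start & df$pos <= gene$end
  if (any(inside)) return(mean(df$map_rcn[inside]))
  up <- df$map_rcn[df$pos < gene$start]
  down <- df$map_rcn[df$pos > gene$end]
  flank <- c(if (length(up)) tail(up, 1), if (length(down)) down[1])
  mean(flank)
}

#' Spearman rank correlation between two RCN vectors
#'
#' Average ranks are used for ties. Zero variance in either vector makes
#' the coefficient undefined (`NA` with a warning).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the rank correlation coefficient.
#' @export
spearman_rcn <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("rank correlation undefined: zero variance")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}
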