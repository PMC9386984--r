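test_that("primer search matches an exhaustive sliding-window oracle", {
  primer <- "ACGTTGACCTGAAGGATCCA" # non-periodic: shifts misalign badly
  expect_equal(locate_primer(paste0(primer, "ACGT"), primer),
               list(position = 0L, distance = 0L))

  # planted copy at offset 3 with one substitution in the middle
  set.seed(4)
  mutated <- paste0(substr(primer, 1, 9), "G", substr(primer, 11, 20))
  planted <- paste0("TTT", mutated, random_dna(40))
  hit <- locate_primer(planted, primer)
  expect_equal(hit, primer_oracle(planted, primer))
  expect_equal(hit$position, 3L)
  expect_equal(hit$distance, 1L)

  set.seed(5)
  for (i in 1:40) {
    read <- random_dna(60)
    oracle <- primer_oracle(read, primer)
    hit <- locate_primer(read, primer, max_distance = 20)
    expect_equal(hit$position, oracle$position)
    expect_equal(hit$distance, oracle$distance)
  }
})

test_that("reads with best primer distance above the cutoff are discarded", {
  primer <- "AAAAAAAAAA"
  read <- paste0("ACACACACAC", random_dna(20)) # best window has distance 5
  expect_equal(primer_oracle(read, primer)$distance, 5)
  expect_false(is.null(locate_primer(read, primer)))
  worse <- paste0("ACACACACCC", strrep("CG", 15)) # distance 6 everywhere
  expect_gt(primer_oracle(worse, primer)$distance, 5)
  expect_null(locate_primer(worse, primer))
  expect_error(locate_primer("", primer), "non-empty")
})

test_that("ties between equal-distance windows go to the leftmost", {
  hit <- locate_primer("AAATTTAAA", "AAA")
  expect_equal(hit$position, 0L)
  # every window of TAATAA is at distance 1 from AAA: leftmost wins
  hit <- locate_primer("TAATAA", "AAA", max_distance = 1)
  expect_equal(hit, list(position = 0L, distance = 1L))
})

test_that("trimming keeps target_len - primer_len bases, qualities in step", {
  primer_len <- 20
  read <- list(id = "r", sequence = random_dna(150),
               qualities = rep(30L, 150))
  out <- trim_read(read, list(position = 0L, distance = 0L), primer_len)
  expect_equal(nchar(out$sequence), 80)
  expect_equal(length(out$qualities), nchar(out$sequence))
  expect_equal(out$sequence, substr(read$sequence, 21, 100))

  # 79 bases remain after the primer: below the cutoff, discarded
  short <- list(id = "s", sequence = random_dna(99),
                qualities = rep(30L, 99))
  expect_null(trim_read(short, list(position = 0L, distance = 0L),
                        primer_len))
  # exactly 80 remain: retained
  exact <- list(id = "e", sequence = random_dna(100),
                qualities = rep(30L, 100))
  expect_equal(nchar(trim_read(exact, list(position = 0L, distance = 0L),
                               primer_len)$sequence), 80)
})

test_that("quality filter rejects low Phred scores and ambiguous bases", {
  ok <- list(id = "a", sequence = "ACGT", qualities = rep(30L, 4))
  expect_true(qc_filter(ok))
  low <- ok; low$qualities[2] <- 19L
  expect_false(qc_filter(low))
  ambig <- list(id = "b", sequence = "ACNT", qualities = rep(40L, 4))
  expect_false(qc_filter(ambig))
  edge <- ok; edge$qualities[1] <- 20L
  expect_true(qc_filter(edge))
})

test_that("deduplication conserves fragments and is idempotent", {
  expect_equal(dedup_reads(c("AAA", "AAA", "CCC")),
               c(AAA = 2L, CCC = 1L))
  expect_equal(length(dedup_reads(character(0))), 0L)
  many <- rep("ACGT", 1000)
  tab <- dedup_reads(many)
  expect_equal(unname(tab), 1000L)
  expect_equal(sum(tab), length(many))
  expect_equal(dedup_reads(names(tab)), setNames(1L, names(tab)))
})

test_that("count matrix assembly takes the union of loci with zero fill", {
  one <- list(
    alignments = data.frame(seq_id = c("s1", "s2"), chrom = c("1", "2"),
                            pos = c(100L, 200L), strand = c("+", "-")),
    counts = c(s1 = 5L, s2 = 7L))
  cm <- build_count_matrix(list(A = one))
  expect_equal(dim(cm$counts), c(2L, 1L))
  expect_equal(unname(cm$counts[, "A"]), c(5L, 7L))

  two <- list(
    alignments = data.frame(seq_id = "t1", chrom = "1", pos = 100L,
                            strand = "+"),
    counts = c(t1 = 3L))
  cm2 <- build_count_matrix(list(A = one, B = two))
  expect_equal(dim(cm2$counts), c(2L, 2L))
  expect_equal(unname(cm2$counts[, "B"]),
               c(3L, 0L)) # missing locus filled with zero
  expect_equal(unname(colSums(cm2$counts)), c(12, 3))

  # two unique sequences at the same locus merge by summation
  dup <- list(
    alignments = data.frame(seq_id = c("u1", "u2"), chrom = "1",
                            pos = 100L, strand = "+"),
    counts = c(u1 = 2L, u2 = 9L))
  cm3 <- build_count_matrix(list(A = dup))
  expect_equal(unname(cm3$counts[1, 1]), 11L)
})

test_that("locus selection removes sex chromosomes, contigs and control zeros", {
  loci <- data.frame(
    chrom = c("1", "2", "X", "Y", "GL000009.2", "3"),
    pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    strand = "+")
  counts <- cbind(ctrl1 = c(5L, 0L, 8L, 2L, 4L, 9L),
                  ctrl2 = c(3L, 7L, 1L, 1L, 1L, 2L),
                  tum = c(0L, 0L, 0L, 0L, 0L, 5L))
  cm <- rcn_count_matrix(loci, counts)
  sel <- select_loci(cm, c("ctrl1", "ctrl2"))
  expect_equal(sel$loci$chrom, c("1", "3")) # X, Y, contig, control-zero gone
  expect_equal(unname(sample_totals(sel)), unname(colSums(sel$counts)))
  expect_error(select_loci(cm, character(0)), "control")
  expect_error(select_loci(cm, "nope"), "unknown control ids")
})

test_that("arm assignment uses half-open intervals and restores order", {
  loci <- data.frame(chrom = c("1", "1", "2"),
                     pos = c(1e6L, 123400001L, 5e6L), strand = "+")
  out <- assign_arms(loci)
  expect_equal(out$arm, c("1p", "1q", "2p"))
  # position exactly at the q-arm start (0-based 123400000) is q;
  # shuffled input comes back in (chrom, pos) order
  shuffled <- loci[c(3, 1, 2), ]
  rownames(shuffled) <- NULL
  expect_equal(assign_arms(shuffled), out)
  bad <- data.frame(chrom = "99", pos = 1L, strand = "+")
  expect_error(assign_arms(bad), "outside")
})

test_that("FASTQ processing conserves reads across all discard classes", {
  primer <- "ACGTACGTACGTACGTACGT"
  good_tail <- strrep("A", 100)
  seqs <- c(
    paste0(primer, good_tail), # retained
    paste0(primer, good_tail), # duplicate of the first
    paste0(primer, strrep("C", 100)), # retained, distinct
    paste0(strrep("T", 120)), # no primer within distance 5
    paste0(primer, strrep("G", 60)), # too short after trimming
    paste0(primer, strrep("A", 40), "N", strrep("A", 59)), # ambiguous base
    paste0(primer, strrep("C", 100)) # low-quality base (see quals)
  )
  quals <- c(rep(strrep("I", 120), 4), strrep("I", 80), strrep("I", 120),
             paste0(strrep("I", 30), "#", strrep("I", 89)))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(seqs, quals, fq)

  res <- process_fastq(fq, primer)
  st <- res$stats
  expect_equal(unname(st["total"]), 7L)
  expect_equal(unname(st["discarded_primer"]), 1L)
  expect_equal(unname(st["discarded_length"]), 1L)
  expect_equal(unname(st["discarded_qc"]), 2L)
  expect_equal(unname(st["retained"]), 3L)
  expect_equal(unname(st["retained"] + st["discarded_primer"] +
                 st["discarded_length"] + st["discarded_qc"]),
               unname(st["total"]))
  expect_equal(sum(res$unique), 3L)
  expect_equal(unname(res$unique[strrep("A", 80)]), 2L)

  # determinism: identical input gives an identical table
  res2 <- process_fastq(fq, primer)
  expect_identical(res, res2)
})

test_that("unique-sequence FASTA round-trips through the alignment table", {
  uniq <- c(ACGTACGT = 4L, TTTTCCCC = 1L)
  fa <- tempfile(fileext = ".fasta")
  map <- write_unique_fasta(uniq, fa)
  lines <- readLines(fa)
  expect_equal(lines[1], ">seq000001;count=4")
  aln <- tempfile()
  writeLines(c("seq000001\t1\t1000\t+", "seq000002\t2\t2000\t-"), aln)
  tab <- read_alignment_table(aln)
  cm <- build_count_matrix(list(S = list(alignments = tab, counts = map)))
  expect_equal(unname(sample_totals(cm)), 5)
})
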