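test_that("read_fasta validates, uppercases and trims terminal stops", {
  f <- write_fasta_tmp(c(h = "atgaaa"))
  rec <- read_fasta(f, "cds")
  expect_equal(rec$seq, "ATGAAA")
  expect_equal(rec$id, "h")

  f2 <- write_fasta_tmp(c(h = "ATGTAA"))
  expect_message(rec2 <- read_fasta(f2, "cds"), "terminal stop")
  expect_equal(rec2$seq, "ATG")

  f3 <- tempfile(); writeLines(character(0), f3)
  expect_warning(rec3 <- read_fasta(f3, "protein"), "empty")
  expect_equal(nrow(rec3), 0)

  f4 <- tempfile(); writeLines(c("MKV", ">h", "MKV"), f4)
  expect_error(read_fasta(f4, "protein"), "line 1")

  f5 <- write_fasta_tmp(c(h = "MK*V"))
  expect_error(read_fasta(f5, "protein"), "internal stop")

  f6 <- write_fasta_tmp(c(h = "ATGTAAAAA"))
  expect_error(read_fasta(f6, "cds"), "internal stop")

  f7 <- write_fasta_tmp(c(h = "ATGA"))
  expect_error(read_fasta(f7, "cds"), "multiple of 3")
})

test_that("codon alignments expand residues and gaps and catch mismatches", {
  aln <- pairwise_alignment("M", "M", "protein")
  ca <- build_codon_alignment(aln, "ATG", "ATG")
  expect_equal(ca$a, "ATG")
  expect_equal(ca$b, "ATG")

  aln2 <- pairwise_alignment("M-", "MK", "protein")
  ca2 <- build_codon_alignment(aln2, "ATG", "ATGAAA")
  expect_equal(ca2$a, "ATG---")
  expect_equal(ca2$b, "ATGAAA")

  aln3 <- pairwise_alignment("MK", "MK", "protein")
  expect_error(build_codon_alignment(aln3, "ATGCCC", "ATGAAA"),
               "residue 2")
})

test_that("codon alignment round-trips over random gapped pairs", {
  for (seed in 1:10) {
    fx <- random_gapped_pair(40, seed = seed)
    ca <- build_codon_alignment(fx$aln, fx$cds_a, fx$cds_b)
    for (row in c("a", "b")) {
      cds <- gsub("-", "", ca[[row]])
      expect_equal(cds, fx[[paste0("cds_", row)]])
      aa <- paste(GC_TABLE[substring(cds, seq(1, nchar(cds), 3),
                                     seq(3, nchar(cds), 3))],
                  collapse = "")
      expect_equal(aa, gsub("-", "", fx$aln[[row]]))
    }
  }
})

test_that("pairwise deletion keeps only clean columns, symmetrically", {
  aln <- pairwise_alignment("AC-", "A-G", "dna")
  expect_equal(pairwise_deletion_mask(aln), 1L)
  flipped <- pairwise_alignment("A-G", "AC-", "dna")
  expect_equal(pairwise_deletion_mask(flipped), 1L)

  clean <- pairwise_alignment("MKVA", "MRVA", "protein")
  expect_equal(pairwise_deletion_mask(clean), 1:4)

  # ambiguity symbols are missing data
  amb <- pairwise_alignment("MXV", "MKV", "protein")
  expect_equal(pairwise_deletion_mask(amb), c(1L, 3L))

  # codon mode: one masked position removes the whole codon
  ca <- structure(list(a = "ATG", b = "AT-"), class = "codon_alignment")
  expect_length(pairwise_deletion_mask(ca), 0)

  ca2 <- structure(list(a = "ATGAAA", b = "ATNAAA"),
                   class = "codon_alignment")
  expect_equal(pairwise_deletion_mask(ca2), 4:6)

  # random alignments: mask invariant under row swap
  for (seed in 1:5) {
    fx <- random_gapped_pair(30, seed = 100 + seed)
    sw <- pairwise_alignment(fx$aln$b, fx$aln$a, "protein")
    expect_equal(pairwise_deletion_mask(fx$aln),
                 pairwise_deletion_mask(sw))
  }
})

test_that("domain slicing follows reference coordinates", {
  dm <- data.frame(gene = "g", segment = c("FL", "EC1"),
                   start = c(1, 1), end = c(4, 3))
  aln <- pairwise_alignment("MKV-A", "MKVQA", "protein")
  ec1 <- slice_domain(aln, dm, "EC1", "a")
  expect_equal(ec1$a, "MKV-")
  expect_equal(ec1$b, "MKVQ")
  fl <- slice_domain(aln, dm, "FL", "a")
  expect_equal(fl$a, aln$a)
  expect_equal(fl$b, aln$b)
  expect_error(slice_domain(aln, dm, "CD", "a"), "not in domain map")
  dm_bad <- data.frame(gene = "g", segment = "EC9", start = 4, end = 5)
  aln3 <- pairwise_alignment("MKV", "MKV", "protein")
  expect_error(slice_domain(aln3, dm_bad, "EC9", "a"), "beyond")
})

test_that("tiling domain slices cover the full-length alignment", {
  fx <- random_gapped_pair(60, seed = 9)
  len <- nchar(gsub("-", "", fx$aln$a))
  cuts <- sort(sample(seq_len(len - 1), 3))
  starts <- c(1, cuts + 1)
  ends <- c(cuts, len)
  dm <- data.frame(gene = "g",
                   segment = paste0("S", seq_along(starts)),
                   start = starts, end = ends)
  pieces_a <- pieces_b <- character(0)
  for (s in dm$segment) {
    sl <- slice_domain(fx$aln, dm, s, "a")
    pieces_a <- c(pieces_a, sl$a)
    pieces_b <- c(pieces_b, sl$b)
  }
  # leading columns where the reference row is gapped precede coordinate 1
  ref <- strsplit(fx$aln$a, "")[[1]]
  lead <- match(TRUE, ref != "-") - 1L
  expect_equal(paste(pieces_a, collapse = ""),
               substring(fx$aln$a, lead + 1L))
  expect_equal(paste(pieces_b, collapse = ""),
               substring(fx$aln$b, lead + 1L))
})

test_that("tabular readers validate their inputs", {
  f <- tempfile()
  writeLines(c("gene\tsegment\tstart\tend", "g\tFL\t1\t100",
               "g\tEC1\t1\t50", "g\tEC2\t51\t100"), f)
  dm <- read_domain_map(f)
  expect_equal(nrow(dm), 3)

  f2 <- tempfile()
  writeLines(c("gene\tsegment\tstart\tend", "g\tEC1\t1\t50",
               "g\tEC2\t40\t100"), f2)
  expect_error(read_domain_map(f2), "overlapping")

  f3 <- tempfile()
  writeLines(c("species\tmyr\tgroup", "chimp\t6.7\tapes"), f3)
  expect_equal(read_divergence_table(f3)$myr, 6.7)

  f4 <- tempfile()
  writeLines(c("species\tmyr\tgroup", "chimp\t-1\tapes"), f4)
  expect_error(read_divergence_table(f4), "positive")
})
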