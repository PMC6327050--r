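test_that("peak-TSS assignment follows the inclusive edge-distance rule", {
  peaks <- GenomicRanges::GRanges("chr14", IRanges::IRanges(1001, 1200))
  names(peaks) <- "peakA"
  inside <- data.frame(gene = "g0", chrom = "chr14", pos = 1100)
  res <- assignPeaksToTss(peaks, inside, 1000)
  expect_equal(res$distance, 0)

  atEdge <- data.frame(gene = "g1", chrom = "chr14", pos = 2200)
  expect_equal(assignPeaksToTss(peaks, atEdge, 1000)$distance, 1000)
  beyond <- data.frame(gene = "g2", chrom = "chr14", pos = 2201)
  expect_equal(nrow(assignPeaksToTss(peaks, beyond, 1000)), 0)
  # empty inputs
  expect_equal(nrow(assignPeaksToTss(peaks[0], inside, 1000)), 0)
})

test_that("assignment equals all-pairs brute force on random instances", {
  set.seed(23)
  for (i in 1:12) {
    nP <- sample(5:60, 1)
    nT <- sample(5:60, 1)
    chr <- c("chr1", "chr14")
    st <- sample(1:50000, nP)
    peaks <- GenomicRanges::GRanges(sample(chr, nP, replace = TRUE),
      IRanges::IRanges(st, width = sample(50:500, nP, replace = TRUE)))
    names(peaks) <- paste0("p", seq_len(nP))
    tss <- data.frame(gene = paste0("g", seq_len(nT)),
      chrom = sample(chr, nT, replace = TRUE),
      pos = sample(1:52000, nT))
    w <- sample(c(0, 100, 1000), 1)
    got <- assignPeaksToTss(peaks, tss, w)
    want <- bruteAssign(peaks, tss, w)
    rownames(got) <- NULL
    expect_equal(got, want)
  }
})

test_that("Hi-C linking thresholds on the max contact over bin pairs", {
  cm <- ContactMap(data.frame(bin_i = c(10, 11), bin_j = c(40, 40),
    value = c(10, 3)), "chr14", 5000)
  a <- GenomicRanges::GRanges("chr14", IRanges::IRanges(50001, 54000)) # bin 10
  b <- GenomicRanges::GRanges("chr14", IRanges::IRanges(200001, 204000)) # bin 40
  expect_true(hicLink(cm, a, b, 5)$linked)
  expect_equal(hicLink(cm, a, b, 5)$value, 10)
  expect_false(hicLink(cm, a, b, 11)$linked)

  # interval spanning bins 10-11 picks the max over both rows
  wide <- GenomicRanges::GRanges("chr14", IRanges::IRanges(50001, 59000))
  expect_equal(hicLink(cm, wide, b, 5)$value, 10)

  # symmetry in the two intervals
  expect_equal(hicLink(cm, b, a, 5)$value, hicLink(cm, a, b, 5)$value)

  # same-bin convention and out-of-extent flag
  same <- hicLink(cm, a, a, 1e9)
  expect_true(same$linked)
  expect_identical(same$flag, "same-bin")
  far <- GenomicRanges::GRanges("chr14", IRanges::IRanges(1e7, 1e7 + 10))
  expect_identical(hicLink(cm, a, far, 5)$flag, "no-data")
})

test_that("motif scanning handles palindromes, mismatches and IUPAC codes", {
  # TTGCGCAA is its own reverse complement: single hit, strand 'both'
  hits <- motifScan("TTGCGCAA", "TTGCGCAA")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1)
  expect_identical(hits$strand, "both")

  expect_equal(nrow(motifScan("AAAAAAAAAA", "TTGCGCAA")), 0)
  # one substitution found with a 1-mismatch budget only
  expect_equal(nrow(motifScan("TTGAGCAAGG", "TTGCGCAA", maxMismatch = 0)), 0)
  expect_gte(nrow(motifScan("TTGAGCAAGG", "TTGCGCAA", maxMismatch = 1)), 1)
  # IUPAC ambiguity in the consensus
  expect_equal(motifScan("GGACGTAG", "ACGTN", bothStrands = FALSE)$start, 3)
  expect_error(motifScan("ACGT", "AXGT"), "X")

  # non-palindromic motif: minus-strand hit reported with strand '-'
  rc <- motifScan("GGTTTCACG", "CGTGAAA", bothStrands = TRUE)
  expect_identical(rc$strand, "-")
  expect_equal(rc$start, 3)
})

test_that("hit sets reflect through reverse complementation", {
  set.seed(31)
  seq <- randomDna(500)
  motif <- "TTGCGCAA"
  fwd <- motifScan(seq, motif)
  rev <- motifScan(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq))), motif)
  L <- nchar(seq)
  # a hit at [s, e] maps to [L - e + 1, L - s + 1] with strand swapped
  expect_setequal(L - rev$end + 1, fwd$start)
})
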