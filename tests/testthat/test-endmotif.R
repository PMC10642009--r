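test_that("Watson and Crick motifs are read from the reference as documented", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACCCAGGTTAAGGCCAATTG"))
  # fragment covers CCCAGGTTAAGGCCAATT (positions 2-19, length 18)
  fs <- FragmentSet(GenomicRanges::GRanges("chr1:2-19"))
  em <- extractEndMotifs(fs, ref, k = 8)
  expect_equal(nEnds(em), 2L)

  # oracle: build the two expected motifs with Biostrings directly
  fragSeq <- Biostrings::subseq(ref[[1]], 2, 19)
  watson <- as.character(Biostrings::subseq(fragSeq, 1, 8))
  crick <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(fragSeq, 11, 18)))
  expect_equal(watson, "CCCAGGTT")
  expect_equal(crick, "AATTGGCC")
  expected <- matrix(0, nrow = 8, ncol = 4,
                     dimnames = list(position = 1:8,
                                     base = c("A", "T", "C", "G")))
  for (j in 1:8) {
    for (b in c(substring(watson, j, j), substring(crick, j, j)))
      expected[j, b] <- expected[j, b] + 0.5
  }
  expect_equal(unname(motifProps(em)), unname(expected))
  expect_true(all(abs(rowSums(motifProps(em)) - 1) < 1e-12))
})

test_that("ends too close to a contig boundary are skipped and counted", {
  ref <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 10)))
  # right end 4 bp from the contig end: Watson ok, Crick ok; second
  # fragment starts 3 bp before the end: Watson window runs off
  fs <- FragmentSet(GenomicRanges::GRanges(c("chr1:1-20", "chr1:38-40")))
  em <- extractEndMotifs(fs, ref, k = 8)
  expect_equal(em@nSkipped, 1L)
  expect_equal(nEnds(em), 3L)
})

test_that("the end-motif matrix is invariant under global strand reversal", {
  ref <- refHuman()
  fs <- simulateFragments(builtinPreset("human_healthy"), 100, ref,
                          seed = 55)
  em <- extractEndMotifs(fs, ref)

  L <- Biostrings::width(ref)[1]
  refRC <- Biostrings::DNAStringSet(Biostrings::reverseComplement(ref[[1]]))
  names(refRC) <- names(ref)
  gr <- fragments(fs)
  flipped <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(start = L - GenomicRanges::end(gr) + 1L,
                              end = L - GenomicRanges::start(gr) + 1L),
    strand = c("+" = "-", "-" = "+")[as.character(
      GenomicRanges::strand(gr))])
  emFlip <- extractEndMotifs(FragmentSet(flipped), refRC)
  expect_identical(motifCounts(emFlip), motifCounts(em))
  expect_equal(motifProps(emFlip), motifProps(em))
})

test_that("the position-1 marginal agrees with the size-stratified C-end tally", {
  ref <- refHuman()
  fs <- simulateFragments(builtinPreset("human_healthy"), 5000, ref,
                          seed = 66)
  em <- extractEndMotifs(fs, ref)
  lens <- fragmentLengths(fs)
  ce <- cEndBySize(fs, ref, lo = min(lens), hi = max(lens))
  expect_equal(sum(ce$n), nEnds(em))
  expect_equal(sum(ce$cFrac * ce$n) / sum(ce$n),
               unname(motifProps(em)[1, "C"]), tolerance = 1e-12)
  expect_equal(sum(motifProps(em)[1, ]), 1, tolerance = 1e-12)
})

test_that("fragments with forced C starts give unit C-end fractions at every occupied size", {
  ref <- Biostrings::DNAStringSet(c(chr1 = strrep("CG", 10000)))
  starts <- seq(1001, 9001, by = 200)  # odd positions: C on Watson
  fs <- FragmentSet(GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = starts, width = 100)))  # ends even: G
  ce <- cEndBySize(fs, ref, lo = 50, hi = 250)
  expect_equal(ce$size, 100L)
  expect_equal(ce$cFrac, 1.0)
  expect_equal(ce$n, 2L * length(starts))
})

test_that("sizes with no ends are absent from the C-end table", {
  ref <- Biostrings::DNAStringSet(c(chr1 = strrep("CG", 1000)))
  fs <- FragmentSet(GenomicRanges::GRanges("chr1:11-110"))
  ce <- cEndBySize(fs, ref)
  expect_identical(ce$size, 100L)
  expect_equal(nrow(ce), 1L)
})

test_that("genome base composition counts unambiguous bases only", {
  expect_equal(unname(genomeBaseComposition("AACCGGTT")),
               rep(0.25, 4))
  expect_equal(unname(genomeBaseComposition("AAAA")), c(1, 0, 0, 0))
  expect_equal(unname(genomeBaseComposition("AANN")), c(1, 0, 0, 0))
  expect_error(genomeBaseComposition("NNNN"), "no unambiguous")

  # recovery from a composition-skewed synthetic reference
  ref <- buildReference(1e6, c(0.295, 0.296, 0.204, 0.205), seed = 8)
  comp <- genomeBaseComposition(ref)
  expect_true(all(abs(comp - c(0.295, 0.296, 0.204, 0.205)) <= 0.002))
})
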