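test_that("buildReference matches the requested composition and is deterministic", {
  ref <- buildReference(10000, c(0.25, 0.25, 0.25, 0.25), seed = 1)
  comp <- genomeBaseComposition(ref)
  expect_true(all(abs(comp - 0.25) <= 0.02))
  expect_equal(Biostrings::width(ref), 10000L)

  refA <- buildReference(10000, c(1, 0, 0, 0), seed = 7)
  expect_equal(as.character(refA[[1]]), strrep("A", 10000))

  r1 <- buildReference(10000, seed = 99)
  r2 <- buildReference(10000, seed = 99)
  expect_identical(as.character(r1[[1]]), as.character(r2[[1]]))

  expect_error(buildReference(10000, c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(buildReference(500), "at least 10,000")
})

test_that("simulateFragments honours degenerate inputs", {
  ref <- refDog()
  p <- builtinPreset("human_healthy")

  fs0 <- simulateFragments(p, 0, ref, seed = 1)
  expect_length(fs0, 0L)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeFragmentsBed(fs0, bed)
  expect_length(readFragmentsBed(bed), 0L)

  spike <- simPreset("spike", nucWeights = c(1, 0, 0, 0),
                     nucSds = c(0, 0, 0, 0),
                     subpeakPositions = integer(0), subpeakWeight = 0)
  fs <- simulateFragments(spike, 100, ref, seed = 5)
  expect_true(all(fragmentLengths(fs) == 167L))
})

test_that("identical simulation arguments give byte-identical BED output", {
  ref <- refDog()
  p <- builtinPreset("dog_healthy")
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeFragmentsBed(simulateFragments(p, 3000, ref, seed = 77), f1)
  writeFragmentsBed(simulateFragments(p, 3000, ref, seed = 77), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("simulated fragments are conserved and placed within the reference", {
  ref <- refHuman()
  fs <- simulateFragments(builtinPreset("human_healthy"), 5000, ref,
                          seed = 13)
  gr <- fragments(fs)
  expect_length(fs, 5000L)
  expect_true(all(GenomicRanges::start(gr) >= 1L))
  expect_true(all(GenomicRanges::end(gr) <= Biostrings::width(ref)))
  expect_true(all(GenomicRanges::width(gr) >= 1L))
})

test_that("the reference base at each 5' end equals the drawn target base", {
  ref <- refHuman()
  fs <- simulateFragments(builtinPreset("human_healthy"), 2000, ref,
                          seed = 21)
  gr <- fragments(fs)
  seqStr <- as.character(ref[[1]])
  watson <- substring(seqStr, GenomicRanges::start(gr),
                      GenomicRanges::start(gr))
  rightBase <- substring(seqStr, GenomicRanges::end(gr),
                         GenomicRanges::end(gr))
  crick <- chartr("ATCG", "TAGC", rightBase)
  expect_identical(watson, S4Vectors::mcols(gr)$watsonBase)
  expect_identical(crick, S4Vectors::mcols(gr)$crickBase)
})

test_that("rejection sampling reports an unplaceable end base", {
  refC <- buildReference(10000, c(0, 0, 1, 0), seed = 3)  # all C
  onlyA <- simPreset("onlyA", endBaseProbs = c(1, 0, 0, 0),
                     subpeakPositions = integer(0), subpeakWeight = 0)
  expect_error(simulateFragments(onlyA, 10, refC, seed = 1),
               "lacks base A")
})

test_that("mixture weights and end-base preference are recovered from a large simulation", {
  fs <- simHuman()
  p <- builtinPreset("human_healthy")
  gr <- fragments(fs)
  labelProps <- tabulate(S4Vectors::mcols(gr)$nucOrder, 4L) / length(gr)
  expect_true(all(abs(labelProps - p@nucWeights) <= 0.005))
  baseFracW <- table(factor(S4Vectors::mcols(gr)$watsonBase,
                            levels = c("A", "T", "C", "G"))) / length(gr)
  expect_true(all(abs(as.numeric(baseFracW) - p@endBaseProbs) <= 0.003))
})
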