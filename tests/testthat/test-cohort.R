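test_that("feature extraction is a deterministic point evaluation of the profile", {
  fs <- FragmentSet(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(100, 500, 900), width = 102)),
    sampleId = "s1")
  f <- extractFeatures(fs)
  expect_equal(unname(peakRatios(f)["102"]), 1.0)
  expect_true(all(peakRatios(f)[names(peakRatios(f)) != "102"] == 0))
  f2 <- extractFeatures(fs)
  expect_identical(peakRatios(f2), peakRatios(f))

  empty <- FragmentSet(GenomicRanges::GRanges())
  expect_error(extractFeatures(empty), "no fragments")
})

test_that("the U statistic matches the brute-force cross-pair count", {
  bruteU <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  set.seed(10)
  for (rep in 1:20) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- round(runif(nx), 2)  # rounding induces occasional ties
    y <- round(runif(ny), 2)
    r <- suppressWarnings(rankSumTest(x, y))
    expect_equal(r$U, bruteU(x, y), label = paste("rep", rep))
  }
})

test_that("fully separated small groups give U = 0 and exact two-sided p = 0.1", {
  r <- rankSumTest(c(0.01, 0.02, 0.03), c(0.11, 0.12, 0.13))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 / choose(6, 3): enumerate the 20 labelings
  expect_equal(r$method, "exact")
})

test_that("identical groups tie out at p = 1 at every position", {
  ratios <- function(v) setNames(v, c("50", "102"))
  g <- lapply(1:4, function(i)
    makeFeatures(paste0("s", i), ratios(c(0.01 * i, 0.02 * i))))
  cmp <- suppressWarnings(comparePeakRatios(g, g))
  expect_true(all(cmp$pValue == 1))
  expect_true(all(cmp$direction == "tie"))
  expect_equal(cmp$U, rep(8, 2))  # nA * nB / 2
})

test_that("swapping group labels flips direction but not p-values", {
  set.seed(3)
  gA <- lapply(1:5, function(i)
    makeFeatures(paste0("a", i), setNames(runif(2, 0.01, 0.02),
                                          c("60", "70")), group = "healthy"))
  gB <- lapply(1:5, function(i)
    makeFeatures(paste0("b", i), setNames(runif(2, 0.03, 0.04),
                                          c("60", "70")), group = "cancer"))
  ab <- comparePeakRatios(gA, gB)
  ba <- comparePeakRatios(gB, gA)
  expect_equal(ba$pValue, ab$pValue)
  expect_equal(ba$pAdj, ab$pAdj)
  expect_true(all(ab$direction == "cancer>healthy"))
  expect_true(all(ba$direction == "cancer>healthy"))
})

test_that("groups below three samples are rejected", {
  g2 <- lapply(1:2, function(i)
    makeFeatures(paste0("s", i), setNames(0.01 * i, "50")))
  g3 <- lapply(1:3, function(i)
    makeFeatures(paste0("s", i), setNames(0.01 * i, "50")))
  expect_error(comparePeakRatios(g2, g3), "at least 3")
  expect_error(compareCend(g3, g2), "at least 3")
})

test_that("paired C-end comparison matches the closed-form paired t statistic", {
  sizes <- 50:99
  cendTab <- function(cf) data.frame(size = sizes, n = 100L, cFrac = cf)
  baseA <- 0.36 + 0.01 * sin(sizes / 5)
  set.seed(8)
  noise <- rnorm(length(sizes), 0, 0.004)
  gA <- lapply(1:3, function(i) makeFeatures(paste0("a", i),
    setNames(0.01, "50"), cend = cendTab(baseA)))
  gB <- lapply(1:3, function(i) makeFeatures(paste0("b", i),
    setNames(0.01, "50"), cend = cendTab(baseA - 0.05 + noise)))
  res <- compareCend(gA, gB)
  d <- (baseA) - (baseA - 0.05 + noise)  # group means equal the tables
  tClosed <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$statistic, tClosed, tolerance = 1e-12)
  expect_equal(res$pValue,
               2 * pt(-abs(tClosed), df = length(d) - 1),
               tolerance = 1e-12)
  expect_equal(res$direction, "A>B")
  expect_equal(res$n, length(sizes))
})

test_that("degenerate paired comparisons are guarded", {
  sizes <- 50:70
  tab <- data.frame(size = sizes, n = 10L, cFrac = 0.3)
  g <- lapply(1:3, function(i) makeFeatures(paste0("s", i),
    setNames(0.01, "50"), cend = tab))
  same <- suppressWarnings(compareCend(g, g))
  expect_equal(same$statistic, 0)
  expect_equal(same$pValue, 1)

  tabShift <- transform(tab, cFrac = cFrac - 0.05)
  gB <- lapply(1:3, function(i) makeFeatures(paste0("b", i),
    setNames(0.01, "50"), cend = tabShift))
  res <- suppressWarnings(compareCend(g, gB))
  expect_equal(res$pValue, 0)
  expect_equal(res$direction, "A>B")

  short <- data.frame(size = 50L, n = 10L, cFrac = 0.3)
  gS <- lapply(1:3, function(i) makeFeatures(paste0("x", i),
    setNames(0.01, "50"), cend = short))
  expect_error(suppressWarnings(compareCend(gS, gS)), "shared")
})

test_that("per-sample mode compares end-count-weighted sample means", {
  tabA <- data.frame(size = 50:69, n = 100L, cFrac = 0.36)
  gA <- lapply(1:4, function(i) makeFeatures(paste0("a", i),
    setNames(0.01, "50"), cend = transform(tabA,
      cFrac = cFrac + 0.002 * i)))
  gB <- lapply(1:4, function(i) makeFeatures(paste0("b", i),
    setNames(0.01, "50"), cend = transform(tabA,
      cFrac = cFrac - 0.05 + 0.002 * i)))
  res <- compareCend(gA, gB, mode = "per_sample")
  a <- sapply(1:4, function(i) 0.36 + 0.002 * i)
  b <- a - 0.05
  tt <- t.test(a, b)
  expect_equal(res$statistic, unname(tt$statistic))
  expect_equal(res$pValue, tt$p.value)
  expect_equal(res$mode, "per_sample")
})

test_that("sample manifests require the documented columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup\tbed_path",
               "s1\thealthy\ts1.bed"), f)
  m <- readSampleManifest(f)
  expect_equal(m$sample_id, "s1")
  writeLines(c("sample\tgroup", "s1\thealthy"), f)
  expect_error(readSampleManifest(f), "missing columns")
})
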