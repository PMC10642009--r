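test_that("the histogram tallies lengths exactly and excludes out-of-range fragments", {
  p <- sizeHistogram(c(167, 167, 167))
  expect_equal(unname(profileCounts(p)["167"]), 3L)
  expect_equal(unname(profileFreq(p)["167"]), 1.0)
  expect_equal(profileTotal(p), 3L)

  expect_equal(profileTotal(sizeHistogram(numeric(0))), 0L)
  expect_equal(profileTotal(sizeHistogram(c(10, 900), lo = 30, hi = 800)),
               0L)

  set.seed(2)
  lens <- sample(100:199, 1000, replace = TRUE)
  p2 <- sizeHistogram(lens, lo = 30, hi = 800)
  expect_equal(profileTotal(p2), 1000L)
  # independent tally oracle
  oracle <- table(factor(lens, levels = 30:800))
  expect_equal(unname(profileCounts(p2)), unname(as.integer(oracle)))
})

test_that("peakRatio is the windowed count fraction, with scale invariance and a total-zero guard", {
  counts <- integer(771)
  names(counts) <- 30:800
  counts[as.character(166:168)] <- c(10L, 20L, 10L)
  counts[as.character(400)] <- 60L
  p <- sizeProfile(counts, 30, 800)
  expect_equal(peakRatio(p, 167), 0.40)
  expect_equal(peakRatio(p, 100), 0.0)          # empty window
  expect_equal(peakRatio(p, 167),
               peakRatio(sizeProfile(counts * 10L, 30, 800), 167))

  empty <- sizeProfile(integer(771), 30, 800)
  expect_error(peakRatio(empty, 167), "undefined ratio")
  expect_error(peakRatio(p, 30), "outside")

  # ratios over a disjoint window partition sum to 1
  p3 <- sizeHistogram(sample(100:129, 500, replace = TRUE), 100, 129)
  centers <- seq(101, 128, by = 3)
  expect_equal(sum(vapply(centers, function(cc) peakRatio(p3, cc, 1L),
                          numeric(1))), 1.0)
})

test_that("a single spike is called as a single major peak at its size", {
  p <- sizeHistogram(rep(167, 50), lo = 30, hi = 800)
  mp <- findMajorPeaks(p)
  expect_equal(nrow(mp), 1L)
  expect_equal(mp$position, 167)
  expect_equal(mp$bin, 167L)
})

test_that("major-peak bins are a subset of the local maxima of the smoothed profile", {
  fs <- simHuman()
  prof <- sizeHistogram(fs)
  mp <- findMajorPeaks(prof)
  # exhaustive-scan oracle for local maxima of the 3-bp smoothed frequency
  f <- unname(profileFreq(prof))
  s <- stats::filter(f, rep(1 / 3, 3), sides = 2)
  sizes <- 30:800
  isMax <- vapply(2:(length(f) - 1), function(i)
    !is.na(s[i]) && s[i] > s[i - 1] && s[i] > s[i + 1], logical(1))
  oracleMaxima <- sizes[c(FALSE, isMax, FALSE)]
  expect_true(all(mp$bin %in% oracleMaxima))
})

test_that("subpeak detection recovers the closed-form maxima of a 10-bp cosine", {
  s <- 40:160
  counts <- round(1000 * (1 + cos(2 * pi * s / 10)))
  p <- sizeProfile(counts, 40, 160)
  sp <- findSubpeaks(p, window = c(40L, 160L))
  expect_identical(sp$position, seq(50L, 150L, by = 10L))
  expect_true(all(diff(sp$position) >= 8L))
})

test_that("flat and empty profiles yield no subpeaks", {
  flat <- sizeProfile(rep(5L, 121), 40, 160)
  expect_equal(nrow(findSubpeaks(flat)), 0L)
  expect_equal(nrow(findSubpeaks(sizeProfile(integer(121), 40, 160))), 0L)
})

test_that("equal-height adjacent subpeak bins resolve to the lower size", {
  counts <- integer(121)  # sizes 40..160
  counts[c(61, 62)] <- 100L   # plateau at 100-101 bp
  counts[81] <- 40L           # smaller peak at 120 bp
  p <- sizeProfile(counts, 40, 160)
  sp <- findSubpeaks(p)
  expect_true(100L %in% sp$position)
  expect_false(101L %in% sp$position)
})

test_that("nucleosome proportions bin lengths by the valley cut points", {
  np <- nucleosomeProportions(c(100, 100, 300, 500, 700))
  expect_equal(unname(proportions(np)), c(0.4, 0.2, 0.2, 0.2))
  expect_equal(sum(proportions(np)), 1)

  np1 <- nucleosomeProportions(rep(167, 10))
  expect_equal(unname(proportions(np1)), c(1, 0, 0, 0))

  expect_error(nucleosomeProportions(numeric(0)), "no classifiable")
  expect_error(nucleosomeProportions(c(900, 1000)), "no classifiable")
  expect_error(nucleosomeProportions(c(100), boundaries = c(450, 250, 650)),
               "increasing")
})

test_that("lifting the upper limit never decreases the tetra-nucleosome tally", {
  lens <- c(100, 300, 700, 790, 810, 950)
  np800 <- nucleosomeProportions(lens, upper = 800)
  npInf <- nucleosomeProportions(lens, upper = 1e9)
  tetra800 <- proportions(np800)["tetra"] * np800@nClassified
  tetraInf <- proportions(npInf)["tetra"] * npInf@nClassified
  expect_gte(tetraInf, tetra800)
})

test_that("canonical cohort query positions expose the 11- and 10-position sets", {
  p11 <- canonicalPeakPositions()
  expect_length(p11, 11L)
  expect_true(144L %in% p11)
  p10 <- canonicalPeakPositions("ten")
  expect_identical(p10, p11[p11 != 144L])
})
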