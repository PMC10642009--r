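#' @include AllClasses.R AllGenerics.R sizeprofile.R endmotif.R
NULL

#' Extract per-sample fragmentomic features
#'
#' Computes the cohort feature vector of one sample: the +/-1 bp peak-ratio
#' proxy at a fixed set of canonical subpeak positions (relative to the
#' sample's total in-range fragments) and, when a reference is supplied,
#' the per-size C-end fractions over the mono-nucleosomal size range.
#'
#' @param frags a non-empty [FragmentSet-class].
#' @param reference DNAStringSet / FASTA path, or NULL to skip the C-end
#'   features (e.g. for size-only analyses).
#' @param positions peak query positions in bp
#'   (default [canonicalPeakPositions()]).
#' @param histRange integer(2), histogram bounds in bp.
#' @param sizeRange integer(2), size range for the C-end stratification.
#' @param group optional group label carried into comparisons.
#' @param bothEnds tally both fragment ends for C-end features.
#' @return A [SampleFeatures-class].
#' @examples
#' fs <- FragmentSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(
#'   start = c(100, 200, 300), width = 102)))
#' extractFeatures(fs)
#' @export
extractFeatures <- function(frags, reference = NULL,
                            positions = canonicalPeakPositions(),
                            histRange = c(30L, 800L),
                            sizeRange = c(50L, 250L),
                            group = NA_character_, bothEnds = TRUE) {
  stopifnot(is(frags, "FragmentSet"))
  profile <- sizeHistogram(frags, histRange[1], histRange[2])
  if (profileTotal(profile) == 0L)
    stop("cannot extract features: no fragments in the histogram range")
  ratios <- vapply(positions, function(p) peakRatio(profile, p, 1L),
                   numeric(1))
  names(ratios) <- as.character(positions)
  cend <- if (is.null(reference)) {
    data.frame(size = integer(0), n = integer(0), cFrac = numeric(0))
  } else {
    cEndBySize(frags, reference, sizeRange[1], sizeRange[2],
               bothEnds = bothEnds)
  }
  new("SampleFeatures", sampleId = frags@sampleId,
      group = as.character(group), peakRatios = ratios, cend = cend,
      total = profileTotal(profile))
}

#' @rdname accessors
setMethod("peakRatios", "SampleFeatures", function(x) x@peakRatios)

#' @rdname accessors
setMethod("sampleId", "SampleFeatures", function(x) x@sampleId)

setMethod("show", "SampleFeatures", function(object) {
  cat("SampleFeatures '", object@sampleId, "'", sep = "")
  if (!is.na(object@group)) cat(" [", object@group, "]", sep = "")
  cat(": ", object@total, " in-range fragments, ",
      length(object@peakRatios), " peak ratios, ",
      nrow(object@cend), " C-end sizes\n", sep = "")
  invisible(object)
})

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Thin wrapper around [stats::wilcox.test()] reporting the U statistic of
#' the first group: the number of cross-group pairs \code{(a, b)} with
#' \code{a > b} plus half the ties (fully separated groups with every
#' \code{a} below every \code{b} give U = 0). The exact null distribution
#' is used when the combined sample
#' size is at most 20 and the data are tie-free; otherwise the normal
#' approximation with tie-corrected variance is used. When every value in
#' both groups is identical the test is degenerate and returns p = 1 with a
#' warning.
#'
#' @param x,y numeric vectors for the two groups.
#' @return A list with \code{U}, \code{p}, and \code{method}.
#' @examples
#' rankSumTest(c(0.01, 0.02, 0.03), c(0.11, 0.12, 0.13))
#' @export
rankSumTest <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied across both groups; degenerate test, p = 1")
    return(list(U = nx * ny / 2, p = 1, method = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (nx + ny) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  # R's W is exactly this U: pairs x > y plus half the ties
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal-tie-corrected")
}

.checkGroup <- function(g, what) {
  if (!is.list(g) || length(g) < 3L ||
      !all(vapply(g, is, logical(1), "SampleFeatures")))
    stop(what, " must be a list of at least 3 SampleFeatures ",
         "(the rank-sum test is degenerate below that)")
}

#' Compare per-peak ratios between two groups
#'
#' For each canonical peak position, performs a two-sided Mann-Whitney
#' U test of the per-sample +/-1 bp peak ratios between the two groups, and
#' applies Benjamini-Hochberg adjustment across positions. Both raw and
#' adjusted p-values are reported.
#'
#' @param groupA,groupB lists of [SampleFeatures-class] (>= 3 samples
#'   each) sharing the same peak positions.
#' @param labels character(2) group display labels used in the
#'   \code{direction} column (defaults to the groups' stored labels, or
#'   "A"/"B").
#' @return A [S4Vectors::DataFrame] with one row per position: \code{U}
#'   (pairs a < b + half ties), \code{pValue}, \code{pAdj} (BH across
#'   positions), \code{direction} (which group has the larger median, or
#'   "tie") and \code{method}.
#' @seealso [rankSumTest()], [compareCend()]
#' @export
comparePeakRatios <- function(groupA, groupB, labels = NULL) {
  .checkGroup(groupA, "groupA")
  .checkGroup(groupB, "groupB")
  posA <- names(groupA[[1]]@peakRatios)
  if (!all(vapply(c(groupA, groupB),
                  function(s) identical(names(s@peakRatios), posA),
                  logical(1))))
    stop("all samples must share the same peak positions")
  if (is.null(labels)) {
    la <- unique(vapply(groupA, function(s) s@group, character(1)))
    lb <- unique(vapply(groupB, function(s) s@group, character(1)))
    labels <- c(if (length(la) == 1L && !is.na(la)) la else "A",
                if (length(lb) == 1L && !is.na(lb)) lb else "B")
  }
  matA <- vapply(groupA, function(s) s@peakRatios,
                 numeric(length(posA)))
  matB <- vapply(groupB, function(s) s@peakRatios,
                 numeric(length(posA)))
  matA <- matrix(matA, nrow = length(posA))
  matB <- matrix(matB, nrow = length(posA))
  res <- lapply(seq_along(posA), function(i) {
    r <- withCallingHandlers(
      rankSumTest(matA[i, ], matB[i, ]),
      warning = function(w) invokeRestart("muffleWarning"))
    mA <- stats::median(matA[i, ]); mB <- stats::median(matB[i, ])
    dir <- if (mA > mB) paste0(labels[1], ">", labels[2])
           else if (mB > mA) paste0(labels[2], ">", labels[1])
           else "tie"
    list(U = r$U, p = r$p, dir = dir, method = r$method)
  })
  out <- DataFrame(
    position = as.integer(posA),
    U = vapply(res, `[[`, numeric(1), "U"),
    pValue = vapply(res, `[[`, numeric(1), "p"),
    direction = vapply(res, `[[`, character(1), "dir"),
    method = vapply(res, `[[`, character(1), "method"))
  out$pAdj <- stats::p.adjust(out$pValue, method = "BH")
  out <- out[, c("position", "U", "pValue", "pAdj", "direction", "method")]
  metadata(out) <- list(labels = labels, nA = length(groupA),
                        nB = length(groupB), adjust = "BH")
  out
}

#' Compare C-end preference between two groups
#'
#' Default mode pairs by fragment size: for every size in the shared
#' occupied set, the group means of the per-sample C-end fractions are
#' paired and a two-sided paired t-test is run across sizes. The
#' alternative \code{"per_sample"} mode reduces each sample to its
#' end-count-weighted mean C-end fraction and runs an unpaired Welch test
#' across samples.
#'
#' Constant pairwise differences make the paired t statistic degenerate
#' (zero variance); this is guarded: the test returns p = 0 (p = 1 when the
#' constant is zero) with a warning.
#'
#' @param groupA,groupB lists of [SampleFeatures-class] whose C-end tables
#'   were computed with a reference.
#' @param mode \code{"paired_by_size"} (default) or \code{"per_sample"}.
#' @param labels character(2) display labels, as in [comparePeakRatios()].
#' @return A list with \code{statistic} (t), \code{pValue},
#'   \code{meanDiff} (mean of A - B), \code{direction}, \code{n} (paired
#'   sizes or samples), and \code{mode}.
#' @seealso [comparePeakRatios()]
#' @export
compareCend <- function(groupA, groupB,
                        mode = c("paired_by_size", "per_sample"),
                        labels = c("A", "B")) {
  mode <- match.arg(mode)
  .checkGroup(groupA, "groupA")
  .checkGroup(groupB, "groupB")
  direction <- function(d) {
    if (d > 0) paste0(labels[1], ">", labels[2])
    else if (d < 0) paste0(labels[2], ">", labels[1]) else "tie"
  }
  if (mode == "paired_by_size") {
    groupMeans <- function(g) {
      tabs <- lapply(g, function(s) s@cend)
      if (any(vapply(tabs, nrow, integer(1)) == 0L))
        stop("every sample needs a non-empty C-end table ",
             "(was extractFeatures run with a reference?)")
      long <- do.call(rbind, tabs)
      out <- tapply(long$cFrac, long$size, mean)
      stats::setNames(as.numeric(out), names(out))
    }
    mA <- groupMeans(groupA)
    mB <- groupMeans(groupB)
    shared <- intersect(names(mA), names(mB))
    if (length(shared) < 2L)
      stop("fewer than 2 shared fragment sizes between groups")
    if (length(shared) < 10L)
      warning("only ", length(shared), " shared sizes; the paired test ",
              "is designed for >= 10")
    d <- mA[shared] - mB[shared]
    if (stats::sd(d) == 0) {
      warning("constant pairwise differences; degenerate paired t-test")
      p <- if (mean(d) == 0) 1 else 0
      tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else {
      tt <- stats::t.test(mA[shared], mB[shared], paired = TRUE)
      p <- tt$p.value
      tstat <- unname(tt$statistic)
    }
    list(statistic = tstat, pValue = p, meanDiff = mean(d),
         direction = direction(mean(d)), n = length(shared), mode = mode)
  } else {
    sampleMean <- function(s) {
      if (nrow(s@cend) == 0L)
        stop("every sample needs a non-empty C-end table")
      stats::weighted.mean(s@cend$cFrac, s@cend$n)
    }
    a <- vapply(groupA, sampleMean, numeric(1))
    b <- vapply(groupB, sampleMean, numeric(1))
    tt <- stats::t.test(a, b)
    list(statistic = unname(tt$statistic), pValue = tt$p.value,
         meanDiff = mean(a) - mean(b),
         direction = direction(mean(a) - mean(b)),
         n = length(a) + length(b), mode = mode)
  }
}

#' Read a cohort sample manifest
#'
#' Reads a tab-separated manifest with columns \code{sample_id},
#' \code{group}, \code{bed_path} and optionally \code{fasta_path}, as
#' consumed by the command-line interface.
#'
#' @param path manifest TSV path.
#' @return A data.frame.
#' @export
readSampleManifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "group", "bed_path")
  missing <- setdiff(needed, names(m))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  m
}
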