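#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a SizeProfile from raw counts
#'
#' @param counts integer counts, one bin per size in \code{[lo, hi]}.
#' @param lo,hi inclusive size bounds in bp.
#' @return A [SizeProfile-class].
#' @export
sizeProfile <- function(counts, lo = 30L, hi = 800L) {
  counts <- as.integer(counts)
  new("SizeProfile", lo = as.integer(lo), hi = as.integer(hi),
      counts = counts, total = sum(counts))
}

#' Fragment-size histogram
#'
#' Tallies fragment lengths into 1-bp bins on the inclusive range
#' \code{[lo, hi]}; fragments outside the range contribute neither to the
#' counts nor to the total, so the +/-1 bp peak-ratio proxy is a fraction of
#' in-range fragments.
#'
#' @param x a [FragmentSet-class] or a numeric vector of fragment lengths.
#' @param lo,hi inclusive size bounds in bp (defaults 30 and 800, spanning
#'   the tetra-nucleosome peak with margin).
#' @return A [SizeProfile-class].
#' @examples
#' p <- sizeHistogram(c(167, 167, 167))
#' peakRatio(p, 167)
#' @rdname sizeHistogram
#' @export
setMethod("sizeHistogram", "numeric", function(x, lo = 30L, hi = 800L) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo >= hi) stop("lo must be below hi")
  lens <- as.integer(round(x))
  lens <- lens[!is.na(lens) & lens >= lo & lens <= hi]
  counts <- tabulate(lens - lo + 1L, nbins = hi - lo + 1L)
  sizeProfile(counts, lo, hi)
})

#' @rdname sizeHistogram
#' @export
setMethod("sizeHistogram", "FragmentSet", function(x, lo = 30L, hi = 800L) {
  sizeHistogram(as.numeric(width(x@fragments)), lo, hi)
})

#' @rdname accessors
setMethod("profileCounts", "SizeProfile", function(x)
  stats::setNames(x@counts, as.character(x@lo:x@hi)))

#' @rdname accessors
setMethod("profileFreq", "SizeProfile", function(x) {
  if (x@total == 0L) stats::setNames(rep(0, length(x@counts)),
                                     as.character(x@lo:x@hi))
  else profileCounts(x) / x@total
})

#' @rdname accessors
setMethod("profileRange", "SizeProfile", function(x) c(x@lo, x@hi))

#' @rdname accessors
setMethod("profileTotal", "SizeProfile", function(x) x@total)

setMethod("show", "SizeProfile", function(object) {
  cat("SizeProfile [", object@lo, ", ", object@hi, "] bp: ",
      object@total, " fragments", sep = "")
  if (object@total > 0L) {
    mode <- which.max(object@counts) + object@lo - 1L
    cat(", modal size ", mode, " bp", sep = "")
  }
  cat("\n")
  invisible(object)
})

# centered moving average of width 3; edges average the available bins
.smooth3 <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  s <- (c(v[-1], 0) + v + c(0, v[-n]))
  s[1] <- (v[1] + v[2]) / 2
  s[n] <- (v[n - 1] + v[n]) / 2
  s[2:(n - 1)] <- s[2:(n - 1)] / 3
  s
}

# strict local maxima of a smoothed vector, plateau-aware: a run of equal
# values that jointly exceeds its distinct neighbours is one maximum,
# placed at the run's highest raw value (smoothing flattens an isolated
# spike into a plateau); remaining ties resolve to the lowest size
.localMaxima <- function(s, raw = s) {
  r <- rle(s)
  k <- length(r$values)
  if (k == 0L) return(integer(0))
  firstIdx <- cumsum(c(1L, r$lengths[-k]))
  out <- integer(0)
  for (i in seq_len(k)) {
    leftOk <- i > 1L && r$values[i] > r$values[i - 1L]
    rightOk <- i < k && r$values[i] > r$values[i + 1L]
    if (leftOk && rightOk) {
      run <- firstIdx[i]:(firstIdx[i] + r$lengths[i] - 1L)
      out <- c(out, run[which.max(raw[run])])
    }
  }
  out
}

# prominence: height above the higher of the two flanking troughs, walking
# outward until the profile rises above the peak or the bounds are hit
.prominence <- function(s, i) {
  h <- s[i]
  left <- h
  j <- i
  while (j > 1L) {
    j <- j - 1L
    if (s[j] > h) break
    left <- min(left, s[j])
  }
  right <- h
  j <- i
  while (j < length(s)) {
    j <- j + 1L
    if (s[j] > h) break
    right <- min(right, s[j])
  }
  h - max(left, right)
}

# half-height width of the smoothed profile around bin index i, walking
# outward until the profile drops below half the apex (or the bounds)
.halfHeightWidth <- function(s, i) {
  half <- s[i] / 2
  l <- i
  while (l > 1L && s[l - 1L] >= half) l <- l - 1L
  r <- i
  while (r < length(s) && s[r + 1L] >= half) r <- r + 1L
  r - l + 1L
}

# Refine a detected peak position by a count-weighted quadratic fit to
# log(counts) around the local-maximum bin. For a discretized Gaussian
# component the log-counts are exactly quadratic in size (truncation only
# removes points), so the fitted vertex recovers the mode with the
# statistical efficiency of a parametric fit rather than the bin-argmax.
# The window scales with the peak's own half-height width, so broad peaks
# get enough flank for a stable vertex while narrow neighbouring structure
# (e.g. sub-nucleosomal rungs) stays outside; a second pass drops gross
# outliers before refitting.
.refinePeak <- function(counts, sizes, bin, halfWindow) {
  sel <- which(sizes >= bin - halfWindow & sizes <= bin + halfWindow &
               counts > 0)
  if (length(sel) < 5L) return(as.numeric(bin))
  x <- sizes[sel] - bin
  y <- log(counts[sel])
  w <- counts[sel]
  fit <- try(stats::lm.wfit(cbind(1, x, x^2), y, w), silent = TRUE)
  if (inherits(fit, "try-error")) return(as.numeric(bin))
  keep <- abs(fit$residuals) <= 2
  if (sum(keep) >= 5L && any(!keep))
    fit <- stats::lm.wfit(cbind(1, x, x^2)[keep, , drop = FALSE],
                          y[keep], w[keep])
  a <- fit$coefficients[3]
  b <- fit$coefficients[2]
  if (!is.finite(a) || a >= 0) return(as.numeric(bin))
  vertex <- bin - b / (2 * a)
  if (abs(vertex - bin) > halfWindow) as.numeric(bin) else unname(vertex)
}

#' Peak-amplitude proxy: fraction of fragments within +/- halfwidth bp
#'
#' The quantitative peak-amplitude statistic used for cohort comparison:
#' the fraction of all in-range fragments whose length falls within
#' \code{center +/- halfwidth} bp.
#'
#' @param profile a [SizeProfile-class] with \code{profileTotal(profile) > 0}.
#' @param center peak size in bp; the window must lie inside the profile.
#' @param halfwidth window half-width in bp (default 1).
#' @return Fraction in [0, 1].
#' @examples
#' p <- sizeProfile(c(10, 20, 10, 60), lo = 166, hi = 169)
#' peakRatio(p, 167)  # 0.4
#' @export
peakRatio <- function(profile, center, halfwidth = 1L) {
  stopifnot(is(profile, "SizeProfile"))
  if (profile@total == 0L)
    stop("undefined ratio: profile has no in-range fragments")
  center <- as.integer(center); halfwidth <- as.integer(halfwidth)
  if (center - halfwidth < profile@lo || center + halfwidth > profile@hi)
    stop("window [", center - halfwidth, ", ", center + halfwidth,
         "] outside profile range [", profile@lo, ", ", profile@hi, "]")
  idx <- (center - halfwidth):(center + halfwidth) - profile@lo + 1L
  sum(profile@counts[idx]) / profile@total
}

#' Detect the major nucleosomal ladder peaks
#'
#' Finds local maxima of the 3-bp moving-average-smoothed frequency and
#' selects the nucleosomal ladder among them: the predominant (highest)
#' maximum first, then the strongest maxima at larger sizes, greedily,
#' subject to a pairwise separation of at least \code{minSeparation} bp and
#' at most \code{maxPeaks} peaks. Maxima below the predominant mode belong
#' to the sub-nucleosomal oscillation and are left to [findSubpeaks()].
#' Each retained peak's position is refined with a robust count-weighted
#' quadratic fit to the log-counts in a window scaled to the peak's
#' half-height width; the raw local-maximum bin is reported alongside.
#'
#' @param profile a [SizeProfile-class] with at least one fragment.
#' @param minSeparation minimum distance between reported peaks in bp
#'   (default 100, below the smallest inter-nucleosomal gap).
#' @param maxPeaks maximum number of peaks to report (default 4:
#'   mono- to tetra-nucleosome).
#' @param refine refine positions by local quadratic fit (default TRUE);
#'   with \code{FALSE} the reported position is the local-maximum bin.
#' @return A [S4Vectors::DataFrame] sorted by position with columns
#'   \code{position} (refined, bp), \code{bin} (local-maximum bin, bp),
#'   \code{ratio} (+/-1 bp proxy at the rounded position) and
#'   \code{prominence} (smoothed height above the flanking troughs).
#' @examples
#' p <- sizeHistogram(rep(c(167, 334), c(90, 10)), lo = 30, hi = 400)
#' findMajorPeaks(p)
#' @export
findMajorPeaks <- function(profile, minSeparation = 100L, maxPeaks = 4L,
                           refine = TRUE) {
  stopifnot(is(profile, "SizeProfile"))
  if (profile@total == 0L)
    stop("cannot detect peaks in an empty profile")
  sizes <- profile@lo:profile@hi
  f <- profile@counts / profile@total
  s <- .smooth3(f)
  cand <- .localMaxima(s, f)
  if (!length(cand)) {
    return(DataFrame(position = numeric(0), bin = integer(0),
                     ratio = numeric(0), prominence = numeric(0)))
  }
  ## the ladder is searched upward from the predominant mode: the first
  ## peak is the global maximum, and additional ladder peaks are the
  ## strongest maxima at larger sizes (the sub-nucleosomal oscillation
  ## below the predominant mode is findSubpeaks' territory)
  ord <- cand[order(-s[cand], sizes[cand])]
  picked <- ord[1]
  for (i in ord[-1]) {
    if (length(picked) >= maxPeaks) break
    if (sizes[i] > sizes[picked[1]] &&
        all(abs(sizes[i] - sizes[picked]) >= minSeparation))
      picked <- c(picked, i)
  }
  picked <- picked[order(sizes[picked])]
  bins <- sizes[picked]
  pos <- if (refine) {
    vapply(picked, function(i) {
      sigmaHat <- .halfHeightWidth(s, i) / 2.355
      hw <- min(min(50L, as.integer(minSeparation) %/% 2L),
                max(6L, as.integer(round(1.5 * sigmaHat))))
      .refinePeak(profile@counts, sizes, sizes[i], hw)
    }, numeric(1))
  } else as.numeric(bins)
  ratio <- vapply(pos, function(p) {
    c0 <- as.integer(round(p))
    if (c0 - 1L < profile@lo || c0 + 1L > profile@hi) NA_real_
    else peakRatio(profile, c0, 1L)
  }, numeric(1))
  prom <- vapply(picked, function(i) .prominence(s, i), numeric(1))
  DataFrame(position = pos, bin = bins, ratio = ratio, prominence = prom)
}

#' Detect the 10-bp periodic sub-nucleosomal subpeaks
#'
#' Finds strict local maxima of the 3-bp-smoothed frequency inside the
#' sub-nucleosomal window (default 40-160 bp, covering the 50-153 bp
#' oscillation range). Equal-height adjacent bins resolve to the lower size.
#' A maximum closer than \code{minPeriod} bp to a larger retained maximum is
#' suppressed, so reported subpeaks are at least one ladder period apart.
#'
#' @param profile a [SizeProfile-class].
#' @param window integer(2), inclusive detection window in bp.
#' @param minPeriod minimum spacing between subpeaks in bp (default 8,
#'   just under the ~10-bp intra-nucleosomal cleavage period).
#' @param maxPeriod nominal upper period in bp; recorded with the call for
#'   interpretation but not used to filter maxima.
#' @return A [S4Vectors::DataFrame] with ascending integer \code{position},
#'   the +/-1 bp \code{ratio}, and \code{prominence}. A flat profile yields
#'   zero rows.
#' @examples
#' s <- 40:160
#' p <- sizeProfile(round(1000 * (1 + cos(2 * pi * s / 10))), 40, 160)
#' findSubpeaks(p)$position
#' @export
findSubpeaks <- function(profile, window = c(40L, 160L), minPeriod = 8L,
                         maxPeriod = 12L) {
  stopifnot(is(profile, "SizeProfile"))
  window <- as.integer(window)
  if (window[1] < profile@lo || window[2] > profile@hi)
    stop("window must lie within the profile range")
  sizes <- profile@lo:profile@hi
  f <- if (profile@total > 0L) profile@counts / profile@total
       else as.numeric(profile@counts)
  s <- .smooth3(f)
  cand <- .localMaxima(s, f)
  cand <- cand[sizes[cand] >= window[1] & sizes[cand] <= window[2]]
  if (!length(cand)) {
    return(DataFrame(position = integer(0), ratio = numeric(0),
                     prominence = numeric(0)))
  }
  ord <- cand[order(-s[cand], sizes[cand])]
  picked <- integer(0)
  for (i in ord) {
    if (all(abs(sizes[i] - sizes[picked]) >= minPeriod))
      picked <- c(picked, i)
  }
  picked <- picked[order(sizes[picked])]
  pos <- sizes[picked]
  ratio <- vapply(pos, function(p) {
    if (p - 1L < profile@lo || p + 1L > profile@hi) NA_real_
    else peakRatio(profile, p, 1L)
  }, numeric(1))
  prom <- vapply(picked, function(i) .prominence(s, i), numeric(1))
  DataFrame(position = pos, ratio = ratio, prominence = prom)
}

#' Decompose fragments into nucleosome-order proportions
#'
#' Classifies fragment lengths into mono- (<= first boundary), di-, tri-
#' and tetra-nucleosome (last boundary to \code{upper}) classes and returns
#' the class fractions over classified fragments; fragments above
#' \code{upper} are excluded. The default cuts 250/450/650/800 bp sit in
#' the valleys between the ladder peaks.
#'
#' @param x a [FragmentSet-class] or numeric fragment lengths.
#' @param boundaries three strictly increasing cut sizes in bp.
#' @param upper upper size limit in bp.
#' @return A [NucleosomeProportions-class].
#' @examples
#' nucleosomeProportions(c(100, 100, 300, 500, 700))
#' @rdname nucleosomeProportions
#' @export
setMethod("nucleosomeProportions", "numeric",
  function(x, boundaries = c(250, 450, 650), upper = 800) {
    boundaries <- as.numeric(boundaries)
    if (length(boundaries) != 3L || any(diff(boundaries) <= 0) ||
        boundaries[3] >= upper)
      stop("boundaries must be 3 strictly increasing cuts below upper")
    lens <- x[!is.na(x)]
    nExcluded <- sum(lens > upper)
    lens <- lens[lens <= upper]
    if (!length(lens))
      stop("undefined proportions: no classifiable fragments")
    cls <- findInterval(lens, c(boundaries, upper),
                        left.open = TRUE) + 1L  # 1=mono .. 4=tetra
    tab <- tabulate(cls, nbins = 4L)
    new("NucleosomeProportions",
        props = stats::setNames(tab / length(lens),
                                c("mono", "di", "tri", "tetra")),
        boundaries = boundaries, upper = as.numeric(upper),
        nClassified = length(lens), nExcluded = as.integer(nExcluded))
  })

#' @rdname nucleosomeProportions
#' @export
setMethod("nucleosomeProportions", "FragmentSet",
  function(x, boundaries = c(250, 450, 650), upper = 800) {
    nucleosomeProportions(as.numeric(width(x@fragments)), boundaries,
                          upper)
  })

#' @rdname accessors
setMethod("proportions", "NucleosomeProportions", function(x) x@props)

setMethod("show", "NucleosomeProportions", function(object) {
  cat("NucleosomeProportions (cuts ",
      paste(object@boundaries, collapse = "/"), "/", object@upper,
      " bp, n = ", object@nClassified, ")\n", sep = "")
  cat(paste(sprintf("  %s: %.1f%%", names(object@props),
                    100 * object@props), collapse = "\n"), "\n")
  invisible(object)
})

#' Canonical subpeak query positions for cohort work
#'
#' The fixed sub-nucleosomal positions at which per-sample +/-1 bp peak
#' ratios are evaluated, so samples are directly comparable: the
#' eleven-position set P50...P153 (default) or the ten-position set that
#' omits 144 bp (a plateau rather than a peak in the healthy human
#' profile).
#'
#' @param set \code{"eleven"} or \code{"ten"}.
#' @return Integer positions in bp.
#' @examples
#' canonicalPeakPositions()
#' @export
canonicalPeakPositions <- function(set = c("eleven", "ten")) {
  set <- match.arg(set)
  p <- c(50L, 60L, 70L, 81L, 91L, 102L, 111L, 122L, 134L, 144L, 153L)
  if (set == "ten") p[p != 144L] else p
}

#' Write a SizeProfile and peak tables as TSV
#'
#' @param profile a [SizeProfile-class].
#' @param path output TSV path (columns size, count).
#' @return \code{path}, invisibly.
#' @export
writeSizeProfileTsv <- function(profile, path) {
  stopifnot(is(profile, "SizeProfile"))
  utils::write.table(
    data.frame(size = profile@lo:profile@hi, count = profile@counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
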