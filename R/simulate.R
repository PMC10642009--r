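#' @include AllClasses.R reference.R
NULL

# draw n lengths from a discretized Gaussian truncated to [lo, hi]
.rTruncRoundNorm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(integer(0))
  if (sd <= 0) return(rep.int(as.integer(mean), n))
  a <- stats::pnorm(lo - 0.5, mean, sd)
  b <- stats::pnorm(hi + 0.5, mean, sd)
  u <- stats::runif(n, a, b)
  x <- as.integer(round(stats::qnorm(u, mean, sd)))
  pmin.int(pmax.int(x, as.integer(lo)), as.integer(hi))
}

# lower truncation of the mono-nucleosome component: just above the
# sub-nucleosomal ladder (one subpeak-detector period above the last rung)
# so the last rung remains a local maximum, or mode - 40 without a ladder
.monoFloor <- function(preset) {
  if (length(preset@subpeakPositions))
    max(preset@subpeakPositions) + 8L
  else
    preset@nucModes[1] - 40L
}

#' Simulate cfDNA fragments from a generative preset
#'
#' Draws \code{n} fragments from the nucleosome-ladder mixture of a
#' [SimPreset-class] and places each on the reference so that the reference
#' base at both 5' ends (the Watson end at the left coordinate and, on the
#' complementary strand, the Crick end at the right coordinate) matches a
#' base drawn independently from the preset's 5'-end distribution. Placement
#' is by rejection sampling over uniformly drawn positions, which keeps the
#' genome composition and the end preference independently controllable.
#'
#' Per fragment: (i) a nucleosome order is drawn from \code{nucWeights};
#' (ii) a mono-nucleosome fragment falls with probability
#' \code{subpeakWeight} on the sub-nucleosomal ladder (uniform rung plus
#' rounded Gaussian jitter), otherwise on a discretized Gaussian at the mono
#' mode truncated to a subpeak-free floor; higher orders draw a rounded
#' Gaussian at their mode; (iii) both 5'-end target bases and a uniform
#' strand are drawn; (iv) the fragment is placed by rejection.
#'
#' @param preset a [SimPreset-class].
#' @param n number of fragments (>= 0).
#' @param reference reference sequence (DNAStringSet / FASTA path); every
#'   contig must be longer than the largest fragment plus a 100 bp margin.
#' @param seed integer seed; identical arguments give identical output.
#' @param sampleId sample identifier for the resulting [FragmentSet-class].
#' @param maxRounds rejection-sampling round cap (safety valve).
#' @return A [FragmentSet-class]; fragment metadata columns record the
#'   generation labels \code{nucOrder} (1-4), \code{subpeak} (logical),
#'   \code{watsonBase} and \code{crickBase}.
#' @examples
#' ref <- buildReference(50000, seed = 1)
#' fs <- simulateFragments(builtinPreset("human_healthy"), 500, ref,
#'                         seed = 7)
#' fs
#' @export
simulateFragments <- function(preset, n, reference, seed = NULL,
                              sampleId = preset@name, maxRounds = 10000L) {
  stopifnot(is(preset, "SimPreset"))
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  ref <- .asReference(reference)
  codes <- .referenceCodes(ref)
  widths <- Biostrings::width(ref)
  prov <- list(source = "simulateFragments", preset = preset@name,
               n = n, seed = seed)

  if (n == 0L) {
    gr <- GRanges(seqlengths = stats::setNames(widths, names(ref)))
    mcols(gr) <- S4Vectors::DataFrame(nucOrder = integer(0),
                                      subpeak = logical(0),
                                      watsonBase = character(0),
                                      crickBase = character(0))
    return(new("FragmentSet", sampleId = sampleId, fragments = gr,
               provenance = prov))
  }

  if (!is.null(seed)) set.seed(as.integer(seed))

  ## nucleosome order and fragment length
  ord <- sample.int(4L, n, replace = TRUE, prob = preset@nucWeights)
  isSub <- ord == 1L & length(preset@subpeakPositions) > 0L &
    stats::runif(n) < preset@subpeakWeight
  len <- integer(n)
  iSub <- which(isSub)
  if (length(iSub)) {
    rung <- preset@subpeakPositions[
      sample.int(length(preset@subpeakPositions), length(iSub),
                 replace = TRUE)]
    jit <- as.integer(round(stats::rnorm(length(iSub), 0,
                                         preset@subpeakJitterSd)))
    len[iSub] <- pmax.int(rung + jit, 20L)
  }
  iMono <- which(ord == 1L & !isSub)
  if (length(iMono)) {
    len[iMono] <- .rTruncRoundNorm(length(iMono), preset@nucModes[1],
                                   preset@nucSds[1], .monoFloor(preset),
                                   preset@nucModes[1] + 40L)
  }
  for (k in 2:4) {
    ik <- which(ord == k)
    if (length(ik)) {
      if (preset@nucSds[k] <= 0) {
        len[ik] <- preset@nucModes[k]
      } else {
        len[ik] <- pmax.int(as.integer(round(
          stats::rnorm(length(ik), preset@nucModes[k], preset@nucSds[k]))),
          20L)
      }
    }
  }

  if (any(widths < max(len) + 100L))
    stop("reference contigs must exceed the largest fragment (",
         max(len), " bp) plus a 100 bp margin")

  ## 5'-end target bases (codes in A,T,C,G order) and strand
  bWatson <- sample.int(4L, n, replace = TRUE, prob = preset@endBaseProbs)
  bCrick <- sample.int(4L, n, replace = TRUE, prob = preset@endBaseProbs)
  str <- sample(c("+", "-"), n, replace = TRUE)
  # Crick 5' base is read on the minus strand, so the plus-strand reference
  # base at the right coordinate must be its complement
  endTarget <- .COMP[bCrick]

  ## contig assignment (weighted by length) and base availability check
  contig <- if (length(ref) == 1L) rep.int(1L, n)
            else sample.int(length(ref), n, replace = TRUE, prob = widths)
  needed <- sort(unique(c(bWatson, endTarget)))
  for (ci in unique(contig)) {
    have <- unique(codes[[ci]])
    miss <- setdiff(needed, have)
    if (length(miss))
      stop("simulation error: reference contig '", names(ref)[ci],
           "' lacks base ", paste(.BASES[miss], collapse = ", "))
  }

  ## rejection sampling over positions until both end bases match
  startPos <- integer(n)
  pending <- seq_len(n)
  round <- 0L
  while (length(pending) && round < maxRounds) {
    round <- round + 1L
    s <- 1L + as.integer(floor(stats::runif(length(pending)) *
                               (widths[contig[pending]] - len[pending] + 1L)))
    e <- s + len[pending] - 1L
    ok <- logical(length(pending))
    for (ci in unique(contig[pending])) {
      sel <- contig[pending] == ci
      cc <- codes[[ci]]
      ok[sel] <- cc[s[sel]] == bWatson[pending[sel]] &
                 cc[e[sel]] == endTarget[pending[sel]]
    }
    startPos[pending[ok]] <- s[ok]
    pending <- pending[!ok]
  }
  if (length(pending))
    stop("simulation error: rejection sampling exceeded ", maxRounds,
         " rounds with ", length(pending), " fragments unplaced")

  gr <- GRanges(seqnames = factor(names(ref)[contig], levels = names(ref)),
                ranges = IRanges(start = startPos,
                                 end = startPos + len - 1L),
                strand = str,
                seqlengths = stats::setNames(widths, names(ref)))
  mcols(gr) <- S4Vectors::DataFrame(nucOrder = ord, subpeak = isSub,
                                    watsonBase = .BASES[bWatson],
                                    crickBase = .BASES[bCrick])
  new("FragmentSet", sampleId = sampleId, fragments = gr,
      provenance = prov)
}
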