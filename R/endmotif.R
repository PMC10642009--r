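#' @include AllClasses.R AllGenerics.R reference.R
NULL

# Per-fragment end coordinates on the reference code vectors, split by
# contig. Returns, for each contig, integer matrices of Watson motif
# positions (start .. start+k-1) handled lazily by the callers.
.splitByContig <- function(frags, ref) {
  gr <- frags@fragments
  chr <- as.character(seqnames(gr))
  bad <- setdiff(unique(chr), names(ref))
  if (length(bad))
    stop("fragments reference unknown contig(s): ",
         paste(bad, collapse = ", "))
  split(seq_along(gr), factor(chr, levels = names(ref)))
}

#' Extract 5' end-motif base content against a reference
#'
#' For every fragment, up to two k-mer end motifs are read from the
#' reference: the Watson end, \code{reference[start .. start+k-1]}, and the
#' Crick end, the reverse complement of \code{reference[end-k+1 .. end]}
#' (both 5' ends of the double-stranded molecule). Motifs whose window runs
#' off the contig or contains an ambiguous base are skipped and counted.
#' Per-position base proportions are returned in A,T,C,G order.
#'
#' Motifs are read from the reference at the fragment coordinates, not from
#' read bases, matching standard practice for aligned cfDNA and making
#' simulated fragments (which carry no read sequence) analyzable.
#'
#' @param frags a [FragmentSet-class].
#' @param reference DNAStringSet / FASTA path covering the fragments.
#' @param k motif length (default 8).
#' @param bothEnds tally both ends of every fragment (default TRUE); with
#'   \code{FALSE} only the 5' end given by the fragment's strand is used
#'   (start for '+', end for '-').
#' @return An [EndMotifMatrix-class].
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ACCCAGGTTAAGGCCAATTG"))
#' fs <- FragmentSet(GenomicRanges::GRanges("chr1:2-19"))
#' motifProps(extractEndMotifs(fs, ref))
#' @export
extractEndMotifs <- function(frags, reference, k = 8L, bothEnds = TRUE) {
  stopifnot(is(frags, "FragmentSet"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  ref <- .asReference(reference)
  codes <- .referenceCodes(ref)
  idxByContig <- .splitByContig(frags, ref)
  gr <- frags@fragments

  counts <- matrix(0L, nrow = k, ncol = 4L,
                   dimnames = list(position = seq_len(k), base = .BASES))
  nEnds <- 0L
  nSkipped <- 0L
  useWatson <- bothEnds | as.character(strand(gr)) != "-"
  useCrick <- bothEnds | as.character(strand(gr)) == "-"

  for (ci in seq_along(codes)) {
    idx <- idxByContig[[ci]]
    if (!length(idx)) next
    cc <- codes[[ci]]
    clen <- length(cc)
    st <- start(gr)[idx]
    en <- end(gr)[idx]

    wIdx <- idx[useWatson[idx]]
    wSt <- st[useWatson[idx]]
    wOk <- wSt + k - 1L <= clen
    nSkipped <- nSkipped + sum(!wOk)
    wSt <- wSt[wOk]
    if (length(wSt)) {
      m <- vapply(seq_len(k), function(j) cc[wSt + j - 1L],
                  integer(length(wSt)))
      m <- matrix(m, ncol = k)
      hasN <- rowSums(m == 0L) > 0L
      nSkipped <- nSkipped + sum(hasN)
      m <- m[!hasN, , drop = FALSE]
      nEnds <- nEnds + nrow(m)
      for (j in seq_len(k))
        counts[j, ] <- counts[j, ] + tabulate(m[, j], nbins = 4L)
    }

    cEn <- en[useCrick[idx]]
    cOk <- cEn - k + 1L >= 1L
    nSkipped <- nSkipped + sum(!cOk)
    cEn <- cEn[cOk]
    if (length(cEn)) {
      m <- vapply(seq_len(k), function(j) cc[cEn - j + 1L],
                  integer(length(cEn)))
      m <- matrix(m, ncol = k)
      hasN <- rowSums(m == 0L) > 0L
      nSkipped <- nSkipped + sum(hasN)
      m <- m[!hasN, , drop = FALSE]
      nEnds <- nEnds + nrow(m)
      for (j in seq_len(k))
        counts[j, ] <- counts[j, ] + tabulate(.COMP[m[, j]], nbins = 4L)
    }
  }

  props <- if (nEnds > 0L) counts / nEnds else counts * 0
  new("EndMotifMatrix", k = k, props = props, counts = counts,
      nEnds = as.integer(nEnds), nSkipped = as.integer(nSkipped))
}

#' @rdname accessors
setMethod("motifProps", "EndMotifMatrix", function(x) x@props)

#' @rdname accessors
setMethod("motifCounts", "EndMotifMatrix", function(x) x@counts)

#' @rdname accessors
setMethod("nEnds", "EndMotifMatrix", function(x) x@nEnds)

setMethod("show", "EndMotifMatrix", function(object) {
  cat("EndMotifMatrix: k = ", object@k, ", ", object@nEnds,
      " ends tallied", sep = "")
  if (object@nSkipped > 0L) cat(" (", object@nSkipped, " skipped)", sep = "")
  cat("\n")
  if (object@nEnds > 0L) {
    cat("  position-1 base content (A/T/C/G): ",
        paste(sprintf("%.3f", object@props[1, ]), collapse = "/"), "\n",
        sep = "")
  }
  invisible(object)
})

#' C-end fraction stratified by fragment size
#'
#' Groups fragments by exact length within \code{[lo, hi]} bp and reports,
#' per size, the fraction of 5' ends whose first base is C. Sizes with no
#' tallied ends are absent from the result rather than reported as zero.
#'
#' @param frags a [FragmentSet-class].
#' @param reference DNAStringSet / FASTA path covering the fragments.
#' @param lo,hi inclusive size range in bp (default 50-250, the first major
#'   peak).
#' @param bothEnds tally both fragment ends (default TRUE).
#' @return A data.frame with columns \code{size}, \code{n} (ends) and
#'   \code{cFrac}, sorted by size.
#' @seealso [extractEndMotifs()]
#' @export
cEndBySize <- function(frags, reference, lo = 50L, hi = 250L,
                       bothEnds = TRUE) {
  stopifnot(is(frags, "FragmentSet"))
  ref <- .asReference(reference)
  codes <- .referenceCodes(ref)
  idxByContig <- .splitByContig(frags, ref)
  gr <- frags@fragments
  lens <- width(gr)
  useWatson <- bothEnds | as.character(strand(gr)) != "-"
  useCrick <- bothEnds | as.character(strand(gr)) == "-"

  sizeAll <- integer(0)
  isC <- logical(0)
  for (ci in seq_along(codes)) {
    idx <- idxByContig[[ci]]
    if (!length(idx)) next
    idx <- idx[lens[idx] >= lo & lens[idx] <= hi]
    if (!length(idx)) next
    cc <- codes[[ci]]
    wIdx <- idx[useWatson[idx]]
    if (length(wIdx)) {
      b <- cc[start(gr)[wIdx]]
      keep <- b != 0L
      sizeAll <- c(sizeAll, lens[wIdx][keep])
      isC <- c(isC, b[keep] == 3L)
    }
    cIdx <- idx[useCrick[idx]]
    if (length(cIdx)) {
      b <- .COMP[pmax(cc[end(gr)[cIdx]], 1L)] *
        (cc[end(gr)[cIdx]] != 0L)
      keep <- b != 0L
      sizeAll <- c(sizeAll, lens[cIdx][keep])
      isC <- c(isC, b[keep] == 3L)
    }
  }
  if (!length(sizeAll)) {
    return(data.frame(size = integer(0), n = integer(0),
                      cFrac = numeric(0)))
  }
  nBy <- tapply(isC, sizeAll, length)
  cBy <- tapply(isC, sizeAll, sum)
  sz <- as.integer(names(nBy))
  ord <- order(sz)
  data.frame(size = sz[ord], n = as.integer(nBy)[ord],
             cFrac = (as.numeric(cBy) / as.numeric(nBy))[ord])
}
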