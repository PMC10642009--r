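#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomicRanges GRanges seqnames strand start end width
#' @importFrom IRanges IRanges
NULL

# base ordering used throughout the package (probabilities, proportions,
# end tallies); note this is A,T,C,G -- not the alphabetical A,C,G,T
.BASES <- c("A", "T", "C", "G")

#' SimPreset: generative parameter set for the cfDNA fragment simulator
#'
#' Bundles every parameter of the synthetic cfDNA fragment model: the
#' nucleosome-ladder size mixture (mono/di/tri/tetra weights, modal sizes and
#' spreads), the sub-nucleosomal 10-bp ladder (positions, weight within the
#' mono component, jitter), the 5' end-base preference, and the base
#' composition used when building a matching synthetic reference.
#'
#' @slot name preset identifier.
#' @slot nucWeights numeric(4), mixture weights of the mono-, di-, tri- and
#'   tetra-nucleosome components; sums to 1.
#' @slot nucModes integer(4), modal fragment lengths in bp, strictly
#'   increasing (e.g. 167/333/527/719 for healthy human plasma).
#' @slot nucSds numeric(4), spreads in bp of the four components.
#' @slot subpeakPositions integer, sub-nucleosomal ladder positions in bp,
#'   all below \code{nucModes[1]}; may be empty.
#' @slot subpeakWeight numeric(1) in [0,1], probability that a
#'   mono-nucleosome fragment is drawn from the sub-nucleosomal ladder.
#' @slot subpeakJitterSd numeric(1), bp jitter around each ladder rung.
#' @slot endBaseProbs numeric(4), 5'-end base probabilities in A,T,C,G
#'   order; sums to 1. Applied independently to both fragment ends.
#' @slot genomeBaseProbs numeric(4), reference base composition (A,T,C,G).
#'
#' @seealso [simPreset()], [builtinPreset()], [simulateFragments()]
#' @exportClass SimPreset
setClass("SimPreset",
  representation(
    name = "character",
    nucWeights = "numeric",
    nucModes = "integer",
    nucSds = "numeric",
    subpeakPositions = "integer",
    subpeakWeight = "numeric",
    subpeakJitterSd = "numeric",
    endBaseProbs = "numeric",
    genomeBaseProbs = "numeric"
  )
)

.validProbs <- function(p, what, n = 4L) {
  if (length(p) != n)
    return(sprintf("%s must have length %d", what, n))
  if (any(!is.finite(p)) || any(p < 0))
    return(sprintf("%s must be finite and non-negative", what))
  if (abs(sum(p) - 1) > 1e-9)
    return(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)))
  NULL
}

setValidity("SimPreset", function(object) {
  msgs <- c(
    .validProbs(object@nucWeights, "nucWeights"),
    .validProbs(object@endBaseProbs, "endBaseProbs"),
    .validProbs(object@genomeBaseProbs, "genomeBaseProbs")
  )
  if (length(object@nucModes) != 4L || any(diff(object@nucModes) <= 0))
    msgs <- c(msgs, "nucModes must be 4 strictly increasing sizes")
  if (length(object@nucSds) != 4L || any(object@nucSds < 0))
    msgs <- c(msgs, "nucSds must be 4 non-negative spreads")
  if (length(object@subpeakPositions) &&
      any(object@subpeakPositions >= object@nucModes[1]))
    msgs <- c(msgs, "all subpeakPositions must lie below nucModes[1]")
  if (length(object@subpeakPositions) > 1L &&
      any(diff(object@subpeakPositions) <= 0))
    msgs <- c(msgs, "subpeakPositions must be strictly increasing")
  if (object@subpeakWeight < 0 || object@subpeakWeight > 1)
    msgs <- c(msgs, "subpeakWeight must be in [0, 1]")
  if (object@subpeakJitterSd < 0)
    msgs <- c(msgs, "subpeakJitterSd must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' FragmentSet: a collection of cfDNA fragments from one sample
#'
#' Wraps a [GenomicRanges::GRanges] of fragment intervals (1-based, closed;
#' fragment length equals the range width) together with the sample
#' identifier and a provenance record of where the fragments came from and
#' which filters were applied. Simulated fragments additionally carry their
#' generation labels (\code{nucOrder}, \code{subpeak}, \code{watsonBase},
#' \code{crickBase}) as metadata columns.
#'
#' @slot sampleId sample identifier.
#' @slot fragments GRanges of fragment intervals; strand is the strand of
#'   read 1 (or the simulated molecule), metadata columns hold per-fragment
#'   quality/generation annotations.
#' @slot provenance named list describing source path / generator and the
#'   active filter settings.
#'
#' @seealso [readFragmentsBam()], [readFragmentsBed()], [simulateFragments()]
#' @exportClass FragmentSet
setClass("FragmentSet",
  representation(
    sampleId = "character",
    fragments = "GRanges",
    provenance = "list"
  )
)

setValidity("FragmentSet", function(object) {
  msgs <- NULL
  if (length(object@sampleId) != 1L)
    msgs <- c(msgs, "sampleId must be a single string")
  if (length(object@fragments) && any(width(object@fragments) < 1L))
    msgs <- c(msgs, "all fragments must have positive length")
  if (length(msgs)) msgs else TRUE
})

#' SizeProfile: per-bp fragment-length histogram
#'
#' Integer counts of fragments at each 1-bp size bin on the inclusive range
#' \code{[lo, hi]}; fragments outside the range are excluded from both the
#' counts and the total, so frequencies sum to 1 whenever any fragment is in
#' range.
#'
#' @slot lo,hi inclusive size bounds in bp.
#' @slot counts integer vector of length \code{hi - lo + 1}.
#' @slot total integer, \code{sum(counts)}.
#'
#' @seealso [sizeHistogram()], [peakRatio()], [findMajorPeaks()],
#'   [findSubpeaks()]
#' @exportClass SizeProfile
setClass("SizeProfile",
  representation(lo = "integer", hi = "integer",
                 counts = "integer", total = "integer")
)

setValidity("SizeProfile", function(object) {
  msgs <- NULL
  if (object@lo >= object@hi)
    msgs <- c(msgs, "lo must be below hi")
  if (length(object@counts) != object@hi - object@lo + 1L)
    msgs <- c(msgs, "counts must have one bin per size in [lo, hi]")
  if (any(object@counts < 0L))
    msgs <- c(msgs, "counts must be non-negative")
  if (sum(object@counts) != object@total)
    msgs <- c(msgs, "total must equal sum(counts)")
  if (length(msgs)) msgs else TRUE
})

#' EndMotifMatrix: per-position base content of 5' fragment end motifs
#'
#' Position-by-base proportions of the k-mer sequences read from the
#' reference at the 5' ends of fragments (Watson end at the left fragment
#' coordinate; Crick end as the reverse complement at the right coordinate).
#' Columns follow the package's A,T,C,G order.
#'
#' @slot k motif length.
#' @slot props k x 4 matrix of base proportions per motif position.
#' @slot counts k x 4 matrix of raw base tallies.
#' @slot nEnds number of ends tallied.
#' @slot nSkipped ends skipped (motif window off the contig or containing N).
#'
#' @seealso [extractEndMotifs()]
#' @exportClass EndMotifMatrix
setClass("EndMotifMatrix",
  representation(k = "integer", props = "matrix", counts = "matrix",
                 nEnds = "integer", nSkipped = "integer")
)

setValidity("EndMotifMatrix", function(object) {
  msgs <- NULL
  if (!identical(dim(object@props), c(object@k, 4L)))
    msgs <- c(msgs, "props must be a k x 4 matrix")
  if (object@nEnds > 0L &&
      any(abs(rowSums(object@props) - 1) > 1e-9))
    msgs <- c(msgs, "each props row must sum to 1 when nEnds > 0")
  if (length(msgs)) msgs else TRUE
})

#' NucleosomeProportions: mono/di/tri/tetra size decomposition
#'
#' Fractions of fragments classified into the mono-, di-, tri- and
#' tetra-nucleosome size classes by fixed cut points; fragments above
#' \code{upper} are excluded, and the fractions sum to 1 over classified
#' fragments.
#'
#' @slot props named numeric(4): mono, di, tri, tetra fractions.
#' @slot boundaries numeric(3) cut sizes in bp (mono/di, di/tri, tri/tetra).
#' @slot upper numeric(1) upper size limit in bp.
#' @slot nClassified,nExcluded fragment counts inside/above the size range.
#'
#' @seealso [nucleosomeProportions()]
#' @exportClass NucleosomeProportions
setClass("NucleosomeProportions",
  representation(props = "numeric", boundaries = "numeric",
                 upper = "numeric", nClassified = "integer",
                 nExcluded = "integer")
)

setValidity("NucleosomeProportions", function(object) {
  msgs <- NULL
  if (length(object@props) != 4L)
    msgs <- c(msgs, "props must have length 4")
  if (object@nClassified > 0L && abs(sum(object@props) - 1) > 1e-9)
    msgs <- c(msgs, "props must sum to 1 over classified fragments")
  if (length(object@boundaries) != 3L || any(diff(object@boundaries) <= 0))
    msgs <- c(msgs, "boundaries must be 3 strictly increasing cut sizes")
  if (object@upper <= object@boundaries[3])
    msgs <- c(msgs, "upper must exceed the last boundary")
  if (length(msgs)) msgs else TRUE
})

#' SampleFeatures: per-sample fragmentomic feature vector
#'
#' The cohort-level summary of one sample: the +/-1 bp peak-ratio proxy
#' evaluated at a fixed set of canonical subpeak positions (so samples are
#' comparable), and the per-size C-end fractions over the mono-nucleosomal
#' size range.
#'
#' @slot sampleId sample identifier.
#' @slot group group label (e.g. "healthy" or "cancer"); may be NA.
#' @slot peakRatios named numeric, position (bp) -> fraction in [0,1].
#' @slot cend data.frame with columns size, n, cFrac (possibly empty when no
#'   reference was supplied).
#' @slot total number of in-range fragments the ratios are relative to.
#'
#' @seealso [extractFeatures()], [comparePeakRatios()], [compareCend()]
#' @exportClass SampleFeatures
setClass("SampleFeatures",
  representation(sampleId = "character", group = "character",
                 peakRatios = "numeric", cend = "data.frame",
                 total = "integer")
)

setValidity("SampleFeatures", function(object) {
  msgs <- NULL
  if (any(object@peakRatios < 0 | object@peakRatios > 1))
    msgs <- c(msgs, "peakRatios must lie in [0, 1]")
  if (nrow(object@cend) &&
      any(object@cend$cFrac < 0 | object@cend$cFrac > 1))
    msgs <- c(msgs, "cFrac values must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
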