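#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Standard accessor generics: \code{fragments()} returns the underlying
#' GRanges of a FragmentSet, \code{sampleId()} its identifier,
#' \code{provenance()} its source record, \code{fragmentLengths()} the
#' fragment lengths in bp, \code{profileCounts()}/\code{profileFreq()}/
#' \code{profileRange()}/\code{profileTotal()} the histogram content of a
#' SizeProfile, \code{motifProps()}/\code{motifCounts()}/\code{nEnds()} the
#' content of an EndMotifMatrix, and \code{proportions()} the class
#' fractions of a NucleosomeProportions.
#'
#' @param x an object of the documented class.
#' @return See the individual accessor descriptions.
#' @name accessors
#' @aliases fragments sampleId provenance fragmentLengths profileCounts
#'   profileFreq profileRange profileTotal motifProps motifCounts nEnds
#'   proportions peakRatios
NULL

#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("fragmentLengths", function(x) standardGeneric("fragmentLengths"))

#' @rdname accessors
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname accessors
#' @export
setGeneric("profileFreq", function(x) standardGeneric("profileFreq"))

#' @rdname accessors
#' @export
setGeneric("profileRange", function(x) standardGeneric("profileRange"))

#' @rdname accessors
#' @export
setGeneric("profileTotal", function(x) standardGeneric("profileTotal"))

#' @rdname accessors
#' @export
setGeneric("motifProps", function(x) standardGeneric("motifProps"))

#' @rdname accessors
#' @export
setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))

#' @rdname accessors
#' @export
setGeneric("nEnds", function(x) standardGeneric("nEnds"))

#' @rdname accessors
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))

#' @rdname accessors
#' @export
setGeneric("peakRatios", function(x) standardGeneric("peakRatios"))

#' @rdname sizeHistogram
#' @export
setGeneric("sizeHistogram",
  function(x, lo = 30L, hi = 800L) standardGeneric("sizeHistogram"))

#' @rdname nucleosomeProportions
#' @export
setGeneric("nucleosomeProportions",
  function(x, boundaries = c(250, 450, 650), upper = 800)
    standardGeneric("nucleosomeProportions"))
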