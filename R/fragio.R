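#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a FragmentSet
#'
#' Low-level constructor used by the readers and the simulator; fragments
#' are 1-based closed intervals (fragment length = interval width).
#'
#' @param fragments a GRanges of fragment intervals.
#' @param sampleId sample identifier.
#' @param provenance named list recording source and filter settings.
#' @return A [FragmentSet-class].
#' @export
FragmentSet <- function(fragments, sampleId = "sample",
                        provenance = list()) {
  new("FragmentSet", sampleId = sampleId, fragments = fragments,
      provenance = provenance)
}

#' @rdname accessors
setMethod("fragments", "FragmentSet", function(x) x@fragments)

#' @rdname accessors
setMethod("sampleId", "FragmentSet", function(x) x@sampleId)

#' @rdname accessors
setMethod("provenance", "FragmentSet", function(x) x@provenance)

#' @rdname accessors
setMethod("fragmentLengths", "FragmentSet",
          function(x) width(x@fragments))

#' @describeIn FragmentSet number of fragments
#' @param x a FragmentSet.
#' @export
setMethod("length", "FragmentSet", function(x) length(x@fragments))

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet '", object@sampleId, "': ",
      length(object@fragments), " fragments", sep = "")
  if (length(object@fragments)) {
    w <- width(object@fragments)
    cat(sprintf(" (median length %d bp, range %d-%d)",
                as.integer(stats::median(w)), min(w), max(w)))
  }
  cat("\n")
  src <- object@provenance$source
  if (!is.null(src)) cat("  source:", src, "\n")
  invisible(object)
})

#' Read cfDNA fragments from a paired-end BAM file
#'
#' Extracts one fragment per properly paired read pair, with the interval
#' spanning the outer mapped coordinates of the pair. Pairs are dropped when
#' either read has mapping quality below \code{mapqThreshold} or carries the
#' PCR/optical duplicate flag; secondary and supplementary alignments are
#' never used. Orphan reads that cannot be paired are skipped and counted in
#' the provenance record.
#'
#' @param path coordinate-sorted, indexed BAM file.
#' @param mapqThreshold pair-level MAPQ cutoff: a pair is kept only when
#'   both reads reach this mapping quality (default 30).
#' @param sampleId sample identifier (defaults to the file name).
#' @param keepDuplicates keep duplicate-flagged pairs (default FALSE).
#' @param coordinateDedup additionally collapse fragments identical in
#'   (chrom, start, end, strand) -- for inputs without duplicate flags
#'   (default FALSE).
#' @return A [FragmentSet-class]; metadata columns \code{mapqMin} (minimum
#'   of the pair) and \code{isDuplicate}.
#' @seealso [readFragmentsBed()]
#' @export
readFragmentsBam <- function(path, mapqThreshold = 30L,
                             sampleId = sub("\\.bam$", "", basename(path)),
                             keepDuplicates = FALSE,
                             coordinateDedup = FALSE) {
  if (!file.exists(path)) stop("BAM file not found: ", path)
  param <- Rsamtools::ScanBamParam(
    what = c("mapq", "flag"),
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  gp <- GenomicAlignments::readGAlignmentPairs(path, param = param)
  nRecords <- Rsamtools::countBam(path, param = param)$records
  nOrphan <- nRecords - 2L * length(gp)
  if (nOrphan > 0L)
    message(nOrphan, " proper-pair records could not be paired; skipped")

  m1 <- mcols(GenomicAlignments::first(gp))
  m2 <- mcols(GenomicAlignments::second(gp))
  mapqMin <- pmin(m1$mapq, m2$mapq)
  isDup <- bitwAnd(m1$flag, 1024L) > 0L | bitwAnd(m2$flag, 1024L) > 0L

  keep <- !is.na(mapqMin) & mapqMin >= mapqThreshold
  if (!keepDuplicates) keep <- keep & !isDup
  gr <- GenomicRanges::granges(gp[keep])
  mcols(gr) <- S4Vectors::DataFrame(mapqMin = mapqMin[keep],
                                    isDuplicate = isDup[keep])
  if (coordinateDedup) {
    gr <- gr[!duplicated(paste(seqnames(gr), start(gr), end(gr),
                               strand(gr)))]
  }
  FragmentSet(gr, sampleId = sampleId,
              provenance = list(source = path, format = "bam",
                                mapqThreshold = mapqThreshold,
                                keepDuplicates = keepDuplicates,
                                coordinateDedup = coordinateDedup,
                                nPairs = length(gp),
                                nOrphanRecords = nOrphan))
}

#' Read cfDNA fragments from a BED file
#'
#' Accepts BED3 and up; a missing strand column defaults to '+'. BED
#' intervals are 0-based half-open on disk and become 1-based closed ranges
#' in the [FragmentSet-class], so fragment length equals BED end - start.
#'
#' @param path BED file path.
#' @param sampleId sample identifier (defaults to the file name).
#' @return A [FragmentSet-class].
#' @seealso [writeFragmentsBed()], [readFragmentsBam()]
#' @export
readFragmentsBed <- function(path,
                             sampleId = sub("\\.bed$", "",
                                            basename(path))) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  prov <- list(source = path, format = "bed")
  if (file.size(path) == 0L) {
    return(FragmentSet(GRanges(), sampleId = sampleId, provenance = prov))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("BED parse error in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  bad <- which(width(gr) < 1L)
  if (length(bad))
    stop("BED parse error: end <= start at line ", bad[1], " of ", path)
  strand(gr)[strand(gr) == "*"] <- "+"
  FragmentSet(gr, sampleId = sampleId, provenance = prov)
}

#' Write a FragmentSet as BED6
#'
#' Writes one line per fragment (chrom, 0-based start, end, name = fragment
#' index, score = 0, strand). Output is byte-deterministic for a given
#' FragmentSet, so identical simulations give identical files.
#'
#' @param x a [FragmentSet-class].
#' @param path output BED path.
#' @return \code{path}, invisibly.
#' @seealso [readFragmentsBed()]
#' @export
writeFragmentsBed <- function(x, path) {
  stopifnot(is(x, "FragmentSet"))
  gr <- x@fragments
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,
                   end = end(gr),
                   name = if (length(gr)) paste0("frag", seq_along(gr))
                          else character(0),
                   score = if (length(gr)) 0L else integer(0),
                   strand = as.character(strand(gr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
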