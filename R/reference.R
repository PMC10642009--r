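#' @include AllClasses.R
NULL

# byte -> base code lookup (A/a=1, T/t=2, C/c=3, G/g=4, anything else 0).
# Soft-masked (lowercase) bases are treated as their uppercase base.
.CODE_TAB <- local({
  tab <- integer(256)
  tab[utf8ToInt("A") + 1L] <- 1L; tab[utf8ToInt("a") + 1L] <- 1L
  tab[utf8ToInt("T") + 1L] <- 2L; tab[utf8ToInt("t") + 1L] <- 2L
  tab[utf8ToInt("C") + 1L] <- 3L; tab[utf8ToInt("c") + 1L] <- 3L
  tab[utf8ToInt("G") + 1L] <- 4L; tab[utf8ToInt("g") + 1L] <- 4L
  tab
})

# complement in code space: A<->T, C<->G; N/other (0) stays 0
.COMP <- c(2L, 1L, 4L, 3L)
.compCode <- function(code) ifelse(code == 0L, 0L, .COMP[pmax(code, 1L)])

# Coerce a reference argument (DNAStringSet, DNAString, plain character
# sequence(s), or a FASTA path) to a named DNAStringSet.
.asReference <- function(reference) {
  if (is(reference, "DNAStringSet")) {
    ref <- reference
  } else if (is(reference, "DNAString")) {
    ref <- Biostrings::DNAStringSet(reference)
  } else if (is.character(reference) && length(reference) == 1L &&
             file.exists(reference)) {
    ref <- Biostrings::readDNAStringSet(reference)
    names(ref) <- sub("\\s.*$", "", names(ref))
  } else if (is.character(reference)) {
    ref <- Biostrings::DNAStringSet(reference)
  } else {
    stop("reference must be a DNAStringSet, DNAString, sequence string, ",
         "or FASTA path")
  }
  if (is.null(names(ref)) || any(!nzchar(names(ref))))
    names(ref) <- paste0("seq", seq_along(ref))
  ref
}

# integer base codes per contig, as a named list
.referenceCodes <- function(reference) {
  ref <- .asReference(reference)
  out <- lapply(seq_along(ref), function(i) {
    .CODE_TAB[as.integer(charToRaw(as.character(ref[[i]]))) + 1L]
  })
  names(out) <- names(ref)
  out
}

#' Build a synthetic reference sequence
#'
#' Generates a single-contig random reference with i.i.d. base composition.
#' The synthetic reference supports end-motif lookup for simulated
#' fragments; its composition is controlled independently of the fragment
#' 5'-end preference, mirroring the reference-versus-fragment-end contrast
#' seen in real cfDNA data.
#'
#' @param length contig length in bases (at least 10,000).
#' @param baseProbs base probabilities in A,T,C,G order; must sum to 1.
#' @param seed integer seed; fixed seed gives an identical sequence.
#' @param name contig name.
#' @return A [Biostrings::DNAStringSet] with one contig.
#' @examples
#' ref <- buildReference(10000, seed = 1)
#' Biostrings::width(ref)
#' @export
buildReference <- function(length, baseProbs = c(0.25, 0.25, 0.25, 0.25),
                           seed = NULL, name = "chrS") {
  length <- as.integer(length)
  if (is.na(length) || length < 10000L)
    stop("reference length must be at least 10,000 bp")
  msg <- .validProbs(as.numeric(baseProbs), "baseProbs")
  if (!is.null(msg)) stop(msg)
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- sample.int(4L, length, replace = TRUE, prob = baseProbs)
  # raw byte codes for A, T, C, G in the package's base order
  bytes <- as.raw(c(65L, 84L, 67L, 71L))[idx]
  ref <- Biostrings::DNAStringSet(rawToChar(bytes))
  names(ref) <- name
  ref
}

#' Write a reference as FASTA
#'
#' Thin wrapper over [Biostrings::writeXStringSet()] using 60-column
#' wrapping.
#'
#' @param reference a DNAStringSet (or anything [buildReference()] returns).
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeReferenceFasta <- function(reference, path) {
  Biostrings::writeXStringSet(.asReference(reference), path, width = 60L)
  invisible(path)
}

#' Base composition of a reference genome
#'
#' Fractions of A, T, C and G over all counted bases; N and other ambiguity
#' codes are excluded from the denominator.
#'
#' @param reference a DNAStringSet / DNAString / FASTA path.
#' @return Named numeric(4) in A,T,C,G order, summing to 1.
#' @examples
#' genomeBaseComposition("AACCGGTT")
#' @export
genomeBaseComposition <- function(reference) {
  ref <- .asReference(reference)
  af <- colSums(Biostrings::alphabetFrequency(ref)[, c("A", "T", "C", "G"),
                                                   drop = FALSE])
  tot <- sum(af)
  if (tot == 0)
    stop("reference contains no unambiguous A/C/G/T bases")
  out <- af / tot
  names(out) <- .BASES
  out
}
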