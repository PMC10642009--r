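#' @include AllClasses.R
NULL

#' Construct a simulation preset
#'
#' Builds a [SimPreset-class] after validating all probability vectors.
#' Weight vectors whose printed values sum to slightly off 1 (within 0.005,
#' as happens with rounded published proportions) are renormalised; larger
#' deviations are a validation error.
#'
#' @param name preset identifier.
#' @param nucWeights mixture weights of the mono/di/tri/tetra components.
#' @param nucModes modal fragment lengths in bp, strictly increasing.
#' @param nucSds spreads (sd, bp) of the four components.
#' @param subpeakPositions sub-nucleosomal ladder positions in bp (all below
#'   \code{nucModes[1]}), or \code{integer(0)} for no ladder.
#' @param subpeakWeight probability that a mono-nucleosome fragment comes
#'   from the sub-nucleosomal ladder.
#' @param subpeakJitterSd bp jitter (sd) around each ladder rung.
#' @param endBaseProbs 5'-end base probabilities, A,T,C,G order.
#' @param genomeBaseProbs reference base composition, A,T,C,G order.
#' @return A validated [SimPreset-class] object.
#' @examples
#' p <- simPreset("flat", nucWeights = c(1, 0, 0, 0),
#'                subpeakPositions = integer(0), subpeakWeight = 0)
#' p
#' @export
simPreset <- function(name,
                      nucWeights = c(0.85, 0.121, 0.023, 0.004),
                      nucModes = c(167L, 333L, 527L, 719L),
                      nucSds = c(6, 15, 20, 25),
                      subpeakPositions = c(50L, 60L, 70L, 81L, 91L, 102L,
                                           111L, 122L, 134L, 153L),
                      subpeakWeight = 0.15,
                      subpeakJitterSd = 1.0,
                      endBaseProbs = c(0.25, 0.25, 0.25, 0.25),
                      genomeBaseProbs = c(0.25, 0.25, 0.25, 0.25)) {
  norm <- function(p, what) {
    s <- sum(p)
    if (is.finite(s) && abs(s - 1) > 1e-9 && abs(s - 1) <= 0.005) p / s
    else p
  }
  new("SimPreset",
      name = as.character(name),
      nucWeights = norm(as.numeric(nucWeights)),
      nucModes = as.integer(nucModes),
      nucSds = as.numeric(nucSds),
      subpeakPositions = as.integer(subpeakPositions),
      subpeakWeight = as.numeric(subpeakWeight),
      subpeakJitterSd = as.numeric(subpeakJitterSd),
      endBaseProbs = norm(as.numeric(endBaseProbs)),
      genomeBaseProbs = norm(as.numeric(genomeBaseProbs)))
}

#' Built-in simulation presets
#'
#' Returns one of the package's built-in generative profiles:
#' \describe{
#'   \item{human_healthy}{healthy human plasma: nucleosome ladder at
#'     167/333/527/719 bp with class weights 85.0/12.1/2.3/0.4\%, the ten
#'     canonical sub-nucleosomal rungs (50--153 bp), 5' end bases
#'     18.8/23.3/35.9/22.0\% (A/T/C/G) and human-like genome composition
#'     29.5/29.6/20.4/20.5\%.}
#'   \item{dog_healthy}{healthy dog plasma: ladder at 163/362/547/728 bp,
#'     weights 74.2/17.2/6.9/1.7\%, eleven rungs (50--153 bp, including
#'     144), end bases 23.7/23.3/30.3/22.7\%; uniform genome composition.}
#'   \item{hl60_pellet}{apoptotic HL60 cell pellet: nucleosomal ladder only
#'     (no sub-nucleosomal rungs -- intracellular digestion is
#'     inter-nucleosomal), end bases 24.9/24.0/31.8/19.3\%.}
#'   \item{hl60_supernatant}{apoptotic HL60 culture supernatant: the
#'     extracellularly digested profile with eleven rungs at
#'     50--150 bp and end bases 21.9/26.9/29.8/21.4\%.}
#'   \item{cancer}{the human_healthy profile with the sub-nucleosomal
#'     weight doubled (0.30) and the C-end probability reduced to 0.30
#'     (the freed mass redistributed proportionally over A/T/G) --
#'     a cancer-like profile with more short fragments and weaker C-end
#'     preference.}
#' }
#'
#' @param name one of \code{presetNames()}.
#' @return A [SimPreset-class].
#' @examples
#' builtinPreset("human_healthy")
#' @export
builtinPreset <- function(name = presetNames()) {
  name <- match.arg(name)
  humanGenome <- c(0.295, 0.296, 0.204, 0.205)
  switch(name,
    human_healthy = simPreset("human_healthy",
      nucWeights = c(0.850, 0.121, 0.023, 0.004),
      nucModes = c(167L, 333L, 527L, 719L),
      nucSds = c(6, 15, 20, 25),
      subpeakPositions = c(50L, 60L, 70L, 81L, 91L, 102L, 111L, 122L,
                           134L, 153L),
      subpeakWeight = 0.15, subpeakJitterSd = 1.0,
      endBaseProbs = c(0.188, 0.233, 0.359, 0.220),
      genomeBaseProbs = humanGenome),
    dog_healthy = simPreset("dog_healthy",
      nucWeights = c(0.742, 0.172, 0.069, 0.017),
      nucModes = c(163L, 362L, 547L, 728L),
      nucSds = c(6, 15, 20, 25),
      subpeakPositions = c(50L, 60L, 70L, 81L, 92L, 102L, 112L, 122L,
                           133L, 144L, 153L),
      subpeakWeight = 0.15, subpeakJitterSd = 1.0,
      endBaseProbs = c(0.237, 0.233, 0.303, 0.227),
      genomeBaseProbs = c(0.25, 0.25, 0.25, 0.25)),
    hl60_pellet = simPreset("hl60_pellet",
      nucWeights = c(0.45, 0.30, 0.16, 0.09),
      nucModes = c(167L, 360L, 540L, 720L),
      nucSds = c(6, 15, 20, 25),
      subpeakPositions = integer(0),
      subpeakWeight = 0, subpeakJitterSd = 1.0,
      endBaseProbs = c(0.249, 0.240, 0.318, 0.193),
      genomeBaseProbs = humanGenome),
    hl60_supernatant = simPreset("hl60_supernatant",
      nucWeights = c(0.80, 0.15, 0.04, 0.01),
      nucModes = c(167L, 360L, 540L, 720L),
      nucSds = c(6, 15, 20, 25),
      subpeakPositions = c(50L, 60L, 70L, 81L, 91L, 101L, 111L, 122L,
                           133L, 141L, 150L),
      subpeakWeight = 0.25, subpeakJitterSd = 1.0,
      endBaseProbs = c(0.219, 0.269, 0.298, 0.214),
      genomeBaseProbs = humanGenome),
    cancer = {
      h <- builtinPreset("human_healthy")
      eb <- h@endBaseProbs
      cNew <- 0.30
      scale <- (1 - cNew) / (1 - eb[3])
      eb <- eb * scale
      eb[3] <- cNew
      simPreset("cancer",
        nucWeights = h@nucWeights, nucModes = h@nucModes,
        nucSds = h@nucSds, subpeakPositions = h@subpeakPositions,
        subpeakWeight = min(1, 2 * h@subpeakWeight),
        subpeakJitterSd = h@subpeakJitterSd,
        endBaseProbs = eb, genomeBaseProbs = h@genomeBaseProbs)
    })
}

#' @rdname builtinPreset
#' @export
presetNames <- function() {
  c("human_healthy", "dog_healthy", "hl60_pellet", "hl60_supernatant",
    "cancer")
}

#' Read / write simulation presets as JSON
#'
#' Presets round-trip through a flat JSON object holding every
#' [SimPreset-class] field, so custom generative profiles can be stored
#' alongside a simulation and fed back via the command-line interface.
#'
#' @param preset a [SimPreset-class].
#' @param path JSON file path.
#' @return \code{writePresetJson} returns \code{path} invisibly;
#'   \code{readPresetJson} returns a [SimPreset-class].
#' @examples
#' f <- tempfile(fileext = ".json")
#' writePresetJson(builtinPreset("dog_healthy"), f)
#' readPresetJson(f)
#' @export
writePresetJson <- function(preset, path) {
  stopifnot(is(preset, "SimPreset"))
  x <- list(
    name = preset@name,
    nucWeights = preset@nucWeights,
    nucModes = preset@nucModes,
    nucSds = preset@nucSds,
    subpeakPositions = preset@subpeakPositions,
    subpeakWeight = preset@subpeakWeight,
    subpeakJitterSd = preset@subpeakJitterSd,
    endBaseProbs = preset@endBaseProbs,
    genomeBaseProbs = preset@genomeBaseProbs
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePresetJson
#' @export
readPresetJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("name", "nucWeights", "nucModes", "nucSds",
              "subpeakPositions", "subpeakWeight", "subpeakJitterSd",
              "endBaseProbs", "genomeBaseProbs")
  missing <- setdiff(needed, names(x))
  if (length(missing))
    stop("preset JSON is missing fields: ", paste(missing, collapse = ", "))
  simPreset(x$name,
            nucWeights = x$nucWeights, nucModes = x$nucModes,
            nucSds = x$nucSds,
            subpeakPositions = as.integer(x$subpeakPositions),
            subpeakWeight = x$subpeakWeight,
            subpeakJitterSd = x$subpeakJitterSd,
            endBaseProbs = x$endBaseProbs,
            genomeBaseProbs = x$genomeBaseProbs)
}

setMethod("show", "SimPreset", function(object) {
  cat("SimPreset '", object@name, "'\n", sep = "")
  cat("  nucleosome weights:",
      paste(sprintf("%.3f", object@nucWeights), collapse = "/"), "\n")
  cat("  modes (bp):", paste(object@nucModes, collapse = "/"), "\n")
  if (length(object@subpeakPositions))
    cat("  subpeak ladder:", paste(object@subpeakPositions, collapse = ","),
        sprintf("(weight %.2f)", object@subpeakWeight), "\n")
  else
    cat("  subpeak ladder: none\n")
  cat("  5' end base probs (A/T/C/G):",
      paste(sprintf("%.3f", object@endBaseProbs), collapse = "/"), "\n")
  invisible(object)
})
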