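# Shared, lazily computed fixtures. The large simulations are reused by
# several test files, so they are generated once per test run and cached.
.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# 2 Mb synthetic references; human-like composition doubles for the HL60
# presets (a human cell line)
refHuman <- function() .cached("refHuman",
  buildReference(2e6, c(0.295, 0.296, 0.204, 0.205), seed = 11))

refDog <- function() .cached("refDog",
  buildReference(2e6, c(0.25, 0.25, 0.25, 0.25), seed = 12))

simHuman <- function() .cached("simHuman",
  simulateFragments(builtinPreset("human_healthy"), 1e6, refHuman(),
                    seed = 42))

simDog <- function() .cached("simDog",
  simulateFragments(builtinPreset("dog_healthy"), 1e6, refDog(),
                    seed = 42))

simHl60Pellet <- function() .cached("simHl60Pellet",
  simulateFragments(builtinPreset("hl60_pellet"), 1e6, refHuman(),
                    seed = 42))

# small synthetic cohort: per-sample FragmentSets from a preset
simCohort <- function(preset, nSamples, nFrags, ref, seedBase) {
  lapply(seq_len(nSamples), function(i) {
    simulateFragments(preset, nFrags, ref, seed = seedBase + i,
                      sampleId = paste0(preset@name, "_", i))
  })
}

# construct a SampleFeatures directly (for statistical unit tests that do
# not need fragments behind the features)
makeFeatures <- function(id, ratios, cend = NULL, group = NA_character_) {
  if (is.null(cend))
    cend <- data.frame(size = integer(0), n = integer(0),
                       cFrac = numeric(0))
  new("SampleFeatures", sampleId = id, group = as.character(group),
      peakRatios = ratios, cend = cend, total = 1000L)
}
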