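# shared fixtures: small ground truths and quick flux tables

brainTruth <- function(o2NoiseSd = 0, fluoNoiseSd = 0, ...) {
  physiologicalPreset(o2NoiseSd = o2NoiseSd, fluoNoiseSd = fluoNoiseSd, ...)
}

zeroFluxTruth <- function() {
  traceGroundTruth(
    o2Flux = setNames(rep(0, 6), suitStates()),
    o2NoiseSd = 0, fluoNoiseSd = 0)
}

# FluxTable straight from mass-specific values (V = m so j_mass = j_v)
massFluxTable <- function(j_mass, csUnits = NA) {
  normalizeFluxes(j_mass, chamberVolume = 2, sampleMass = 2,
                  csUnits = csUnits)
}

amrSchedule <- function(...) {
  suitSchedule(preSampleTitrations = 2, sampleTime = 240,
               titrationInterval = 1200, ...)
}

trueCorrected <- function(truth) {
  f <- truth@o2Flux
  out <- f - f[["ROX"]]
  out[["ROX"]] <- 0
  out
}
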