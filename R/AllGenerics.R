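#' @include AllClasses.R
NULL

#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))

#' @export
setGeneric("o2Concentration", function(x) standardGeneric("o2Concentration"))

#' @export
setGeneric("fluorescence", function(x) standardGeneric("fluorescence"))

#' @export
setGeneric("traceEvents", function(x) standardGeneric("traceEvents"))

#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @export
setGeneric("transientMask", function(x) standardGeneric("transientMask"))

#' @export
setGeneric("chamberVolume", function(x) standardGeneric("chamberVolume"))

#' @export
setGeneric("sampleMass", function(x) standardGeneric("sampleMass"))

#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @export
setGeneric("isRoxCorrected", function(x) standardGeneric("isRoxCorrected"))

#' @export
setGeneric("sensitivityAt", function(object, time) standardGeneric("sensitivityAt"))

#' @export
setGeneric("particles", function(x) standardGeneric("particles"))

#' @export
setGeneric("excludedParticles", function(x) standardGeneric("excludedParticles"))

#' @export
setGeneric("cellArea", function(x) standardGeneric("cellArea"))
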