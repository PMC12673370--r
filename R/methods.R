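#' @include AllGenerics.R
NULL

#' @describeIn RespirometryTrace-class sampling times (s).
#' @param x a `RespirometryTrace`.
#' @export
setMethod("traceTime", "RespirometryTrace", function(x) x@time)

#' @describeIn RespirometryTrace-class O2 concentration series (uM).
#' @export
setMethod("o2Concentration", "RespirometryTrace", function(x) x@o2)

#' @describeIn RespirometryTrace-class fluorescence series (V), length 0
#'   when absent.
#' @export
setMethod("fluorescence", "RespirometryTrace", function(x) x@fluo)

#' @describeIn RespirometryTrace-class event schedule.
#' @export
setMethod("traceEvents", "RespirometryTrace", function(x) x@events)

#' @describeIn RespirometryTrace-class per-sample state annotation.
#' @export
setMethod("stateLabels", "RespirometryTrace", function(x) x@stateLabel)

#' @describeIn RespirometryTrace-class logical mask of injection artifacts.
#' @export
setMethod("transientMask", "RespirometryTrace", function(x) x@transient)

#' @describeIn RespirometryTrace-class chamber volume (mL).
#' @export
setMethod("chamberVolume", "RespirometryTrace", function(x) x@chamberVolume)

#' @describeIn RespirometryTrace-class wet sample mass in the chamber (mg).
#' @export
setMethod("sampleMass", "RespirometryTrace", function(x) x@sampleMass)

setMethod("show", "RespirometryTrace", function(object) {
  cat("RespirometryTrace:", length(object@time), "samples,",
      sprintf("%.0f-%.0f s,", min(object@time), max(object@time)),
      if (length(object@fluo)) "O2 + fluorescence" else "O2 only", "\n")
  cat("  chamber", object@chamberVolume, "mL, sample", object@sampleMass,
      "mg,", nrow(object@events), "events\n")
  st <- setdiff(unique(object@stateLabel), "")
  if (length(st)) cat("  states:", paste(st, collapse = " "), "\n")
})

#' @describeIn FluxTable-class the per-state flux table as a data.frame.
#' @param x a `FluxTable`.
#' @export
setMethod("fluxes", "FluxTable", function(x) x@table)

#' @describeIn FluxTable-class whether Rox correction has been applied.
#' @export
setMethod("isRoxCorrected", "FluxTable", function(x) x@roxCorrected)

#' @describeIn FluxTable-class chamber volume used for normalization (mL).
#' @export
setMethod("chamberVolume", "FluxTable", function(x) x@chamberVolume)

#' @describeIn FluxTable-class sample mass used for normalization (mg).
#' @export
setMethod("sampleMass", "FluxTable", function(x) x@sampleMass)

setMethod("show", "FluxTable", function(object) {
  cat(sprintf("FluxTable (%s), V = %g mL, m = %g mg%s\n",
              if (object@roxCorrected) "Rox-corrected" else "raw",
              object@chamberVolume, object@sampleMass,
              if (is.finite(object@csUnits))
                sprintf(", CS = %g IU", object@csUnits) else ""))
  print(object@table, row.names = FALSE, digits = 4)
})

#' @describeIn AmrCalibration-class sensitivity (V/uM) at arbitrary times:
#'   linear interpolation between knots, nearest-knot value outside them.
#' @param object an `AmrCalibration`.
#' @param time numeric vector of times (s).
#' @export
setMethod("sensitivityAt", "AmrCalibration", function(object, time) {
  k <- object@knots
  if (nrow(k) == 1L) return(rep(k$sensitivity, length(time)))
  stats::approx(k$time_s, k$sensitivity, xout = time, rule = 2)$y
})

#' Chemical background fluorescence at arbitrary times
#'
#' Evaluates the fitted linear chemical background (intercept + drift) of
#' an [AmrCalibration-class] at the requested times.
#'
#' @param calibration an `AmrCalibration`.
#' @param time numeric vector of times (s).
#' @return numeric vector of background fluorescence values (V).
#' @export
backgroundAt <- function(calibration, time) {
  stopifnot(is(calibration, "AmrCalibration"))
  calibration@backgroundIntercept + calibration@backgroundSlope * time
}

setMethod("show", "AmrCalibration", function(object) {
  cat(sprintf("AmrCalibration: background %.4g V + %.3g V/s, %d sensitivity knot(s)\n",
              object@backgroundIntercept, object@backgroundSlope,
              nrow(object@knots)))
  cat(sprintf("  sensitivity %.4g-%.4g V/uM, residual SD %.3g V\n",
              min(object@knots$sensitivity), max(object@knots$sensitivity),
              object@residualSd))
})

#' @describeIn ParticleSet-class retained particles.
#' @param x a `ParticleSet`.
#' @export
setMethod("particles", "ParticleSet", function(x) x@particles)

#' @describeIn ParticleSet-class excluded particles with reasons.
#' @export
setMethod("excludedParticles", "ParticleSet", function(x) x@excluded)

#' @describeIn ParticleSet-class cell area in calibrated units.
#' @export
setMethod("cellArea", "ParticleSet", function(x) x@cellArea)

setMethod("show", "ParticleSet", function(object) {
  cat("ParticleSet", object@imageId, ":", nrow(object@particles),
      "particles retained,", nrow(object@excluded), "excluded,",
      "cell area", object@cellArea, "\n")
})

setMethod("show", "GroupComparison", function(object) {
  cat(object@test, "(", object@summaryStyle, ")\n")
  s <- object@summaries
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %.4g +/- %.4g (n = %d)\n",
                s$group[i], s$center[i], s$spread[i], s$n[i]))
  if (nrow(object@outliers))
    cat("  outliers removed (ROUT):",
        paste(sprintf("%s=%.4g", object@outliers$group, object@outliers$value),
              collapse = ", "), "\n")
  cat(sprintf("  %s = %.4g, p = %.4g\n",
              names(object@statistic)[1], object@statistic[1], object@pValue))
  if (nrow(object@pairwise)) {
    cat("  pairwise (Sidak-adjusted):\n")
    pw <- object@pairwise
    for (i in seq_len(nrow(pw)))
      cat(sprintf("    %s vs %s: diff %.4g, p_adj = %.4g\n",
                  pw$group1[i], pw$group2[i], pw$estimate[i], pw$p_adj[i]))
  }
})
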