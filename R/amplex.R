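#' @include AllClasses.R
NULL

#' Fit the chemical background and initial AmR sensitivity
#'
#' Uses the pre-sample calibration segment of a fluorometric run - the
#' chelator/SOD/HRP/AmR medium titrated with known 0.1 uM H2O2 steps in
#' the absence of biological sample - to determine the chemical background
#' fluorescence (linear in time) and the fluorophore sensitivity. All
#' non-artifact samples before sample addition enter one least-squares fit
#' `F = b0 + b1*t + s0*C_added(t)`, where `C_added` is the known cumulative
#' titrated H2O2; `s0` is the fitted sensitivity (equivalently, the
#' least-squares slope of step height against added H2O2, estimated
#' jointly with the drift).
#'
#' @param trace a [RespirometryTrace-class] with a fluorescence channel
#'   whose event schedule contains >= 2 `H2O2` titrations before the
#'   `sample` event.
#' @return An [AmrCalibration-class] with one sensitivity knot at the mean
#'   pre-sample titration time.
#' @export
fitBackgroundCalibration <- function(trace) {
  stopifnot(is(trace, "RespirometryTrace"))
  f <- fluorescence(trace)
  if (!length(f)) stop("trace has no fluorescence channel")
  ev <- traceEvents(trace)
  sampleT <- ev$time_s[ev$substance == "sample"]
  if (!length(sampleT)) stop("no sample event in schedule")
  sampleT <- min(sampleT)
  tit <- ev[ev$substance == "H2O2" & ev$time_s < sampleT, ]
  if (nrow(tit) < 2L)
    stop("background calibration needs >= 2 pre-sample H2O2 titrations")
  time <- traceTime(trace)
  keep <- time < sampleT & !transientMask(trace)
  t0 <- time[keep]; f0 <- f[keep]
  cAdd <- rowSums(outer(t0, tit$time_s, ">=") *
                    rep(tit$final_conc, each = length(t0)))
  fit <- stats::lm(f0 ~ t0 + cAdd)
  s0 <- stats::coef(fit)[["cAdd"]]
  if (!is.finite(s0) || s0 <= 0)
    stop("fitted AmR sensitivity is non-positive")
  new("AmrCalibration",
      backgroundIntercept = stats::coef(fit)[["(Intercept)"]],
      backgroundSlope = stats::coef(fit)[["t0"]],
      knots = data.frame(time_s = mean(tit$time_s), sensitivity = s0),
      residualSd = suppressWarnings(summary(fit))$sigma)
}

# step height of a titration at te: local linear fits on both sides,
# both extrapolated to te; isolation from neighbouring events enforced
.stepHeight <- function(time, f, transient, te, otherEvents,
                        halfWindow = 30, transientDuration = 10) {
  prevEv <- suppressWarnings(max(otherEvents[otherEvents < te]))
  nextEv <- suppressWarnings(min(otherEvents[otherEvents > te]))
  pre <- which(time >= max(te - halfWindow, prevEv + transientDuration) &
                 time < te & !transient)
  post <- which(time > te & time <= min(te + transientDuration + halfWindow,
                                        nextEv) & !transient)
  if (length(pre) < 3L || length(post) < 3L) return(NA_real_)
  pf <- stats::lm(f[pre] ~ time[pre])
  qf <- stats::lm(f[post] ~ time[post])
  unname((stats::coef(qf)[1] + stats::coef(qf)[2] * te) -
           (stats::coef(pf)[1] + stats::coef(pf)[2] * te))
}

#' Update the sensitivity calibration from in-run H2O2 titrations
#'
#' Each in-run 0.1 uM H2O2 titration step yields a sensitivity knot
#' `s(t) = step height / 0.1 uM`; the step height is measured by local
#' linear fits before and after the injection (both extrapolated to the
#' injection time), which cancels the chemical and metabolic drift.
#' Between knots the sensitivity is interpolated linearly; outside them
#' the nearest knot value is used (see [sensitivityAt()]).
#'
#' @param trace a fluorometric [RespirometryTrace-class].
#' @param calibration the [AmrCalibration-class] from
#'   [fitBackgroundCalibration()].
#' @param halfWindow length (s) of the local fit windows, default 30.
#' @return The calibration with in-run sensitivity knots appended.
#' @export
updateSensitivity <- function(trace, calibration, halfWindow = 30) {
  stopifnot(is(trace, "RespirometryTrace"), is(calibration, "AmrCalibration"))
  f <- fluorescence(trace)
  if (!length(f)) stop("trace has no fluorescence channel")
  ev <- traceEvents(trace)
  sampleT <- min(c(ev$time_s[ev$substance == "sample"], Inf))
  tit <- ev[ev$substance == "H2O2" & ev$time_s > sampleT, ]
  if (!nrow(tit)) return(calibration)
  time <- traceTime(trace)
  knots <- calibration@knots
  for (i in seq_len(nrow(tit))) {
    te <- tit$time_s[i]
    h <- .stepHeight(time, f, transientMask(trace), te,
                     setdiff(ev$time_s, te), halfWindow = halfWindow)
    if (is.na(h)) {
      warning(sprintf("titration at t = %g s not isolated; knot skipped", te))
      next
    }
    if (h <= 0)
      stop(sprintf("non-positive step height at H2O2 titration t = %g s", te))
    knots <- rbind(knots,
                   data.frame(time_s = te, sensitivity = h / tit$final_conc[i]))
  }
  knots <- knots[order(knots$time_s), ]
  rownames(knots) <- NULL
  calibration@knots <- knots
  calibration
}

#' H2O2 flux over a state window
#'
#' Converts the fluorescence signal to an H2O2 concentration,
#' `c(t) = (F(t) - background(t)) / s(t)`, using the fitted chemical
#' background and the time-resolved sensitivity, then fits the
#' concentration slope on the window (common slope across sub-segments
#' split at interior events, so titration steps and reoxygenations do not
#' bias it) and scales it to mass- and CS-specific fluxes.
#'
#' @param trace a fluorometric [RespirometryTrace-class].
#' @param window numeric `c(start, end)` (s) or a one-row window
#'   data.frame.
#' @param calibration an [AmrCalibration-class] whose knots (extended by
#'   at most `maxExtrapolation`) cover the window.
#' @param csUnits citrate synthase activity in the chamber (IU) or `NA`.
#' @param maxExtrapolation how far (s) beyond the outermost sensitivity
#'   knot the calibration may be extrapolated, default 1800.
#' @return list with `j_mass` (pmol H2O2 s^-1 mg^-1), `j_cs`
#'   (pmol s^-1 IU^-1 or `NA`), `se`, `n`.
#' @export
h2o2Flux <- function(trace, window, calibration, csUnits = NA,
                     maxExtrapolation = 1800) {
  stopifnot(is(trace, "RespirometryTrace"), is(calibration, "AmrCalibration"))
  if (is.data.frame(window)) window <- c(window$start_s[1], window$end_s[1])
  window <- as.numeric(window)
  k <- calibration@knots
  if (window[1] < min(k$time_s) - maxExtrapolation ||
      window[2] > max(k$time_s) + maxExtrapolation)
    stop(sprintf("window [%g, %g] outside calibration span", window[1],
                 window[2]))
  f <- fluorescence(trace)
  if (!length(f)) stop("trace has no fluorescence channel")
  time <- traceTime(trace)
  keep <- time >= window[1] & time <= window[2] & !transientMask(trace)
  if (sum(keep) < 10L)
    stop(sprintf("window [%g, %g] has fewer than 10 usable samples",
                 window[1], window[2]))
  t0 <- time[keep]
  conc <- (f[keep] - backgroundAt(calibration, t0)) /
    sensitivityAt(calibration, t0)
  ev <- traceEvents(trace)
  cuts <- ev$time_s[ev$time_s > window[1] & ev$time_s < window[2]]
  seg <- factor(findInterval(t0, sort(cuts)))
  fit <- if (nlevels(seg) > 1L) stats::lm(conc ~ seg + t0)
         else stats::lm(conc ~ t0)
  slope <- stats::coef(fit)[["t0"]]          # uM/s of H2O2 production
  se <- suppressWarnings(summary(fit))$coefficients["t0", "Std. Error"]
  V <- chamberVolume(trace); m <- sampleMass(trace)
  list(j_mass = slope * 1000 * V / m,
       j_cs = if (is.na(csUnits)) NA_real_ else slope * 1000 * V / csUnits,
       se = se * 1000 * V / m, n = sum(keep))
}

#' Per-state H2O2 flux table
#'
#' Applies [h2o2Flux()] to every SUIT state window of a fluorometric trace.
#'
#' @inheritParams h2o2Flux
#' @param policy a [windowPolicy()].
#' @return data.frame (`state`, `j_mass`, `j_cs`, `se`).
#' @export
h2o2FluxTable <- function(trace, calibration, csUnits = NA,
                          policy = windowPolicy(), maxExtrapolation = 1800) {
  windows <- markStateWindows(trace, policy)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    r <- h2o2Flux(trace, windows[i, ], calibration, csUnits,
                  maxExtrapolation)
    data.frame(state = windows$state[i], j_mass = r$j_mass, j_cs = r$j_cs,
               se = r$se)
  })
  do.call(rbind, rows)
}

#' H2O2/O2 flux ratio
#'
#' Ratio of H2O2 produced to O2 consumed per state. The O2 fluxes must
#' come from a paired measurement of the same sample without AmR and
#' fluorescence light (which affect respiration), Rox-corrected; the ratio
#' is reported only where the paired O2 flux is positive.
#'
#' @param h2o2Table data.frame from [h2o2FluxTable()] (or with columns
#'   `state`, `j_mass`).
#' @param o2FluxTable a Rox-corrected [FluxTable-class] from the paired
#'   AmR-free run.
#' @return data.frame (`state`, `j_h2o2`, `j_o2`, `ratio`, `percent`);
#'   `ratio` is `NA` where `j_o2 <= 0`.
#' @export
#' @examples
#' o2 <- roxCorrect(normalizeFluxes(
#'   c(N_L = 10, N_P = 45, NS_P = 90, NS_E = 110, S_E = 55, ROX = 2), 2, 2))
#' h <- data.frame(state = "N_P", j_mass = 0.4)
#' fluxRatio(h, o2)
fluxRatio <- function(h2o2Table, o2FluxTable) {
  stopifnot(is(o2FluxTable, "FluxTable"))
  if (!isRoxCorrected(o2FluxTable))
    warning("paired O2 flux table is not Rox-corrected")
  o2 <- fluxes(o2FluxTable)[, c("state", "j_mass")]
  names(o2)[2] <- "j_o2"
  out <- merge(h2o2Table[, c("state", "j_mass")], o2, by = "state",
               sort = FALSE)
  names(out)[2] <- "j_h2o2"
  out$ratio <- ifelse(out$j_o2 > 0, out$j_h2o2 / out$j_o2, NA_real_)
  out$percent <- 100 * out$ratio
  out
}

#' Full fluorometric trace analysis
#'
#' Convenience pipeline for an AmR run: background calibration, in-run
#' sensitivity update, per-state H2O2 fluxes, and (when a paired AmR-free
#' O2 flux table is supplied) the H2O2/O2 flux ratios.
#'
#' @param trace a fluorometric [RespirometryTrace-class].
#' @param pairedO2 optional Rox-corrected [FluxTable-class] from the
#'   paired AmR-free measurement.
#' @param csUnits citrate synthase activity in the chamber (IU) or `NA`.
#' @param policy a [windowPolicy()].
#' @return list with `calibration`, `h2o2` and (optionally) `ratios`.
#' @export
analyzeH2o2Trace <- function(trace, pairedO2 = NULL, csUnits = NA,
                             policy = windowPolicy()) {
  cal <- updateSensitivity(trace, fitBackgroundCalibration(trace))
  h <- h2o2FluxTable(trace, cal, csUnits, policy)
  out <- list(calibration = cal, h2o2 = h)
  if (!is.null(pairedO2)) out$ratios <- fluxRatio(h, pairedO2)
  out
}
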