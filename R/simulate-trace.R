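#' @include AllClasses.R
NULL

.STATE_EVENTS <- c(G = "N_L", D = "N_P", S = "NS_P", U = "NS_E",
                   Rot = "S_E", Ama = "ROX")

#' Build a SUIT titration event schedule
#'
#' Constructs the event table for one chamber run of the SUIT protocol used
#' throughout the package: pyruvate + malate + glutamate (LEAK), ADP
#' (OXPHOS), optional cytochrome c (outer-membrane integrity check),
#' succinate (convergent NS OXPHOS), a stepwise CCCP uncoupler titration
#' (ET capacity), rotenone (S-linked ET) and antimycin A (residual oxygen
#' consumption). Optional 0.1 uM H2O2 calibration titrations can be placed
#' before the sample (chemical background / sensitivity calibration) and at
#' regular intervals during the run (sensitivity-drift monitoring).
#'
#' @param stateDuration plateau length per titration step (s), default 180.
#' @param sampleTime time of sample addition (s).
#' @param uncouplerSteps number of CCCP titration steps, default 3.
#' @param cytochromeC include a cytochrome c event after ADP, default TRUE.
#' @param preSampleTitrations number of 0.1 uM H2O2 calibration titrations
#'   before the sample (needed for the fluorometric channel), default 0.
#' @param titrationInterval interval (s) between in-run 0.1 uM H2O2
#'   titrations, or `NA` for none.
#' @return data.frame with columns `time_s`, `substance`, `final_conc`,
#'   `units`, carrying an attribute `end_s` (run end time).
#' @export
#' @examples
#' head(suitSchedule())
suitSchedule <- function(stateDuration = 180, sampleTime = 60,
                         uncouplerSteps = 3, cytochromeC = TRUE,
                         preSampleTitrations = 0, titrationInterval = NA) {
  stopifnot(stateDuration >= 120, uncouplerSteps >= 1)
  ev <- data.frame(time_s = numeric(0), substance = character(0),
                   final_conc = numeric(0), units = character(0))
  add <- function(t, sub, conc, unit) {
    rbind(ev, data.frame(time_s = t, substance = sub, final_conc = conc,
                         units = unit))
  }
  if (preSampleTitrations > 0) {
    tt <- sampleTime - 60 * rev(seq_len(preSampleTitrations))
    if (min(tt) < 20)
      stop("sampleTime too early for the requested pre-sample titrations")
    for (t in tt) ev <- add(t, "H2O2", 0.1, "uM")
  }
  ev <- add(sampleTime, "sample", NA, "")
  pgm <- sampleTime + 120
  ev <- add(pgm, "P", 5, "mM")
  ev <- add(pgm + 5, "M", 2, "mM")
  ev <- add(pgm + 10, "G", 10, "mM")
  t <- pgm + 10 + stateDuration
  ev <- add(t, "D", 2.5, "mM")
  if (cytochromeC) {
    t <- t + stateDuration
    ev <- add(t, "c", 10, "uM")
  }
  t <- t + stateDuration
  ev <- add(t, "S", 50, "mM")
  uconc <- seq(1.5, 3.5, length.out = max(uncouplerSteps, 2))[seq_len(uncouplerSteps)]
  for (i in seq_len(uncouplerSteps)) {
    t <- t + stateDuration
    ev <- add(t, "U", uconc[i], "uM")
  }
  t <- t + stateDuration
  ev <- add(t, "Rot", 0.5, "uM")
  t <- t + stateDuration
  ev <- add(t, "Ama", 2.5, "uM")
  end <- t + stateDuration
  if (is.finite(titrationInterval)) {
    tt <- seq(sampleTime + titrationInterval, end - 60, by = titrationInterval)
    for (t0 in tt) {
      # keep sensitivity titrations clear of other injections
      while (any(abs(ev$time_s - t0) < 45)) t0 <- t0 + 60
      if (t0 < end - 45) ev <- add(t0, "H2O2", 0.1, "uM")
    }
    # terminal calibration titration so the sensitivity knots span every
    # analysis window (ROX windows close before it)
    if (!any(ev$substance == "H2O2" & ev$time_s > end - 300)) {
      t0 <- end - 60
      while (any(abs(ev$time_s - t0) < 45)) t0 <- t0 - 60
      ev <- add(t0, "H2O2", 0.1, "uM")
    }
  }
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  if (any(diff(ev$time_s) <= 0)) stop("event times must be strictly increasing")
  attr(ev, "end_s") <- end
  ev
}

.regimeBounds <- function(o2Regime) {
  if (is.character(o2Regime)) {
    switch(match.arg(o2Regime, c("air", "normoxic")),
           air = c(floor = 150, ceiling = 200),
           normoxic = c(floor = 30, ceiling = 40))
  } else {
    stopifnot(length(o2Regime) == 2, o2Regime[1] < o2Regime[2])
    c(floor = o2Regime[1], ceiling = o2Regime[2])
  }
}

# per-sample state labels implied by the last state-defining event
.labelStates <- function(time, events) {
  lab <- rep("pre", length(time))
  ev <- events[events$substance %in% names(.STATE_EVENTS), ]
  for (i in seq_len(nrow(ev)))
    lab[time >= ev$time_s[i]] <- .STATE_EVENTS[[ev$substance[i]]]
  lab
}

# mass-specific flux multiplier per uncoupler step; the maximum must be 1
# so that the truth's NS_E value is the attained maximum
.defaultUncouplerProfile <- function(k) {
  if (k == 1L) return(1)
  if (k == 2L) return(c(0.95, 1))
  c(seq(0.9, 1, length.out = k - 1), 0.97)
}

#' Simulate a SUIT respirometry oxygen trace
#'
#' Generates the O2 concentration series of one chamber run: the true flux
#' is piecewise-constant per SUIT state (scaled per uncoupler step by
#' `uncouplerProfile`), O2 concentration integrates `-flux/volume` between
#' events, the chamber is reoxygenated (instantaneous step back to the
#' regime ceiling, recorded as an event) whenever the concentration reaches
#' the regime floor, each injection produces a 10 s masked mixing artifact,
#' and Gaussian noise is added. Every sample is annotated with its true
#' state label.
#'
#' @param schedule event schedule from [suitSchedule()] (or same format).
#' @param truth a [TraceGroundTruth-class].
#' @param o2Regime `"air"` (150-200 uM), `"normoxic"` (30-40 uM), or a
#'   numeric `c(floor, ceiling)` in uM.
#' @param chamberVolume chamber volume (mL), default 2.
#' @param sampleMass wet tissue mass added (mg), default 2.
#' @param dt sampling interval (s), default 2.
#' @param seed optional integer seed for reproducibility.
#' @param autoReoxygenate reoxygenate at the regime floor (default TRUE);
#'   when FALSE the simulation stops with an error naming the state in
#'   which O2 would be driven below zero.
#' @param transientDuration duration of the masked mixing artifact after
#'   each injection (s), default 10.
#' @param transientAmplitude amplitude of the artifact spike (uM), default 1.
#' @param cytochromeCEffect multiplicative flux change after cytochrome c
#'   (1 = intact outer membrane), default 1.
#' @param uncouplerProfile per-step multiplier of the NS_E flux during the
#'   uncoupler titration (maximum must be 1); default rises to a maximum at
#'   the penultimate step.
#' @param duration total run length (s); defaults to the schedule's
#'   `end_s` attribute.
#' @return A [RespirometryTrace-class]; together with `truth` it fully
#'   specifies the simulation ground truth.
#' @export
#' @examples
#' tr <- simulateRespirometryTrace(suitSchedule(),
#'   traceGroundTruth(o2Flux = c(N_L = 10, N_P = 45, NS_P = 90,
#'                               NS_E = 110, S_E = 55, ROX = 2)),
#'   seed = 1)
#' tr
simulateRespirometryTrace <- function(schedule, truth, o2Regime = "air",
                                      chamberVolume = 2, sampleMass = 2,
                                      dt = 2, seed = NULL,
                                      autoReoxygenate = TRUE,
                                      transientDuration = 10,
                                      transientAmplitude = 1,
                                      cytochromeCEffect = 1,
                                      uncouplerProfile = NULL,
                                      duration = attr(schedule, "end_s")) {
  stopifnot(is(truth, "TraceGroundTruth"))
  validObject(truth)
  if (any(diff(schedule$time_s) <= 0))
    stop("events must be strictly increasing in time")
  if (is.null(duration)) duration <- max(schedule$time_s) + 180
  bounds <- .regimeBounds(o2Regime)
  if (!is.null(seed)) set.seed(seed)

  time <- seq(0, duration, by = dt)
  n <- length(time)
  lab <- .labelStates(time, schedule)

  nU <- sum(schedule$substance == "U")
  if (is.null(uncouplerProfile)) uncouplerProfile <- .defaultUncouplerProfile(nU)
  if (nU > 0 && length(uncouplerProfile) != nU)
    stop("uncouplerProfile length must match the number of U events")

  # volume-specific flux (pmol s^-1 mL^-1) as a function of time
  fluxAt <- function(t) {
    ev <- schedule[schedule$time_s <= t, ]
    stEv <- ev[ev$substance %in% names(.STATE_EVENTS), ]
    if (!nrow(stEv) || !any(ev$substance == "sample")) return(0)
    state <- .STATE_EVENTS[[stEv$substance[nrow(stEv)]]]
    j <- truth@o2Flux[[state]]
    if (state == "NS_E") {
      step <- sum(ev$substance == "U")
      j <- j * uncouplerProfile[step]
    }
    if (state == "N_P" && any(ev$substance == "c")) j <- j * cytochromeCEffect
    j * sampleMass / chamberVolume
  }

  # exact integration over breakpoints = sample times + event times
  bp <- sort(unique(c(time, schedule$time_s)))
  bp <- bp[bp <= duration + 1e-9]
  conc <- numeric(n)
  events <- schedule
  cNow <- bounds[["ceiling"]]
  iSample <- 1L
  for (k in seq_along(bp)) {
    if (k > 1L) {
      t0 <- bp[k - 1L]
      cNow <- cNow - fluxAt(t0) * (bp[k] - t0) / 1000
    }
    if (cNow < 0) {
      stop(sprintf(
        "O2 concentration driven below 0 in state %s: flux too high for regime",
        .labelStates(bp[k], schedule)))
    }
    if (autoReoxygenate && cNow <= bounds[["floor"]]) {
      cNow <- bounds[["ceiling"]]
      events <- rbind(events, data.frame(time_s = bp[k],
                                         substance = "reoxygenation",
                                         final_conc = bounds[["ceiling"]],
                                         units = "uM"))
    }
    while (iSample <= n && abs(time[iSample] - bp[k]) < 1e-9) {
      conc[iSample] <- cNow
      iSample <- iSample + 1L
    }
  }
  events <- events[order(events$time_s), ]
  rownames(events) <- NULL

  # injection/mixing artifacts: masked and spiked
  transient <- rep(FALSE, n)
  measured <- conc
  inj <- events$time_s
  for (te in inj) {
    idx <- which(time > te & time <= te + transientDuration)
    transient[idx] <- TRUE
    measured[idx] <- measured[idx] +
      transientAmplitude * exp(-(time[idx] - te) / (transientDuration / 3))
  }
  if (truth@o2NoiseSd > 0)
    measured <- measured + stats::rnorm(n, 0, truth@o2NoiseSd)
  measured <- pmax(measured, 0)

  respirometryTrace(time = time, o2 = measured, events = events,
                    chamberVolume = chamberVolume, sampleMass = sampleMass,
                    transient = transient, stateLabel = lab)
}

#' Sensitivity decay law of the simulated fluorescence channel
#'
#' The Amplex UltraRed sensitivity decays exponentially so that after one
#' hour it is multiplied by `1 - decay`: `s(t) = s0 * (1 - decay)^(t/3600)`.
#'
#' @param s0 initial sensitivity (V/uM).
#' @param decay fractional loss per hour in [0, 1).
#' @param time time (s).
#' @return sensitivity values (V/uM).
#' @export
sensitivityDecayLaw <- function(s0, decay, time) {
  stopifnot(decay >= 0, decay < 1, s0 > 0)
  s0 * (1 - decay)^(time / 3600)
}

#' Simulate the Amplex UltraRed fluorescence channel of a trace
#'
#' Adds a fluorescence series to a simulated [RespirometryTrace-class]:
#' `F(t) = background(t) + s(t) * C(t)`, where the chemical background is
#' linear in time, the sensitivity `s(t)` follows [sensitivityDecayLaw()],
#' and the cumulative H2O2 concentration `C(t)` integrates the true
#' mass-specific H2O2 flux of the current state (after sample addition)
#' plus an instantaneous step for every 0.1 uM H2O2 calibration titration.
#' Titration events must be present in the trace's event schedule (see
#' `preSampleTitrations` / `titrationInterval` of [suitSchedule()]).
#'
#' @param trace a [RespirometryTrace-class] from
#'   [simulateRespirometryTrace()].
#' @param truth the same [TraceGroundTruth-class] used for the O2 channel.
#' @param seed optional integer seed for the fluorescence noise.
#' @return The trace with its `fluo` slot populated.
#' @export
simulateAmrChannel <- function(trace, truth, seed = NULL) {
  stopifnot(is(trace, "RespirometryTrace"), is(truth, "TraceGroundTruth"))
  validObject(truth)
  if (!is.null(seed)) set.seed(seed)
  ev <- traceEvents(trace)
  time <- traceTime(trace)
  tit <- ev[ev$substance == "H2O2", ]
  sampleT <- ev$time_s[ev$substance == "sample"]
  if (nrow(tit) && length(sampleT) &&
      !any(tit$time_s < min(sampleT)))
    warning("no pre-sample calibration titrations in the schedule")

  lab <- stateLabels(trace)
  m <- sampleMass(trace); V <- chamberVolume(trace)
  # volume-specific H2O2 flux in uM/s at each sample
  jv <- ifelse(lab %in% names(truth@h2o2Flux),
               unname(truth@h2o2Flux[lab]) * m / V / 1000, 0)
  jv[lab == "pre"] <- 0
  # cumulative H2O2: trapezoid-free exact integration (flux is
  # piecewise-constant; state changes coincide with event times which are
  # masked anyway, so left-Riemann over samples is exact between events)
  dtv <- diff(time)
  C <- cumsum(c(0, jv[-length(jv)] * dtv))
  for (i in seq_len(nrow(tit)))
    C <- C + ifelse(time >= tit$time_s[i], tit$final_conc[i], 0)

  s <- sensitivityDecayLaw(truth@sensitivity0, truth@sensitivityDecay, time)
  if (any(s <= 0)) stop("sensitivity must remain positive")
  f <- truth@backgroundIntercept + truth@backgroundSlope * time + s * C
  # mixing spikes on masked samples
  for (te in ev$time_s) {
    idx <- which(time > te & time <= te + 10)
    f[idx] <- f[idx] + 0.01 * exp(-(time[idx] - te) / 3)
  }
  if (truth@fluoNoiseSd > 0)
    f <- f + stats::rnorm(length(f), 0, truth@fluoNoiseSd)
  trace@fluo <- f
  trace
}

#' Physiological simulation preset
#'
#' Ground truth emulating a brain-tissue homogenate run under the
#' fluorometric protocol: mass-specific O2 fluxes typical of mouse brain
#' homogenate across the SUIT states and H2O2 fluxes below 2% of the
#' Rox-corrected O2 flux in every state, the physiological range of
#' electron leak to reactive oxygen species.
#'
#' @param o2NoiseSd O2 noise SD (uM), default 0.5.
#' @param fluoNoiseSd fluorescence noise SD (V), default 0.002.
#' @param sensitivityDecay sensitivity loss per hour, default 0.1.
#' @return A [TraceGroundTruth-class].
#' @export
physiologicalPreset <- function(o2NoiseSd = 0.5, fluoNoiseSd = 0.002,
                                sensitivityDecay = 0.1) {
  traceGroundTruth(
    o2Flux  = c(N_L = 10, N_P = 45, NS_P = 90, NS_E = 110, S_E = 55, ROX = 2),
    h2o2Flux = c(N_L = 0.10, N_P = 0.40, NS_P = 0.80, NS_E = 0.70,
                 S_E = 0.45, ROX = 0.10),
    sensitivity0 = 0.5, sensitivityDecay = sensitivityDecay,
    backgroundIntercept = 0.05, backgroundSlope = 1e-6,
    o2NoiseSd = o2NoiseSd, fluoNoiseSd = fluoNoiseSd)
}
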