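#' @include AllClasses.R
NULL

#' Window-marking policy for SUIT state plateaus
#'
#' Controls how the flux-calculation window of each respiratory state is
#' placed on its plateau: the window is the latest `maxLength` seconds of
#' the plateau, ending `endMargin` seconds before the next titration, with
#' every injection's mixing artifact (`transientDuration` seconds) masked.
#'
#' @param maxLength maximal window length (s), default 120.
#' @param endMargin gap kept before the next event (s), default 30.
#' @param transientDuration injection artifact duration to mask (s),
#'   default 10.
#' @param minSamples minimal number of usable samples per window,
#'   default 10.
#' @return A list of class `windowPolicy`.
#' @export
windowPolicy <- function(maxLength = 120, endMargin = 30,
                         transientDuration = 10, minSamples = 10) {
  structure(list(maxLength = maxLength, endMargin = endMargin,
                 transientDuration = transientDuration,
                 minSamples = minSamples),
            class = "windowPolicy")
}

.eventTime <- function(events, substance) {
  t <- events$time_s[events$substance == substance]
  if (length(t)) t[1] else NA_real_
}

#' Mark per-state flux windows on a SUIT trace
#'
#' Locates the six SUIT states from the event schedule and places one
#' flux-calculation window per state according to the window policy. The
#' `N_P` window is taken between ADP and cytochrome c (when present) so
#' that the outer-membrane integrity check does not contaminate the OXPHOS
#' estimate. For the multi-step uncoupler titration the flux of every step
#' is computed and the `NS_E` window is the step selected by
#' [uncouplerOptimum()].
#'
#' @param trace a [RespirometryTrace-class].
#' @param policy a [windowPolicy()].
#' @return data.frame (`state`, `start_s`, `end_s`) in SUIT order, with
#'   attributes `uncoupler` (per-step flux table, chosen step, and an
#'   under-titration flag) and `cytochromeC` (pre/post-c windows when a c
#'   event is present).
#' @export
markStateWindows <- function(trace, policy = windowPolicy()) {
  ev <- traceEvents(trace)
  tEnd <- max(traceTime(trace))
  need <- c(G = "N_L", D = "N_P", S = "NS_P", U = "NS_E",
            Rot = "S_E", Ama = "ROX")
  for (sub in names(need)) {
    if (!any(ev$substance == sub))
      stop(sprintf("state %s cannot be marked: missing event %s",
                   need[[sub]], sub))
  }
  tG <- .eventTime(ev, "G"); tD <- .eventTime(ev, "D")
  tc <- .eventTime(ev, "c"); tS <- .eventTime(ev, "S")
  tU <- ev$time_s[ev$substance == "U"]
  tRot <- .eventTime(ev, "Rot"); tAma <- .eventTime(ev, "Ama")

  win <- function(a, b) {
    end <- b - policy$endMargin
    start <- max(a + policy$transientDuration, end - policy$maxLength)
    c(start = start, end = end)
  }
  npEnd <- if (is.finite(tc)) tc else tS
  uEnds <- c(tU[-1], tRot)
  uWins <- lapply(seq_along(tU), function(i) win(tU[i], uEnds[i]))
  uFlux <- vapply(uWins, function(w) {
    f <- computeVolumeFlux(trace, w)
    f$j_v
  }, numeric(1))
  opt <- uncouplerOptimum(uFlux)
  uTab <- data.frame(step = seq_along(tU), time_s = tU,
                     j_v = uFlux)

  rows <- rbind(
    data.frame(state = "N_L",  t(win(tG, tD))),
    data.frame(state = "N_P",  t(win(tD, npEnd))),
    data.frame(state = "NS_P", t(win(tS, tU[1]))),
    data.frame(state = "NS_E", t(uWins[[opt$index]])),
    data.frame(state = "S_E",  t(win(tRot, tAma))),
    data.frame(state = "ROX",
               t(win(tAma, min(c(ev$time_s[ev$substance == "H2O2" &
                                              ev$time_s > tAma],
                                 tEnd + policy$endMargin)))))
  )
  names(rows) <- c("state", "start_s", "end_s")
  attr(rows, "uncoupler") <- c(opt, list(steps = uTab))
  if (is.finite(tc))
    attr(rows, "cytochromeC") <- list(pre = win(tD, tc), post = win(tc, tS))
  rows
}

#' Volume-specific O2 flux over a window
#'
#' Least-squares slope of the O2 concentration on the window, converted to
#' a volume-specific flux (`1 uM/s = 1000 pmol s^-1 mL^-1`, flux is the
#' negative concentration derivative). Samples inside injection artifacts
#' are excluded; if the window contains interior events (reoxygenations,
#' H2O2 titrations), a common slope is fitted across the sub-segments with
#' separate intercepts, so concentration steps do not bias the slope.
#'
#' @param trace a [RespirometryTrace-class].
#' @param window numeric `c(start, end)` in seconds (or a one-row
#'   data.frame with `start_s`, `end_s`).
#' @param channel `"o2"` (default) or `"fluo"` to fit the raw
#'   fluorescence channel instead.
#' @param minSamples minimal usable samples, default 10.
#' @param instrumentBackground optional `c(a, b)`: instrumental O2
#'   background flux (sensor consumption / back-diffusion) modelled as
#'   `a + b * c` (pmol s^-1 mL^-1, with `c` the mean window
#'   concentration in uM) and subtracted from the O2 flux; default off.
#' @return list with `j_v` (pmol s^-1 mL^-1; for `channel = "fluo"` the
#'   raw slope in V/s is returned as `slope`), `se` (same units),
#'   `n` and `window_s`.
#' @export
computeVolumeFlux <- function(trace, window, channel = c("o2", "fluo"),
                              minSamples = 10, instrumentBackground = NULL) {
  channel <- match.arg(channel)
  if (is.data.frame(window)) window <- c(window$start_s[1], window$end_s[1])
  window <- as.numeric(window)
  time <- traceTime(trace)
  y <- if (channel == "o2") o2Concentration(trace) else fluorescence(trace)
  if (!length(y)) stop("trace has no fluorescence channel")
  keep <- time >= window[1] & time <= window[2] & !transientMask(trace)
  if (sum(keep) < minSamples)
    stop(sprintf("window [%g, %g] has %d usable samples (< %d)",
                 window[1], window[2], sum(keep), minSamples))
  t0 <- time[keep]; y0 <- y[keep]
  ev <- traceEvents(trace)
  cuts <- ev$time_s[ev$time_s > window[1] & ev$time_s < window[2]]
  seg <- factor(findInterval(t0, sort(cuts)))
  fit <- if (nlevels(seg) > 1L) stats::lm(y0 ~ seg + t0)
         else stats::lm(y0 ~ t0)
  slope <- stats::coef(fit)[["t0"]]
  se <- suppressWarnings(summary(fit))$coefficients["t0", "Std. Error"]
  if (channel == "o2") {
    jv <- -slope * 1000
    if (!is.null(instrumentBackground))
      jv <- jv - (instrumentBackground[1] +
                    instrumentBackground[2] * mean(y0))
    list(j_v = jv, se = se * 1000, n = sum(keep),
         window_s = diff(window))
  } else
    list(slope = slope, se = se, n = sum(keep), window_s = diff(window))
}

#' Normalize per-state volume-specific fluxes
#'
#' Converts volume-specific fluxes into mass-specific
#' (`J_mass = J_V * V / m`) and citrate-synthase-specific
#' (`J_CS = J_V * V / IU`) fluxes and assembles a [FluxTable-class].
#'
#' @param j_v named numeric of volume-specific fluxes (pmol s^-1 mL^-1),
#'   names are state labels.
#' @param chamberVolume chamber volume (mL), > 0.
#' @param sampleMass sample wet mass (mg), > 0.
#' @param csUnits citrate synthase activity in the chamber (IU), > 0, or
#'   `NA` to skip CS normalization.
#' @param slope_se optional named numeric of slope standard errors (same
#'   units as `j_v`).
#' @param window_s optional named numeric of window lengths (s).
#' @return A [FluxTable-class] (not yet Rox-corrected).
#' @export
#' @examples
#' normalizeFluxes(c(N_L = 10, NS_E = 100, ROX = 2),
#'                 chamberVolume = 2, sampleMass = 2, csUnits = 0.2)
normalizeFluxes <- function(j_v, chamberVolume, sampleMass, csUnits = NA,
                            slope_se = NULL, window_s = NULL) {
  if (chamberVolume <= 0 || sampleMass <= 0)
    stop("chamberVolume and sampleMass must be > 0")
  if (!is.na(csUnits) && csUnits <= 0)
    stop("csUnits must be > 0 (or NA to skip CS normalization)")
  states <- names(j_v)
  if (is.null(states)) stop("j_v must be named by state")
  get <- function(x) if (is.null(x)) rep(NA_real_, length(j_v)) else
    unname(x[states])
  tb <- data.frame(
    state = states,
    j_v = unname(j_v),
    j_mass = unname(j_v) * chamberVolume / sampleMass,
    j_cs = if (is.na(csUnits)) NA_real_ else
      unname(j_v) * chamberVolume / csUnits,
    slope_se = get(slope_se),
    window_s = get(window_s),
    negative = FALSE
  )
  new("FluxTable", table = tb, roxCorrected = FALSE,
      chamberVolume = chamberVolume, sampleMass = sampleMass,
      csUnits = as.numeric(csUnits))
}

#' Residual-oxygen-consumption (Rox) correction
#'
#' Subtracts the ROX-state flux from every state under every normalization.
#' After correction the ROX entry is exactly 0; states whose corrected flux
#' is negative are retained and flagged (`negative = TRUE`) rather than
#' clamped, so downstream ratios stay faithful to the data. The operation
#' is idempotent.
#'
#' @param fluxTable a [FluxTable-class] containing a `ROX` state.
#' @return The Rox-corrected [FluxTable-class].
#' @export
roxCorrect <- function(fluxTable) {
  stopifnot(is(fluxTable, "FluxTable"))
  tb <- fluxTable@table
  i <- which(tb$state == "ROX")
  if (!length(i)) stop("Rox correction impossible: no ROX state in table")
  for (col in c("j_v", "j_mass", "j_cs")) {
    rox <- tb[[col]][i]
    if (is.na(rox)) next
    tb[[col]] <- tb[[col]] - rox
    tb[[col]][i] <- 0
  }
  tb$negative <- tb$j_mass < 0 & tb$state != "ROX"
  if (any(tb$negative))
    warning("Rox correction produced negative flux in state(s): ",
            paste(tb$state[tb$negative], collapse = ", "))
  fluxTable@table <- tb
  fluxTable@roxCorrected <- TRUE
  fluxTable
}

.stateFlux <- function(fluxTable, state) {
  tb <- fluxTable@table
  i <- which(tb$state == state)
  if (!length(i)) stop(sprintf("state %s absent from flux table", state))
  tb$j_mass[i]
}

#' Flux control ratios
#'
#' Normalizes the flux of each state to the maximal flux (NS-linked ET
#' capacity, `NS_E`), yielding dimensionless flux control ratios that
#' remove mitochondrial-content dependence. Ratios are identical across
#' the three normalizations by construction; the mass-specific column is
#' used.
#'
#' @param fluxTable a Rox-corrected [FluxTable-class].
#' @return named numeric of FCR values (one per state); `FCR(NS_E) = 1`.
#' @export
fluxControlRatios <- function(fluxTable) {
  stopifnot(is(fluxTable, "FluxTable"))
  nse <- .stateFlux(fluxTable, "NS_E")
  if (!is.finite(nse) || nse <= 0)
    stop("FCR undefined: NS_E flux must be > 0")
  setNames(fluxTable@table$j_mass / nse, fluxTable@table$state)
}

#' Coupling control efficiencies
#'
#' The E-P control efficiency `1 - NS_P/NS_E` quantifies how much the
#' phosphorylation system limits OXPHOS relative to ET capacity (0 means
#' OXPHOS capacity is not limited); the P-L control efficiency
#' `1 - N_L/N_P` quantifies coupling tightness (1 is a fully coupled
#' system, 0 no coupling). Both are invariant under uniform rescaling of
#' all fluxes.
#'
#' @param fluxTable a Rox-corrected [FluxTable-class] containing states
#'   `N_L`, `N_P`, `NS_P`, `NS_E`.
#' @return named numeric `c(e_p = ..., p_l = ...)`.
#' @export
#' @examples
#' ft <- normalizeFluxes(c(N_L = 0, N_P = 100, NS_P = 100, NS_E = 100,
#'                         S_E = 60, ROX = 0), 2, 2)
#' controlEfficiencies(ft)
controlEfficiencies <- function(fluxTable) {
  nse <- .stateFlux(fluxTable, "NS_E")
  np <- .stateFlux(fluxTable, "N_P")
  if (nse <= 0) stop("E-P control efficiency undefined: NS_E must be > 0")
  if (np <= 0) stop("P-L control efficiency undefined: N_P must be > 0")
  c(e_p = 1 - .stateFlux(fluxTable, "NS_P") / nse,
    p_l = 1 - .stateFlux(fluxTable, "N_L") / np)
}

#' Optimal uncoupler titration step
#'
#' Selects the CCCP titration step with maximal O2 flux as the ET-capacity
#' estimate. Ties are broken toward the lower concentration. If the flux is
#' still rising at the final step the maximum may not have been reached and
#' an under-titration flag is raised.
#'
#' @param stepFluxes numeric, flux at each titration step in order of
#'   increasing uncoupler concentration.
#' @return list with `index`, `flux`, `underTitration`.
#' @export
#' @examples
#' uncouplerOptimum(c(80, 95, 90))
uncouplerOptimum <- function(stepFluxes) {
  stopifnot(length(stepFluxes) >= 1)
  i <- which.max(stepFluxes)   # first maximum: lower concentration on ties
  k <- length(stepFluxes)
  list(index = i, flux = stepFluxes[i],
       underTitration = (i == k) && k > 1 &&
         stepFluxes[k] > stepFluxes[k - 1])
}

#' Cytochrome c outer-membrane integrity test
#'
#' Relative flux increase after cytochrome c addition; an increase above
#' the threshold indicates a damaged outer mitochondrial membrane.
#'
#' @param fluxBefore mass-specific flux before cytochrome c (> 0).
#' @param fluxAfter mass-specific flux after cytochrome c.
#' @param threshold integrity threshold on the relative increase,
#'   default 0.15.
#' @return list with `relativeIncrease` and logical `intact`.
#' @export
cytochromeCTest <- function(fluxBefore, fluxAfter, threshold = 0.15) {
  if (!is.finite(fluxBefore) || fluxBefore <= 0)
    stop("fluxBefore must be > 0")
  inc <- (fluxAfter - fluxBefore) / fluxBefore
  list(relativeIncrease = inc, intact = inc <= threshold)
}

#' Full per-trace respirometry analysis
#'
#' Convenience pipeline: marks state windows, fits per-state volume fluxes,
#' normalizes them, applies Rox correction, and derives flux control ratios
#' and control efficiencies, plus the cytochrome c integrity test when a c
#' event is present.
#'
#' @param trace a [RespirometryTrace-class].
#' @param csUnits citrate synthase activity in the chamber (IU), or `NA`.
#' @param policy a [windowPolicy()].
#' @param cytochromeCThreshold integrity threshold, default 0.15.
#' @return list with `fluxTable` (Rox-corrected), `raw` (uncorrected
#'   table), `fcr`, `efficiencies`, `windows`, `uncoupler`, `cytochromeC`.
#' @export
analyzeTrace <- function(trace, csUnits = NA, policy = windowPolicy(),
                         cytochromeCThreshold = 0.15) {
  windows <- markStateWindows(trace, policy)
  fits <- lapply(seq_len(nrow(windows)), function(i)
    computeVolumeFlux(trace, windows[i, ]))
  jv <- setNames(vapply(fits, `[[`, numeric(1), "j_v"), windows$state)
  se <- setNames(vapply(fits, `[[`, numeric(1), "se"), windows$state)
  ws <- setNames(vapply(fits, `[[`, numeric(1), "window_s"), windows$state)
  raw <- normalizeFluxes(jv, chamberVolume(trace), sampleMass(trace),
                         csUnits, slope_se = se, window_s = ws)
  corrected <- roxCorrect(raw)
  cyt <- NULL
  cw <- attr(windows, "cytochromeC")
  if (!is.null(cw)) {
    fb <- computeVolumeFlux(trace, cw$pre)$j_v *
      chamberVolume(trace) / sampleMass(trace)
    fa <- computeVolumeFlux(trace, cw$post)$j_v *
      chamberVolume(trace) / sampleMass(trace)
    cyt <- cytochromeCTest(fb, fa, cytochromeCThreshold)
  }
  list(fluxTable = corrected, raw = raw,
       fcr = fluxControlRatios(corrected),
       efficiencies = controlEfficiencies(corrected),
       windows = windows, uncoupler = attr(windows, "uncoupler"),
       cytochromeC = cyt)
}
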