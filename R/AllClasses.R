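#' Canonical SUIT respiratory state labels
#'
#' The six respiratory states resolved by the SUIT protocol used throughout
#' the package, in titration order: NADH-linked LEAK (`N_L`), NADH-linked
#' OXPHOS (`N_P`), NADH- and succinate-linked OXPHOS (`NS_P`), NADH- and
#' succinate-linked electron-transfer capacity (`NS_E`), succinate-linked
#' ET capacity (`S_E`), and residual oxygen consumption (`ROX`).
#'
#' @return Character vector of state labels in protocol order.
#' @export
#' @examples
#' suitStates()
suitStates <- function() c("N_L", "N_P", "NS_P", "NS_E", "S_E", "ROX")

.checkNumScalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (length(x) != 1L || !is.finite(x))
    return(sprintf("'%s' must be a finite scalar", name))
  if (strict && x <= lower) return(sprintf("'%s' must be > %g", name, lower))
  if (!strict && x < lower) return(sprintf("'%s' must be >= %g", name, lower))
  NULL
}

#' TraceGroundTruth: generative parameters of a simulated respirometry run
#'
#' Holds the true per-state oxygen and hydrogen peroxide fluxes and the
#' fluorescence-channel parameters used by [simulateRespirometryTrace()] and
#' [simulateAmrChannel()], so that every simulated trace carries a complete
#' record of its ground truth.
#'
#' @slot o2Flux named numeric, true mass-specific O2 flux per SUIT state
#'   (pmol O2 s^-1 mg^-1).
#' @slot h2o2Flux named numeric, true mass-specific H2O2 flux per state
#'   (pmol H2O2 s^-1 mg^-1).
#' @slot sensitivity0 initial Amplex UltraRed sensitivity (V per uM H2O2).
#' @slot sensitivityDecay fractional sensitivity loss per hour, in [0, 1).
#' @slot backgroundIntercept chemical background fluorescence at t = 0 (V).
#' @slot backgroundSlope chemical background drift (V per s).
#' @slot o2NoiseSd Gaussian noise SD of the O2 channel (uM).
#' @slot fluoNoiseSd Gaussian noise SD of the fluorescence channel (V).
#'
#' @export
setClass("TraceGroundTruth",
  representation(
    o2Flux = "numeric",
    h2o2Flux = "numeric",
    sensitivity0 = "numeric",
    sensitivityDecay = "numeric",
    backgroundIntercept = "numeric",
    backgroundSlope = "numeric",
    o2NoiseSd = "numeric",
    fluoNoiseSd = "numeric"
  )
)

setValidity("TraceGroundTruth", function(object) {
  msg <- character(0)
  st <- suitStates()
  if (!all(st %in% names(object@o2Flux)))
    msg <- c(msg, "o2Flux must be named with all SUIT states")
  if (!all(is.finite(object@o2Flux))) msg <- c(msg, "o2Flux must be finite")
  if (!all(is.finite(object@h2o2Flux))) msg <- c(msg, "h2o2Flux must be finite")
  if ("ROX" %in% names(object@o2Flux) && object@o2Flux[["ROX"]] < 0)
    msg <- c(msg, "ROX-state true O2 flux must be >= 0")
  for (s in c("sensitivity0")) {
    m <- .checkNumScalar(slot(object, s), s, 0, strict = TRUE)
    if (!is.null(m)) msg <- c(msg, m)
  }
  if (object@sensitivityDecay < 0 || object@sensitivityDecay >= 1)
    msg <- c(msg, "sensitivityDecay must be in [0, 1) (fraction per hour)")
  if (object@o2NoiseSd < 0 || object@fluoNoiseSd < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct the ground truth for a simulated respirometry run
#'
#' @param o2Flux named numeric of true mass-specific O2 fluxes
#'   (pmol s^-1 mg^-1), one entry per [suitStates()] label.
#' @param h2o2Flux named numeric of true mass-specific H2O2 fluxes
#'   (pmol s^-1 mg^-1); defaults to zero for all states.
#' @param sensitivity0 initial fluorophore sensitivity (V/uM), default 0.5.
#' @param sensitivityDecay fractional sensitivity loss per hour (e.g. 0.1
#'   means the sensitivity is multiplied by 0.9 after one hour), default 0.
#' @param backgroundIntercept chemical background at t = 0 (V), default 0.05.
#' @param backgroundSlope chemical background drift (V/s), default 1e-6.
#' @param o2NoiseSd O2 channel noise SD (uM), default 0.5.
#' @param fluoNoiseSd fluorescence noise SD (V), default 0.002.
#' @return A [TraceGroundTruth-class] object.
#' @export
#' @examples
#' traceGroundTruth(o2Flux = c(N_L = 10, N_P = 45, NS_P = 90, NS_E = 110,
#'                             S_E = 55, ROX = 2))
traceGroundTruth <- function(o2Flux,
                             h2o2Flux = setNames(rep(0, 6), suitStates()),
                             sensitivity0 = 0.5,
                             sensitivityDecay = 0,
                             backgroundIntercept = 0.05,
                             backgroundSlope = 1e-6,
                             o2NoiseSd = 0.5,
                             fluoNoiseSd = 0.002) {
  new("TraceGroundTruth",
      o2Flux = o2Flux, h2o2Flux = h2o2Flux,
      sensitivity0 = sensitivity0, sensitivityDecay = sensitivityDecay,
      backgroundIntercept = backgroundIntercept,
      backgroundSlope = backgroundSlope,
      o2NoiseSd = o2NoiseSd, fluoNoiseSd = fluoNoiseSd)
}

#' RespirometryTrace: a time-resolved oxygraph record
#'
#' Container for one chamber of a high-resolution respirometry run: the O2
#' concentration series, the optional Amplex UltraRed fluorescence channel,
#' the titration event schedule, and the chamber metadata needed for flux
#' normalization.
#'
#' @slot time numeric, sampling times (s), strictly increasing.
#' @slot o2 numeric, O2 concentration (uM), same length as `time`.
#' @slot fluo numeric, fluorescence (V); length 0 when no fluorometric
#'   channel was recorded, otherwise same length as `time`.
#' @slot transient logical, TRUE for samples inside an injection/mixing
#'   artifact that must be excluded from slope fitting.
#' @slot stateLabel character, per-sample SUIT state annotation (simulated
#'   traces carry the true state; empty labels allowed for measured data).
#' @slot events data.frame with columns `time_s`, `substance`, `final_conc`,
#'   `units` (one row per titration/reoxygenation event).
#' @slot chamberVolume chamber volume (mL).
#' @slot sampleMass wet tissue mass in the chamber (mg).
#'
#' @export
setClass("RespirometryTrace",
  representation(
    time = "numeric",
    o2 = "numeric",
    fluo = "numeric",
    transient = "logical",
    stateLabel = "character",
    events = "data.frame",
    chamberVolume = "numeric",
    sampleMass = "numeric"
  )
)

setValidity("RespirometryTrace", function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (n < 2L) msg <- c(msg, "trace needs at least 2 samples")
  if (any(diff(object@time) <= 0)) msg <- c(msg, "time must be strictly increasing")
  if (length(object@o2) != n) msg <- c(msg, "o2 and time lengths differ")
  if (any(!is.finite(object@o2)) || any(object@o2 < 0))
    msg <- c(msg, "O2 concentrations must be finite and >= 0")
  if (length(object@fluo) && length(object@fluo) != n)
    msg <- c(msg, "fluo must be empty or match time length")
  if (length(object@transient) != n) msg <- c(msg, "transient flag length mismatch")
  if (length(object@stateLabel) != n) msg <- c(msg, "stateLabel length mismatch")
  ev <- object@events
  need <- c("time_s", "substance", "final_conc", "units")
  if (!all(need %in% names(ev)))
    msg <- c(msg, "events must have columns time_s, substance, final_conc, units")
  else if (nrow(ev) && (min(ev$time_s) < min(object@time) - 1e-9 ||
                        max(ev$time_s) > max(object@time) + 1e-9))
    msg <- c(msg, "events must lie within the sampled time span")
  m <- .checkNumScalar(object@chamberVolume, "chamberVolume", 0, strict = TRUE)
  if (!is.null(m)) msg <- c(msg, m)
  m <- .checkNumScalar(object@sampleMass, "sampleMass", 0)
  if (!is.null(m)) msg <- c(msg, m)
  if (length(msg)) msg else TRUE
})

#' Construct a RespirometryTrace
#'
#' @param time sampling times (s), strictly increasing.
#' @param o2 O2 concentration (uM).
#' @param events event schedule data.frame (`time_s`, `substance`,
#'   `final_conc`, `units`).
#' @param chamberVolume chamber volume (mL).
#' @param sampleMass wet tissue mass in the chamber (mg); 0 while no sample
#'   has been added.
#' @param fluo optional fluorescence channel (V).
#' @param transient optional logical mask of injection artifacts.
#' @param stateLabel optional per-sample state annotation.
#' @return A [RespirometryTrace-class] object.
#' @export
respirometryTrace <- function(time, o2, events, chamberVolume, sampleMass,
                              fluo = numeric(0), transient = NULL,
                              stateLabel = NULL) {
  n <- length(time)
  if (is.null(transient)) transient <- rep(FALSE, n)
  if (is.null(stateLabel)) stateLabel <- rep("", n)
  new("RespirometryTrace", time = as.numeric(time), o2 = as.numeric(o2),
      fluo = as.numeric(fluo), transient = transient,
      stateLabel = stateLabel, events = events,
      chamberVolume = chamberVolume, sampleMass = sampleMass)
}

#' FluxTable: per-state oxygen (or H2O2) fluxes under three normalizations
#'
#' One row per SUIT state with the volume-specific flux `j_v`
#' (pmol s^-1 mL^-1), the mass-specific flux `j_mass` (pmol s^-1 mg^-1),
#' the citrate-synthase-specific flux `j_cs` (pmol s^-1 IU^-1, `NA` when no
#' CS activity was supplied), the slope standard error and window length of
#' the underlying fit, and a `negative` flag set when Rox correction drives
#' a state below zero.
#'
#' @slot table data.frame with columns `state`, `j_v`, `j_mass`, `j_cs`,
#'   `slope_se`, `window_s`, `negative`.
#' @slot roxCorrected logical, TRUE once [roxCorrect()] has been applied.
#' @slot chamberVolume chamber volume (mL) used for normalization.
#' @slot sampleMass sample mass (mg) used for normalization.
#' @slot csUnits citrate synthase activity in the chamber (IU); `NA` when
#'   CS normalization is unavailable.
#'
#' @export
setClass("FluxTable",
  representation(
    table = "data.frame",
    roxCorrected = "logical",
    chamberVolume = "numeric",
    sampleMass = "numeric",
    csUnits = "numeric"
  )
)

setValidity("FluxTable", function(object) {
  msg <- character(0)
  tb <- object@table
  need <- c("state", "j_v", "j_mass", "j_cs", "slope_se", "window_s", "negative")
  if (!all(need %in% names(tb))) {
    msg <- c(msg, paste("table must have columns", paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(tb$state)) msg <- c(msg, "duplicate states in table")
    ratio <- object@chamberVolume / object@sampleMass
    bad <- abs(tb$j_mass - tb$j_v * ratio) >
      1e-6 * pmax(1, abs(tb$j_mass))
    if (any(bad, na.rm = TRUE))
      msg <- c(msg, "j_mass inconsistent with j_v * volume / mass")
    if (isTRUE(object@roxCorrected) && "ROX" %in% tb$state) {
      if (abs(tb$j_mass[tb$state == "ROX"]) > 1e-9)
        msg <- c(msg, "ROX entry must be exactly 0 after Rox correction")
    }
  }
  if (length(msg)) msg else TRUE
})

#' AmrCalibration: background and time-resolved sensitivity of the
#' Amplex UltraRed channel
#'
#' @slot backgroundIntercept chemical background fluorescence at t = 0 (V).
#' @slot backgroundSlope chemical background drift (V/s).
#' @slot knots data.frame (`time_s`, `sensitivity`): fluorophore sensitivity
#'   (V/uM) measured at each 0.1 uM H2O2 calibration titration; sensitivity
#'   is interpolated linearly between knots and held at the nearest knot
#'   value outside their range.
#' @slot residualSd residual SD of the calibration fit (V).
#'
#' @export
setClass("AmrCalibration",
  representation(
    backgroundIntercept = "numeric",
    backgroundSlope = "numeric",
    knots = "data.frame",
    residualSd = "numeric"
  )
)

setValidity("AmrCalibration", function(object) {
  msg <- character(0)
  k <- object@knots
  if (!all(c("time_s", "sensitivity") %in% names(k)))
    msg <- c(msg, "knots must have columns time_s and sensitivity")
  else {
    if (nrow(k) < 1L) msg <- c(msg, "at least one sensitivity knot required")
    if (any(k$sensitivity <= 0)) msg <- c(msg, "sensitivities must be > 0")
    if (is.unsorted(k$time_s, strictly = TRUE)) msg <- c(msg, "knot times must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' ParticleSet: segmented mitochondrial particles of one cell
#'
#' @slot particles data.frame (`id`, `area`, `x`, `y`): retained particles
#'   with calibrated area and centroid.
#' @slot excluded data.frame (`id`, `area`, `reason`): particles removed by
#'   the area filter or by the manual-correction exclusion list.
#' @slot cellArea cell area in the same calibrated units.
#' @slot areaCutoff particles with area <= this value are excluded
#'   (default 3, the macro's false-positive filter).
#' @slot imageId source image identifier.
#'
#' @export
setClass("ParticleSet",
  representation(
    particles = "data.frame",
    excluded = "data.frame",
    cellArea = "numeric",
    areaCutoff = "numeric",
    imageId = "character"
  )
)

setValidity("ParticleSet", function(object) {
  msg <- character(0)
  if (!all(c("id", "area", "x", "y") %in% names(object@particles)))
    msg <- c(msg, "particles must have columns id, area, x, y")
  else if (nrow(object@particles) &&
           any(object@particles$area <= object@areaCutoff))
    msg <- c(msg, "retained particle areas must exceed the area cutoff")
  if (object@cellArea <= 0) msg <- c(msg, "cellArea must be > 0")
  if (length(msg)) msg else TRUE
})

#' GroupComparison: an outlier-screened group comparison
#'
#' Result container for [compareTwo()] and [anovaSidak()]: the test used,
#' group sizes after ROUT screening, the statistic and p-value(s), removed
#' outliers, and per-group summaries in the convention matching the test
#' (mean +/- SD for parametric tests, median +/- IQR for Mann-Whitney).
#'
#' @slot test character, one of "t-test", "Mann-Whitney U",
#'   "one-way ANOVA + Sidak".
#' @slot groups character, group labels.
#' @slot n integer, per-group n after outlier removal.
#' @slot statistic named numeric test statistic.
#' @slot pValue numeric, omnibus/two-group p-value.
#' @slot pairwise data.frame of pairwise comparisons (ANOVA only):
#'   `group1`, `group2`, `estimate`, `p_raw`, `p_adj`.
#' @slot outliers data.frame (`group`, `value`) of ROUT-removed values.
#' @slot summaries data.frame (`group`, `n`, `center`, `spread`).
#' @slot summaryStyle "mean +/- SD" or "median +/- IQR".
#'
#' @export
setClass("GroupComparison",
  representation(
    test = "character",
    groups = "character",
    n = "integer",
    statistic = "numeric",
    pValue = "numeric",
    pairwise = "data.frame",
    outliers = "data.frame",
    summaries = "data.frame",
    summaryStyle = "character"
  )
)

setValidity("GroupComparison", function(object) {
  msg <- character(0)
  if (any(object@pValue < 0 | object@pValue > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (nrow(object@pairwise) &&
      any(object@pairwise$p_adj < object@pairwise$p_raw - 1e-12, na.rm = TRUE))
    msg <- c(msg, "Sidak-adjusted p must be >= raw p")
  if (length(msg)) msg else TRUE
})
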