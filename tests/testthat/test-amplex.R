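test_that("background calibration recovers constructed step heights and drift", {
  # noiseless constructed series: drift 2e-6 V/s, steps of 0.05 V per 0.1 uM
  t <- seq(0, 230, by = 2)
  tit <- data.frame(time_s = c(60, 150), substance = "H2O2",
                    final_conc = 0.1, units = "uM")
  ev <- rbind(tit, data.frame(time_s = 220, substance = "sample",
                              final_conc = NA, units = ""))
  cAdd <- (t >= 60) * 0.1 + (t >= 150) * 0.1
  f <- 0.04 + 2e-6 * t + 0.5 * cAdd
  tr <- respirometryTrace(t, rep(180, length(t)), ev, 2, 2, fluo = f)
  cal <- fitBackgroundCalibration(tr)
  expect_equal(cal@knots$sensitivity[1], 0.5, tolerance = 1e-9)
  expect_equal(cal@backgroundSlope, 2e-6, tolerance = 1e-12)
  expect_equal(cal@backgroundIntercept, 0.04, tolerance = 1e-9)
  # zero drift fits exactly zero
  tr0 <- respirometryTrace(t, rep(180, length(t)), ev, 2, 2,
                           fluo = 0.04 + 0.5 * cAdd)
  expect_equal(fitBackgroundCalibration(tr0)@backgroundSlope, 0,
               tolerance = 1e-9)
  # fewer than two pre-sample steps is an error
  ev1 <- ev[-1, ]
  expect_error(fitBackgroundCalibration(
    respirometryTrace(t, rep(180, length(t)), ev1, 2, 2, fluo = f)),
    ">= 2 pre-sample")
})

test_that("calibration on simulated data recovers s0 within 1% at default noise", {
  truth <- brainTruth(o2NoiseSd = 0.5, fluoNoiseSd = 0.002)
  tr <- simulateAmrChannel(
    simulateRespirometryTrace(amrSchedule(), truth, "normoxic", seed = 5),
    truth, seed = 6)
  cal <- fitBackgroundCalibration(tr)
  expect_lt(abs(cal@knots$sensitivity[1] / truth@sensitivity0 - 1), 0.01)
})

test_that("in-run titrations yield decay-law knots with linear interpolation", {
  truth <- traceGroundTruth(
    o2Flux = setNames(rep(0, 6), suitStates()),
    sensitivityDecay = 0.1, o2NoiseSd = 0, fluoNoiseSd = 0)
  tr <- simulateAmrChannel(
    simulateRespirometryTrace(amrSchedule(), truth, "air"), truth)
  cal <- updateSensitivity(tr, fitBackgroundCalibration(tr))
  k <- cal@knots
  expect_gt(nrow(k), 2)
  expected <- sensitivityDecayLaw(truth@sensitivity0, 0.1, k$time_s)
  expect_equal(k$sensitivity / expected, rep(1, nrow(k)), tolerance = 0.002)
  # knots 1 h apart would differ by the factor 0.9; check on the law and
  # on linear interpolation at a midpoint
  mid <- mean(k$time_s[1:2])
  expect_equal(sensitivityAt(cal, mid), mean(k$sensitivity[1:2]))
  expect_equal(sensitivityAt(cal, min(k$time_s) - 100), k$sensitivity[1])
  expect_equal(sensitivityAt(cal, max(k$time_s) + 100),
               k$sensitivity[nrow(k)])
})

test_that("constant sensitivity gives equal knots", {
  truth <- traceGroundTruth(
    o2Flux = setNames(rep(0, 6), suitStates()),
    o2NoiseSd = 0, fluoNoiseSd = 0)
  tr <- simulateAmrChannel(
    simulateRespirometryTrace(amrSchedule(), truth, "air"), truth)
  cal <- updateSensitivity(tr, fitBackgroundCalibration(tr))
  expect_equal(cal@knots$sensitivity,
               rep(truth@sensitivity0, nrow(cal@knots)), tolerance = 1e-6)
})

test_that("flat background-corrected fluorescence gives zero H2O2 flux", {
  t <- seq(0, 1000, by = 2)
  ev <- data.frame(time_s = c(60, 120, 200), substance = c("H2O2", "H2O2",
                                                           "sample"),
                   final_conc = c(0.1, 0.1, NA), units = c("uM", "uM", ""))
  f <- 0.05 + 1e-6 * t + 0.5 * ((t >= 60) * 0.1 + (t >= 120) * 0.1)
  tr <- respirometryTrace(t, rep(180, length(t)), ev, 2, 2, fluo = f)
  cal <- fitBackgroundCalibration(tr)
  r <- h2o2Flux(tr, c(300, 600), cal)
  expect_equal(r$j_mass, 0, tolerance = 1e-9)
  expect_error(h2o2Flux(tr, c(4000, 4300), cal), "outside calibration span")
})

test_that("noiseless H2O2 fluxes round-trip through the full pipeline", {
  truth <- brainTruth()
  tr <- simulateAmrChannel(
    simulateRespirometryTrace(amrSchedule(), truth, "normoxic"), truth)
  res <- analyzeH2o2Trace(tr)
  got <- setNames(res$h2o2$j_mass, res$h2o2$state)
  expect_equal(got / truth@h2o2Flux[names(got)], setNames(rep(1, 6),
                                                          names(got)),
               tolerance = 0.02)
  # with decay switched off the round trip is essentially exact
  truth0 <- brainTruth(sensitivityDecay = 0)
  tr0 <- simulateAmrChannel(
    simulateRespirometryTrace(amrSchedule(), truth0, "normoxic"), truth0)
  res0 <- analyzeH2o2Trace(tr0)
  got0 <- setNames(res0$h2o2$j_mass, res0$h2o2$state)
  expect_equal(got0 / truth0@h2o2Flux[names(got0)],
               setNames(rep(1, 6), names(got0)), tolerance = 1e-6)
})

test_that("ignoring sensitivity decay biases fluxes low; correction removes it", {
  truth <- brainTruth()   # 10 %/h decay
  tr <- simulateAmrChannel(
    simulateRespirometryTrace(amrSchedule(), truth, "normoxic"), truth)
  cal0 <- fitBackgroundCalibration(tr)          # single early knot
  cal <- updateSensitivity(tr, cal0)
  w <- markStateWindows(tr)
  w <- w[w$state == "S_E", ]
  biased <- h2o2Flux(tr, w, cal0)$j_mass
  corrected <- h2o2Flux(tr, w, cal)$j_mass
  truthVal <- truth@h2o2Flux[["S_E"]]
  expect_lt(biased, truthVal * 0.99)            # visibly biased low
  expect_lt(abs(corrected / truthVal - 1), 0.01)
})

test_that("doubling the sensitivity halves the inferred concentration", {
  cal1 <- new("AmrCalibration", backgroundIntercept = 0, backgroundSlope = 0,
              knots = data.frame(time_s = 0, sensitivity = 0.5),
              residualSd = 0)
  cal2 <- new("AmrCalibration", backgroundIntercept = 0, backgroundSlope = 0,
              knots = data.frame(time_s = 0, sensitivity = 1),
              residualSd = 0)
  f <- 0.3
  expect_equal((f - backgroundAt(cal1, 10)) / sensitivityAt(cal1, 10),
               2 * (f - backgroundAt(cal2, 10)) / sensitivityAt(cal2, 10))
})

test_that("flux ratios are H2O2 per O2 with undefined entries where O2 <= 0", {
  o2 <- roxCorrect(massFluxTable(
    c(N_L = 100, N_P = 100, NS_P = 100, NS_E = 100, S_E = 100, ROX = 0)))
  h <- data.frame(state = c("N_L", "N_P", "ROX"), j_mass = c(1, 0, 0.5))
  r <- fluxRatio(h, o2)
  expect_equal(r$ratio[r$state == "N_L"], 0.01)
  expect_equal(r$percent[r$state == "N_L"], 1)
  expect_equal(r$ratio[r$state == "N_P"], 0)
  expect_true(is.na(r$ratio[r$state == "ROX"]))
})
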