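test_that("zero flux and zero noise give a constant O2 concentration", {
  tr <- simulateRespirometryTrace(suitSchedule(), zeroFluxTruth(), "air")
  o2 <- o2Concentration(tr)[!transientMask(tr)]
  expect_equal(o2, rep(200, length(o2)))
})

test_that("a known mass-specific flux produces the closed-form O2 slope", {
  # J_mass = 100 pmol/s/mg, V = 2 mL, m = 2 mg -> J_V = 100 pmol/s/mL
  # 1 uM = 1000 pmol/mL, so dc/dt = -0.1 uM/s exactly
  truth <- traceGroundTruth(
    o2Flux = c(N_L = 100, N_P = 100, NS_P = 100, NS_E = 100, S_E = 100,
               ROX = 100),
    o2NoiseSd = 0, fluoNoiseSd = 0)
  tr <- simulateRespirometryTrace(suitSchedule(), truth, "air",
                                  chamberVolume = 2, sampleMass = 2,
                                  uncouplerProfile = c(1, 1, 1))
  t <- traceTime(tr); o2 <- o2Concentration(tr)
  inside <- which(stateLabels(tr) == "N_L" & !transientMask(tr))
  slopes <- diff(o2[inside]) / diff(t[inside])
  expect_equal(slopes, rep(-0.1, length(slopes)), tolerance = 1e-12)
})

test_that("identical seeds reproduce identical traces", {
  truth <- brainTruth(o2NoiseSd = 0.5, fluoNoiseSd = 0.002)
  sch <- amrSchedule()
  a <- simulateAmrChannel(simulateRespirometryTrace(sch, truth, "air",
                                                    seed = 42), truth,
                          seed = 43)
  b <- simulateAmrChannel(simulateRespirometryTrace(sch, truth, "air",
                                                    seed = 42), truth,
                          seed = 43)
  expect_identical(o2Concentration(a), o2Concentration(b))
  expect_identical(fluorescence(a), fluorescence(b))
})

test_that("noiseless O2 removal between reoxygenations matches the flux integral", {
  truth <- brainTruth()
  tr <- simulateRespirometryTrace(suitSchedule(), truth, "normoxic",
                                  transientAmplitude = 0)
  t <- traceTime(tr); o2 <- o2Concentration(tr)
  ev <- traceEvents(tr)
  reox <- ev$time_s[ev$substance == "reoxygenation"]
  expect_gt(length(reox), 2)
  # within each between-reoxygenation stretch the total drop equals the
  # left-Riemann integral of the true volume flux / 1000
  lab <- stateLabels(tr)
  jm <- ifelse(lab %in% names(truth@o2Flux), truth@o2Flux[lab], 0)
  jm[lab == "pre"] <- 0
  # uncoupler steps scale NS_E by the default profile
  nU <- sum(traceEvents(tr)$substance == "U")
  uT <- ev$time_s[ev$substance == "U"]
  prof <- mitoflux:::.defaultUncouplerProfile(nU)
  for (i in seq_len(nU))
    jm[lab == "NS_E" & t >= uT[i] & (i == nU | t < uT[min(i + 1, nU)])] <-
      truth@o2Flux[["NS_E"]] * prof[i]
  jv <- jm * sampleMass(tr) / chamberVolume(tr) / 1000
  bounds <- sort(c(min(t), reox, max(t)))
  for (k in seq_len(length(bounds) - 1)) {
    i <- which(t >= bounds[k] & t < bounds[k + 1])
    if (length(i) < 5) next
    drop <- o2[i[1]] - o2[i[length(i)]]
    integral <- sum(jv[i[-length(i)]] * diff(t[i]))
    expect_equal(drop, integral, tolerance = 1e-6)
  }
})

test_that("oxygen depletion without reoxygenation names the offending state", {
  truth <- traceGroundTruth(
    o2Flux = c(N_L = 10, N_P = 500, NS_P = 500, NS_E = 500, S_E = 100,
               ROX = 2),
    o2NoiseSd = 0, fluoNoiseSd = 0)
  expect_error(
    simulateRespirometryTrace(suitSchedule(), truth, "normoxic",
                              autoReoxygenate = FALSE),
    "below 0.*flux too high")
})

test_that("fluorescence is flat between titrations without flux, drift or decay", {
  truth <- traceGroundTruth(
    o2Flux = setNames(rep(0, 6), suitStates()),
    backgroundSlope = 0, o2NoiseSd = 0, fluoNoiseSd = 0)
  tr <- simulateAmrChannel(
    simulateRespirometryTrace(amrSchedule(), truth, "air"), truth)
  f <- fluorescence(tr); t <- traceTime(tr)
  ev <- traceEvents(tr)
  tit <- ev$time_s[ev$substance == "H2O2"]
  seg <- f[t > tit[1] + 15 & t < tit[2] - 5 & !transientMask(tr)]
  expect_equal(seg, rep(seg[1], length(seg)))
})

test_that("titration step heights follow the sensitivity decay law", {
  # 10 %/h decay: a titration at t = 1 h steps 0.9 times the t = 0 step
  expect_equal(sensitivityDecayLaw(0.5, 0.1, 3600) /
                 sensitivityDecayLaw(0.5, 0.1, 0), 0.9)
  truth <- traceGroundTruth(
    o2Flux = setNames(rep(0, 6), suitStates()),
    sensitivityDecay = 0.1, backgroundSlope = 0,
    o2NoiseSd = 0, fluoNoiseSd = 0)
  tr <- simulateAmrChannel(
    simulateRespirometryTrace(amrSchedule(), truth, "air"), truth)
  f <- fluorescence(tr); t <- traceTime(tr)
  ev <- traceEvents(tr)
  tit <- ev$time_s[ev$substance == "H2O2"]
  step <- function(te) {
    pre <- max(f[t < te & t > te - 20 & !transientMask(tr)])
    post <- f[t > te + 12 & t < te + 30][1]
    post - pre
  }
  h <- vapply(tit, step, numeric(1))
  expect_equal(h / (0.1 * sensitivityDecayLaw(truth@sensitivity0, 0.1, tit)),
               rep(1, length(tit)), tolerance = 0.01)
})

test_that("noiseless calibration round-trips the configured sensitivity", {
  truth <- traceGroundTruth(
    o2Flux = setNames(rep(0, 6), suitStates()),
    sensitivity0 = 0.5, o2NoiseSd = 0, fluoNoiseSd = 0)
  tr <- simulateAmrChannel(
    simulateRespirometryTrace(amrSchedule(), truth, "air"), truth)
  cal <- fitBackgroundCalibration(tr)
  expect_equal(cal@knots$sensitivity[1], 0.5, tolerance = 1e-9)
  expect_equal(cal@backgroundSlope, truth@backgroundSlope, tolerance = 1e-9)
})

test_that("CS absorbance simulation inverts the activity equation", {
  flat <- simulateCsAbsorbance(0)
  expect_equal(flat$absorbance, rep(flat$absorbance[1], 13))
  expect_equal(nrow(flat), 13)
  expect_equal(diff(flat$time_s), rep(10, 12))
  # 0.1 IU/mg at default parameters implies slope 0.136 per minute
  a <- simulateCsAbsorbance(0.1)
  slope <- stats::coef(stats::lm(absorbance ~ time_s, a))[[2]] * 60
  expect_equal(slope, 0.136, tolerance = 1e-12)
  # noiseless round trip through the analysis side is exact
  r <- fitAbsorbanceSlope(a)
  expect_equal(csActivity(r$r_a), 0.1, tolerance = 1e-12)
})

test_that("simulated Ct tables recover configured fold changes exactly", {
  ct <- simulateQpcr(list(Mfn1 = c(Ctrl = 1, HPC = 1)), nPerGroup = 4)
  dd <- deltaDeltaCt(ct, controlGroup = "Ctrl")
  expect_equal(dd$perSample$dd_ct, rep(0, 8))
  ct2 <- simulateQpcr(list(Mfn1 = c(Ctrl = 1, HPC = 2)), nPerGroup = 4)
  dd2 <- deltaDeltaCt(ct2, controlGroup = "Ctrl")
  expect_equal(dd2$perGroup$mean_fold[dd2$perGroup$group == "HPC"], 2)
})

test_that("reference-gene preset mimics the reported Ct stability", {
  ct <- simulateQpcr(list(Mfn1 = c(Ctrl = 1, HPC = 1.5)),
                     nPerGroup = c(Ctrl = 41, HPC = 21),
                     ctNoiseSd = 0.7, refCtMean = 20, seed = 11)
  rs <- referenceStability(ct)
  expect_equal(rs$mean_ct, rep(20, 2), tolerance = 0.03)
  expect_equal(rs$sd_ct, rep(0.7, 2), tolerance = 0.35)
})

test_that("rendered images honour count, fusion and placement constraints", {
  blank <- renderCellImage(imageGroundTruth(0), seed = 1)
  expect_equal(max(blank$labels), 0)
  fused <- renderCellImage(imageGroundTruth(10, fusionDegree = 1,
                                            canvas = c(128, 128),
                                            cellRadii = c(50, 40)), seed = 2)
  expect_equal(max(fused$labels), 1)
  expect_error(
    renderCellImage(imageGroundTruth(200, canvas = c(64, 64),
                                     cellRadii = c(25, 20)), seed = 3),
    "cannot place")
  # determinism
  a <- renderCellImage(imageGroundTruth(15, canvas = c(96, 96),
                                        cellRadii = c(40, 32)), seed = 9)
  b <- renderCellImage(imageGroundTruth(15, canvas = c(96, 96),
                                        cellRadii = c(40, 32)), seed = 9)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
})
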