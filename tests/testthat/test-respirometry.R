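test_that("state windows are marked in SUIT order with safe margins", {
  tr <- simulateRespirometryTrace(suitSchedule(), brainTruth(), "air")
  w <- markStateWindows(tr)
  expect_equal(w$state, suitStates())
  expect_true(all(diff(w$start_s) > 0))
  expect_true(all(w$end_s > w$start_s))
  # each window ends at least 30 s before the next titration event
  ev <- traceEvents(tr)
  for (i in seq_len(nrow(w))) {
    nxt <- ev$time_s[ev$time_s > w$start_s[i] &
                       !(ev$substance %in% c("reoxygenation", "H2O2"))]
    if (length(nxt)) expect_gte(min(nxt) - w$end_s[i], 30)
  }
})

test_that("a schedule without antimycin A cannot mark the ROX state", {
  sch <- suitSchedule()
  sch <- sch[sch$substance != "Ama", ]
  truth <- brainTruth()
  tr <- simulateRespirometryTrace(sch, truth, "air",
                                  duration = max(sch$time_s) + 200)
  expect_error(markStateWindows(tr), "ROX.*missing event Ama")
})

test_that("volume flux is the negative concentration slope in pmol/s/mL", {
  ev <- data.frame(time_s = 1, substance = "sample", final_conc = NA,
                   units = "")
  t <- seq(0, 300, by = 2)
  flat <- respirometryTrace(t, rep(180, length(t)), ev, 2, 2)
  expect_equal(computeVolumeFlux(flat, c(50, 250))$j_v, 0)
  ramp <- respirometryTrace(t, 200 - 0.1 * t, ev, 2, 2)
  f <- computeVolumeFlux(ramp, c(50, 250))
  expect_equal(f$j_v, 100, tolerance = 1e-9)
  expect_error(computeVolumeFlux(ramp, c(50, 60)), "usable samples")
  # optional instrumental O2 background correction J0 = a + b * c
  fb <- computeVolumeFlux(ramp, c(50, 250),
                          instrumentBackground = c(4, 0.02))
  cbar <- mean((200 - 0.1 * t)[t >= 50 & t <= 250])
  expect_equal(fb$j_v, 100 - 4 - 0.02 * cbar, tolerance = 1e-9)
})

test_that("a noisy window recovers the true slope within 3 standard errors", {
  set.seed(7)
  t <- seq(0, 180, by = 2)
  ev <- data.frame(time_s = 1, substance = "sample", final_conc = NA,
                   units = "")
  tr <- respirometryTrace(t, 200 - 0.05 * t + rnorm(length(t), 0, 0.5),
                          ev, 2, 2)
  f <- computeVolumeFlux(tr, c(0, 180))
  expect_lt(abs(f$j_v - 50), 3 * f$se)
})

test_that("normalization converts volume flux to mass- and CS-specific flux", {
  ft <- normalizeFluxes(c(N_P = 100), chamberVolume = 2, sampleMass = 2,
                        csUnits = 0.2)
  tb <- fluxes(ft)
  expect_equal(tb$j_mass, 100)        # J_V * V / m
  expect_equal(tb$j_cs, 1000)         # J_V * V / IU
  # numerically equal volume and mass leave j_mass = j_v
  ft2 <- normalizeFluxes(c(N_P = 37), chamberVolume = 1.7, sampleMass = 1.7)
  expect_equal(fluxes(ft2)$j_mass, fluxes(ft2)$j_v)
  expect_error(normalizeFluxes(c(N_P = 1), 0, 2), "must be > 0")
  expect_error(normalizeFluxes(c(N_P = 1), 2, 2, csUnits = -1), "csUnits")
})

test_that("Rox correction subtracts ROX everywhere, flags negatives, and is idempotent", {
  ft <- massFluxTable(c(N_L = 10, N_P = 50, NS_P = 80, NS_E = 100,
                        S_E = 1, ROX = 2), csUnits = 0.2)
  expect_warning(corr <- roxCorrect(ft), "negative")
  tb <- fluxes(corr)
  expect_equal(tb$j_mass[tb$state == "N_L"], 8)
  expect_equal(tb$j_mass[tb$state == "ROX"], 0)
  expect_equal(tb$j_cs[tb$state == "ROX"], 0)
  expect_true(tb$negative[tb$state == "S_E"])
  expect_true(isRoxCorrected(corr))
  again <- suppressWarnings(roxCorrect(corr))
  expect_equal(fluxes(again), tb)
  noRox <- massFluxTable(c(N_L = 10, NS_E = 100))
  expect_error(roxCorrect(noRox), "no ROX state")
})

test_that("Rox correction commutes with normalization", {
  jv <- c(N_L = 12, N_P = 50, NS_P = 88, NS_E = 104, S_E = 51, ROX = 4)
  a <- fluxes(roxCorrect(normalizeFluxes(jv, 2, 1.6, csUnits = 0.25)))
  b <- fluxes(normalizeFluxes(jv - jv[["ROX"]], 2, 1.6, csUnits = 0.25))
  for (col in c("j_v", "j_mass", "j_cs"))
    expect_equal(a[[col]], b[[col]])
})

test_that("flux control ratios normalize to NS_E and are scale invariant", {
  jm <- c(N_L = 10, N_P = 50, NS_P = 80, NS_E = 100, S_E = 60, ROX = 0)
  fcr <- fluxControlRatios(massFluxTable(jm))
  expect_identical(unname(fcr["NS_E"]), 1)
  expect_equal(unname(fcr["N_L"]), 0.1)
  expect_equal(fcr, fluxControlRatios(massFluxTable(jm / 2)))
  expect_error(fluxControlRatios(massFluxTable(c(N_L = 1, NS_E = 0))),
               "NS_E")
})

test_that("control efficiencies reproduce their definitional endpoints", {
  # P = E: phosphorylation system does not limit OXPHOS capacity
  eff <- controlEfficiencies(massFluxTable(
    c(N_L = 20, N_P = 80, NS_P = 100, NS_E = 100, S_E = 60, ROX = 0)))
  expect_identical(unname(eff["e_p"]), 0)
  # zero LEAK: fully coupled system
  eff2 <- controlEfficiencies(massFluxTable(
    c(N_L = 0, N_P = 100, NS_P = 110, NS_E = 120, S_E = 60, ROX = 0)))
  expect_identical(unname(eff2["p_l"]), 1)
  # LEAK equals OXPHOS: no coupling
  eff3 <- controlEfficiencies(massFluxTable(
    c(N_L = 50, N_P = 50, NS_P = 60, NS_E = 70, S_E = 30, ROX = 0)))
  expect_identical(unname(eff3["p_l"]), 0)
  # invariance under uniform rescaling
  jm <- c(N_L = 11, N_P = 47, NS_P = 86, NS_E = 104, S_E = 52, ROX = 0)
  expect_equal(controlEfficiencies(massFluxTable(jm)),
               controlEfficiencies(massFluxTable(jm * 3.7)))
  expect_error(controlEfficiencies(massFluxTable(
    c(N_L = 1, N_P = 0, NS_P = 1, NS_E = 1))), "N_P")
})

test_that("uncoupler optimum picks the maximal step and flags under-titration", {
  o <- uncouplerOptimum(c(80, 95, 90))
  expect_equal(o$index, 2)
  expect_equal(o$flux, 95)
  expect_false(o$underTitration)
  expect_equal(uncouplerOptimum(88)$index, 1)
  expect_equal(uncouplerOptimum(c(90, 90, 85))$index, 1)  # tie -> lower conc
  rising <- uncouplerOptimum(c(80, 90, 100))
  expect_equal(rising$index, 3)
  expect_true(rising$underTitration)
})

test_that("cytochrome c test flags outer-membrane damage above threshold", {
  intact <- cytochromeCTest(100, 100)
  expect_equal(intact$relativeIncrease, 0)
  expect_true(intact$intact)
  damaged <- cytochromeCTest(100, 130)
  expect_equal(damaged$relativeIncrease, 0.3)
  expect_false(damaged$intact)
  lower <- cytochromeCTest(100, 90)
  expect_equal(lower$relativeIncrease, -0.1)
  expect_true(lower$intact)
  expect_error(cytochromeCTest(0, 10), "> 0")
})

test_that("noiseless traces are analyzed back to their exact ground truth", {
  truth <- brainTruth()
  for (reg in c("air", "normoxic")) {
    res <- analyzeTrace(simulateRespirometryTrace(suitSchedule(), truth, reg))
    tb <- fluxes(res$fluxTable)
    tc <- trueCorrected(truth)
    expect_equal(setNames(tb$j_mass, tb$state), tc[tb$state],
                 tolerance = 1e-9)
    expect_identical(unname(res$fcr["NS_E"]), 1)
    expect_equal(unname(res$efficiencies["e_p"]),
                 1 - tc[["NS_P"]] / tc[["NS_E"]], tolerance = 1e-9)
    expect_equal(res$uncoupler$index, 2)
    expect_true(res$cytochromeC$intact)
  }
})

test_that("a damaged outer membrane is detected from the trace", {
  truth <- brainTruth()
  tr <- simulateRespirometryTrace(suitSchedule(), truth, "air",
                                  cytochromeCEffect = 1.3)
  res <- analyzeTrace(tr)
  expect_false(res$cytochromeC$intact)
  expect_equal(res$cytochromeC$relativeIncrease, 0.3, tolerance = 1e-6)
})
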