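# Concentration scaling, conversion, rates, synergism and distributions.

test_that("actual glucose count evaluates the macroscopic scaling", {
  rxn <- reactionSpec(wSample = 100, solidFraction = 0.1,
                      celluloseFraction = 1, vActual = 100)
  expect_equal(actualGlucoseCount(rxn), 100 * 0.1 * 6.023e23 / 162)
  expect_equal(actualGlucoseCount(rxn), 3.718e22, tolerance = 1e-4)
  # linear in sample weight; zero solids give zero
  expect_equal(actualGlucoseCount(reactionSpec(200, 0.1, 1, 100)),
               2 * actualGlucoseCount(rxn))
  expect_equal(actualGlucoseCount(reactionSpec(100, 0, 1, 100)), 0)
})

test_that("concentrations match the hand mass balance to 1e-9 relative", {
  # 1000 glucose molecules out of 1e6 simulated units at 100 g/L glucan:
  # 0.1% of the anhydro mass, hydrated by 180/162 -> 0.1111... g/L
  toy <- makeToyAssembly(dp = 10)
  res <- runHydrolysis(toy, enzymeSystem(enzymeSpec("BG", iuPerG = 1e-9)),
                       durationMin = 1, seed = 1,
                       initialPool = c(1000, 500, 0, 0, 0, 0))
  res@assembly@gSim <- 1e6  # scale denominator to the documented case
  rxn <- reactionSpec(100, 0.1, 1, 100)
  cp <- concentrationProfiles(res, rxn)
  expGlu <- 1000 * (actualGlucoseCount(rxn) / 1e6) * 180 / 6.023e23 * 1000 / 100
  expect_equal(cp$cGlu[1], expGlu, tolerance = 1e-9)
  expect_equal(cp$cGlu[1], 0.111, tolerance = 2e-3)
  expG2 <- 500 * (actualGlucoseCount(rxn) / 1e6) * 342 / 6.023e23 * 1000 / 100
  expect_equal(cp$cG2[1], expG2, tolerance = 1e-9)
  expect_equal(cp$cG2[1], 0.1056, tolerance = 1e-3)
})

test_that("conversion spans 0 to 100 and equals the solubilized fraction", {
  toy <- makeToyAssembly(dp = 10)
  res <- runHydrolysis(toy, cbhNoDesorb(loading = 400), durationMin = 200,
                       seed = 2)
  conv <- celluloseConversion(res, at = "trajectory")
  expect_equal(conv[1], 0)
  expect_equal(conv[length(conv)], 100)
  tr <- trajectory(res)
  expect_equal(conv, 100 * (1 - tr$insolubleUnits / glucoseCount(toy)))
})

test_that("hydrolysis rate is the windowed loss of insoluble cellulose", {
  toy <- makeToyAssembly(dp = 40)
  rxn <- standardReaction(100)
  res <- runHydrolysis(toy, enzymePreset("CBHI", 50), durationMin = 240,
                       seed = 4, recordInterval = 30)
  hr <- hydrolysisRate(res, rxn, windowMin = 60)
  cp <- concentrationProfiles(res, rxn)
  # manual first window: -(delta cG6plus) * V/1000 per hour
  manual <- -(cp$cG6plus[3] - cp$cG6plus[1]) * rxn@vActual / 1000
  expect_equal(hr$rate[1], manual)
  expect_true(all(hr$rate >= 0))
  # no enzymes: all-zero rate series
  none <- suppressWarnings(runHydrolysis(toy, enzymeSystem(),
                                         durationMin = 120, seed = 1,
                                         recordInterval = 30))
  expect_true(all(hydrolysisRate(none, rxn)$rate == 0))
  expect_error(hydrolysisRate(res, rxn, windowMin = 45), "multiple")
})

test_that("degree of synergism is the mixture/sum conversion ratio", {
  expect_equal(degreeOfSynergism(20, c(10, 10)), 1)
  expect_equal(degreeOfSynergism(36, c(10, 10)), 1.8)
  expect_error(degreeOfSynergism(10, c(0, 0)), "zero")
})

test_that("chain-length distribution conserves mass and tracks cleavage", {
  toy <- makeToyAssembly(dp = 300, maxUnits = 11000)
  d0 <- chainLengthDistribution(toy)
  expect_equal(d0$dp, 300)
  expect_equal(d0$count, 36)
  res <- runHydrolysis(toy, enzymeSystem(enzymePreset("EGI", 30),
                                         enzymePreset("CBHI", 30)),
                       durationMin = 300, seed = 5)
  d1 <- chainLengthDistribution(res)
  expect_equal(sum(d1$dp * d1$count), glucoseCount(toy))
  expect_gt(nrow(d1), 1)
  # CBH-only: soluble mass flows almost exclusively into the DP-2 bin
  resC <- runHydrolysis(toy, enzymePreset("CBHI", 30), durationMin = 600,
                        seed = 5)
  dC <- chainLengthDistribution(resC)
  sol <- dC[dC$phase == "soluble", ]
  expect_gt(sol$count[sol$dp == 2] * 2, 0.8 * sum(sol$dp * sol$count))
})

test_that("end-of-run crystallinity uses the insoluble remainder only", {
  toy <- makeToyAssembly(dp = 40, bands = cbind(0, 20))
  res <- runHydrolysis(toy, enzymePreset("EGI", 40), durationMin = 400,
                       seed = 7)
  tr <- tail(trajectory(res), 1)
  expect_equal(crystallinityIndex(res),
               tr$crystallineInsoluble / tr$insolubleUnits)
  # fully solubilized substrate: undefined, NA with a warning
  gone <- runHydrolysis(makeToyAssembly(dp = 10), cbhNoDesorb(loading = 400),
                        durationMin = 200, seed = 2)
  expect_warning(val <- crystallinityIndex(gone), "undefined")
  expect_true(is.na(val))
})
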