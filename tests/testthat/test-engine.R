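# Monte Carlo engine mechanics: determinism, conservation, class-specific
# action patterns, solubilization and layer exposure.

test_that("identical inputs and seed give identical trajectories", {
  toy <- toyAmorphous(30)
  sys <- enzymeSystem(enzymePreset("EGI", 20), cbhNoDesorb())
  a <- runHydrolysis(toy, sys, durationMin = 120, seed = 11)
  b <- runHydrolysis(toy, sys, durationMin = 120, seed = 11)
  expect_identical(trajectory(a), trajectory(b))
  expect_identical(a@finalState$removed, b@finalState$removed)
  expect_identical(eventTallies(a), eventTallies(b))
  c <- runHydrolysis(toy, sys, durationMin = 120, seed = 12)
  expect_false(identical(trajectory(a), trajectory(c)))
})

test_that("glucose units are conserved and conversion is monotone", {
  toy <- makeToyAssembly(dp = 40, bands = cbind(10, 30))
  sys <- enzymeSystem(enzymePreset("EGI", 30), enzymePreset("CBHI", 30),
                      enzymePreset("BG", iuPerG = 500))
  res <- runHydrolysis(toy, sys, durationMin = 400, seed = 5,
                       recordInterval = 20)
  expectConserved(res)
  conv <- celluloseConversion(res, at = "trajectory")
  expect_true(all(diff(conv) >= 0))
  # each internal cleavage raises the fragment/molecule count by one:
  # fragments + soluble molecules never decrease below the initial chain count
  tr <- trajectory(res)
  nMol <- tr$fragments + tr$nGlu + tr$nG2 + tr$nG3 + tr$nG4 + tr$nG5 + tr$nG6
  expect_true(all(diff(nMol) >= 0))
})

test_that("processive CBH I releases cellobiose pairs down to a DP-4 tail", {
  # DP-10 chains, desorption off: 3 cellobiose + one soluble G4 per chain
  toy <- makeToyAssembly(dp = 10)
  res <- runHydrolysis(toy, cbhNoDesorb(loading = 400), durationMin = 200,
                       seed = 2)
  tr <- tail(trajectory(res), 1)
  expect_equal(tr$conversion, 100)
  expect_equal(tr$nG2, 36 * 3)
  expect_equal(tr$nG4, 36)
  expect_equal(tr$nGlu + tr$nG3 + tr$nG5 + tr$nG6, 0)
})

test_that("non-processive CBH II releases exactly one cellobiose per binding", {
  toy <- makeToyAssembly(dp = 20)
  spec <- cbhNoDesorb("CBH2_nonproc", loading = 50, activity = 1.6)
  res <- runHydrolysis(toy, spec, durationMin = 30, seed = 4)
  tl <- eventTallies(res)
  tr <- tail(trajectory(res), 1)
  expect_equal(tr$nG2, tl[1, "productive"])
  expect_gt(tr$nG2, 0)
})

test_that("exo attack respects chain-end polarity", {
  # CBH I consumes from the reducing end (axial 0): after a partial run on
  # DP-20 chains, surviving fragments retain the chain's last axial position
  # (non-reducing end) and lose the first
  toy <- makeToyAssembly(dp = 20)
  res <- runHydrolysis(toy, cbhNoDesorb(loading = 20), durationMin = 60,
                       seed = 9)
  sn <- substrateSnapshot(res)
  eaten <- sn$soluble & sn$axial == 0
  intactNR <- !sn$soluble & sn$axial == 19
  expect_gt(sum(eaten), 0)
  # some chains partially consumed: their non-reducing tail survives
  partly <- unique(sn$chain[eaten])
  expect_true(any(intactNR[sn$chain %in% partly]))
  # mirrored for CBH II on the non-reducing end
  res2 <- runHydrolysis(toy, cbhNoDesorb("CBH2_proc", loading = 20,
                                         activity = 1.6),
                        durationMin = 60, seed = 9)
  sn2 <- substrateSnapshot(res2)
  expect_gt(sum(sn2$soluble & sn2$axial == 19), 0)
})

test_that("beta-glucosidase hydrolyzes the soluble pool and is glucose-inhibited", {
  toy <- makeToyAssembly(dp = 10)
  bg <- enzymeSpec("BG", iuPerG = 3000)
  # cellobiose -> 2 glucose
  res <- runHydrolysis(toy, bg, durationMin = 240, seed = 1,
                       initialPool = c(0, 500, 0, 0, 0, 0))
  tr <- tail(trajectory(res), 1)
  expect_equal(tr$nGlu, 1000)
  expect_equal(tr$nG2, 0)
  # G6 -> G5 + glucose single-cut chain
  res6 <- runHydrolysis(toy, bg, durationMin = 600, seed = 1,
                        initialPool = c(0, 0, 0, 0, 0, 200))
  tr6 <- tail(trajectory(res6), 1)
  expect_equal(tr6$nGlu, 1200)  # fully hydrolyzed eventually
  # glucose-only pool: the whole budget is consumed by inhibitor encounters
  resG <- runHydrolysis(toy, bg, durationMin = 30, seed = 1,
                        initialPool = c(400, 0, 0, 0, 0, 0))
  tl <- eventTallies(resG)
  expect_equal(tl[1, "productive"], 0)
  expect_gt(tl[1, "inhibited"], 0)
  expect_equal(tail(trajectory(resG), 1)$nGlu, 400)
})

test_that("enzymes ignore soluble oligomers below their minimum length", {
  toy <- makeToyAssembly(dp = 10)
  # footprint larger than any chain disables lattice action, isolating the
  # soluble-pool behaviour
  noLattice <- list(footprint = 1000)
  eg <- enzymeSpec("EG_nonproc_CBM", loading = 1e3, activity = 0.4,
                   params = noLattice)
  # EG does not touch DP-3 oligomers ...
  egOnly <- runHydrolysis(toy, eg, durationMin = 20, seed = 3,
                          initialPool = c(0, 0, 300, 0, 0, 0))
  expect_equal(tail(trajectory(egOnly), 1)$nG3, 300)
  # ... but does cut DP-4 (cellotetraose falls under endoglucanase action)
  egG4 <- runHydrolysis(toy, eg, durationMin = 20, seed = 3,
                        initialPool = c(0, 0, 0, 300, 0, 0))
  expect_lt(tail(trajectory(egG4), 1)$nG4, 300)
  # CBH does not act below DP 5
  cbh <- cbhNoDesorb(loading = 50, params = noLattice)
  resC <- runHydrolysis(toy, cbh, durationMin = 10, seed = 3,
                        initialPool = c(0, 0, 0, 300, 0, 0))
  expect_equal(tail(trajectory(resC), 1)$nG4, 300)
  # CBH cuts a DP-5 oligomer once: cellobiose + cellotriose
  resC5 <- runHydrolysis(toy, cbh, durationMin = 30, seed = 3,
                         initialPool = c(0, 0, 0, 0, 300, 0))
  trC5 <- tail(trajectory(resC5), 1)
  expect_gt(trC5$nG2, 0)
  expect_equal(trC5$nG2, trC5$nG3)
  expect_equal(trC5$nG2, 300 - trC5$nG5)
})

test_that("solubilizing a surface chain exposes the layer beneath", {
  # strong CBH consumes far more than the initially accessible surface
  # (20 of 36 chains per elementary fibril), which requires layer exposure
  toy <- makeToyAssembly(dp = 10)
  res <- runHydrolysis(toy, cbhNoDesorb(loading = 400), durationMin = 200,
                       seed = 6)
  expect_gt(celluloseConversion(res), 100 * 20 / 36)
  # and the final snapshot marks previously buried units as EF surface
  mid <- runHydrolysis(toy, cbhNoDesorb(loading = 30), durationMin = 30,
                       seed = 6)
  sn <- substrateSnapshot(mid)
  ch <- mid@assembly@chains
  buriedChains <- which(ch$depth > 0) - 1L
  expect_gt(sum(sn$efSurface[sn$chain %in% buriedChains & !sn$soluble]), 0)
})

test_that("empty enzyme systems warn and leave the substrate untouched", {
  toy <- toyAmorphous(10)
  expect_warning(res <- runHydrolysis(toy, enzymeSystem(), durationMin = 5,
                                      seed = 1), "empty")
  expect_equal(celluloseConversion(res), 0)
})

test_that("seeded soluble pools participate in candidate draws (inhibition)", {
  # cellobiose-rich pool throttles CBH I: fewer productive events than the
  # same run without the pool
  toy <- makeToyAssembly(dp = 10)
  free <- runHydrolysis(toy, enzymePreset("CBHI", 20), durationMin = 60,
                        seed = 8)
  inhib <- runHydrolysis(toy, enzymePreset("CBHI", 20), durationMin = 60,
                         seed = 8, initialPool = c(0, 5000, 0, 0, 0, 0))
  expect_lt(eventTallies(inhib)[1, "productive"],
            eventTallies(free)[1, "productive"])
  expect_gt(eventTallies(inhib)[1, "inhibited"], 0)
})
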