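# Substrate construction: band layout, censuses, end fractions, determinism.

test_that("chain-end fraction follows 100/DP for uniform substrates", {
  cases <- list(list(dp = 300, expect = 0.33),
                list(dp = 2000, expect = 0.05))
  for (cs in cases) {
    toy <- makeToyAssembly(dp = cs$dp, maxUnits = 1e5)
    expect_equal(chainEndFraction(toy, "reducing"), 100 / cs$dp,
                 tolerance = 1e-12)
    expect_equal(round(chainEndFraction(toy, "reducing"), 2), cs$expect)
    expect_equal(chainEndFraction(toy, "nonreducing"),
                 chainEndFraction(toy, "reducing"))
  }
  # every other unit is a reducing end at DP 2
  expect_equal(chainEndFraction(makeToyAssembly(dp = 2)), 50)
})

test_that("crystallinity index counts crystalline over insoluble units", {
  expect_equal(crystallinityIndex(makeToyAssembly(dp = 200, bands = TRUE)), 1)
  expect_equal(crystallinityIndex(
    makeToyAssembly(dp = 400, bands = cbind(100, 300))), 0.5)
  av <- buildSubstrate("avicel", seed = 1)
  cri <- crystallinityIndex(av)
  expect_gte(cri, 0.5)
  expect_lte(cri, 0.6)
})

test_that("preset builds honour size, DP range and band end-coverage", {
  av <- buildSubstrate("avicel", seed = 2)
  expect_gte(glucoseCount(av), 1e6)
  expect_equal(av@nMicrofibrils, 5L)
  expect_true(all(av@chains$dp >= 250 & av@chains$dp <= 300))
  expect_equal(sum(av@chains$dp), glucoseCount(av))
  # both axial ends of every chain lie in crystalline bands
  cry <- as.integer(av@crystalline)
  starts <- av@chains$startUid + 1
  ends <- av@chains$startUid + av@chains$dp
  expect_true(all(cry[starts] == 1))
  expect_true(all(cry[ends] == 1))
})

test_that("infeasible crystallinity targets error; crowded bands warn", {
  expect_error(buildSubstrate(dpRange = c(400, 400), criRange = c(0.001, 0.002),
                              nMicrofibrils = 1, seed = 1),
               "crystalline")
  # too little amorphous material to separate the requested bands
  expect_warning(cellulosim:::makeBandMask(601, 600), "band count")
})

test_that("builds are bit-identical for a fixed seed and differ across seeds", {
  a <- buildSubstrate("avicel", seed = 7)
  b <- buildSubstrate("avicel", seed = 7)
  expect_identical(a@chains, b@chains)
  expect_identical(a@crystalline, b@crystalline)
  d <- buildSubstrate("avicel", seed = 8)
  expect_false(identical(a@crystalline, d@crystalline))
})

test_that("surface census matches direct counts", {
  toy <- makeToyAssembly(dp = 10)
  cen <- surfaceCensus(toy)
  expect_equal(cen$nR, 36)
  expect_equal(cen$nNR, 36)
  # 20 perimeter chains of a 6x6 lattice
  expect_equal(cen$nS, 20 * 10)
  av <- buildSubstrate("avicel", seed = 3)
  cenAv <- surfaceCensus(av)
  ch <- av@chains
  for (j in seq_len(av@nMicrofibrils)) {
    expect_equal(cenAv$nS[j], sum(ch$dp[ch$mf == j & ch$depth == 0]))
    expect_equal(cenAv$nR[j], sum(ch$mf == j))
  }
})

test_that("snapshot attributes are internally consistent", {
  toy <- makeToyAssembly(dp = 12, bands = cbind(0, 6))
  sn <- substrateSnapshot(toy)
  expect_equal(nrow(sn), glucoseCount(toy))
  # one reducing and one non-reducing end per chain
  expect_equal(sum(sn$endState == 1), 36)
  expect_equal(sum(sn$endState == -1), 36)
  # distance to the non-reducing end is 0 exactly at non-reducing ends
  expect_true(all((sn$distanceNR == 0) == (sn$endState == -1)))
  # walking distanceNR from any unit lands on the chain's non-reducing end
  expect_true(all(sn$axial + sn$distanceNR == 12 - 1))
  # serial numbers unique and row-major contiguous
  expect_identical(sn$uid, seq_len(nrow(sn)) - 1L)
  # band [0,6): first six axial positions crystalline
  expect_true(all(sn$crystalline == (sn$axial < 6)))
})

test_that("elementary fibril lattice exposes layers consistently", {
  lat <- cellulosim:::efLattice()
  expect_equal(sum(lat$depth == 0), 20)
  expect_equal(sum(lat$depth == 1), 12)
  expect_equal(sum(lat$depth == 2), 4)
  # every buried chain has a cover one layer shallower
  buried <- which(lat$depth > 0)
  expect_true(all(!is.na(lat$cover[buried])))
  expect_true(all(lat$depth[lat$cover[buried]] == lat$depth[buried] - 1))
  # cover mapping is injective, so 'below' is well-defined
  expect_false(any(duplicated(lat$cover[buried])))
})

test_that("toy assemblies reject non-exhaustive sizes", {
  expect_error(makeToyAssembly(dp = 5000), "exceeds")
})
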