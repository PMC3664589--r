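# Engine vs independent enumeration oracle: mean productive events per minute
# over replicate single-minute runs must match the exhaustive expectation
# within 3 standard errors (inhibition costs neutralized, desorption off,
# non-processive classes).

oracleSpec <- function(cls, loading, activity, extra = list()) {
  enzymeSpec(cls, loading = loading, activity = activity,
             params = c(unitCounters,
                        list(pDesorbAmorphous = 0, pDesorbCrystalline = 0),
                        extra))
}

engineMeanProductive <- function(assembly, spec, nRep = 200, pool = NULL) {
  vapply(seq_len(nRep), function(k) {
    res <- runHydrolysis(assembly, spec, durationMin = 1, seed = 1e6 + k,
                         recordInterval = 1, initialPool = pool)
    unname(eventTallies(res)[1, "productive"])
  }, numeric(1))
}

expectOracleAgreement <- function(assembly, spec, pool6 = NULL, nRep = 200) {
  expected <- bruteForceEventExpectation(assembly, spec, pool = pool6)
  obs <- engineMeanProductive(assembly, spec, nRep = nRep, pool = pool6)
  se <- stats::sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), max(3 * se, 0.05 * expected + 1e-9))
  invisible(c(expected = expected, observed = mean(obs)))
}

test_that("endoglucanase acceptance matches enumeration on varied toys", {
  configs <- list(
    list(toy = makeToyAssembly(dp = 60), loading = 10),              # amorphous
    list(toy = makeToyAssembly(dp = 60, bands = cbind(0, 30)),       # half cryst
         loading = 10),
    list(toy = makeToyAssembly(dp = 60, bands = TRUE), loading = 10),# all cryst
    list(toy = makeToyAssembly(dp = 60, efRows = 2, efCols = 2),     # buried mix
         loading = 10),
    list(toy = makeToyAssembly(dp = 25), loading = 60))               # short chains
  for (cf in configs) {
    spec <- oracleSpec("EG_nonproc_CBM", cf$loading, 0.4)
    expectOracleAgreement(cf$toy, spec)
  }
  # soluble candidates dilute the list and add their own acceptance
  spec <- oracleSpec("EG_nonproc_CBM", 10, 0.4)
  expectOracleAgreement(makeToyAssembly(dp = 60), spec,
                        pool6 = c(0, 0, 0, 0, 300, 300))
})

test_that("cellobiohydrolase acceptance matches enumeration on varied toys", {
  cbh1 <- function(l, extra = list()) oracleSpec("CBH1_nonproc", l, 0.8, extra)
  cbh2 <- function(l, extra = list()) oracleSpec("CBH2_nonproc", l, 1.6, extra)
  configs <- list(
    list(toy = makeToyAssembly(dp = 40), spec = cbh1(200)),
    list(toy = makeToyAssembly(dp = 40, efRows = 2, efCols = 2),
         spec = cbh1(200)),
    # long chains: inverse chain-length preference engages (prefDp = 20)
    list(toy = makeToyAssembly(dp = 40), spec = cbh1(200, list(prefChainDp = 20))),
    list(toy = makeToyAssembly(dp = 40), spec = cbh2(100)),
    list(toy = makeToyAssembly(dp = 40, efRows = 2, efCols = 2),
         spec = cbh2(100)),
    list(toy = makeToyAssembly(dp = 40), spec = cbh2(100, list(prefChainDp = 20))))
  for (cf in configs) expectOracleAgreement(cf$toy, cf$spec, nRep = 300)
  # soluble oligomers accepted with pSoluble
  expectOracleAgreement(makeToyAssembly(dp = 40), cbh1(200),
                        pool6 = c(0, 0, 0, 0, 500, 0), nRep = 300)
})

test_that("beta-glucosidase rates match enumeration over pool compositions", {
  toy <- makeToyAssembly(dp = 10)
  pools <- list(c(0, 400, 0, 0, 0, 0),
                c(200, 200, 0, 0, 0, 0),
                c(0, 0, 100, 100, 100, 100),
                c(300, 50, 50, 0, 0, 0),
                c(50, 50, 50, 50, 50, 50))
  spec <- oracleSpec("BG", 0, 0)
  spec@iuPerG <- 50
  for (p in pools) expectOracleAgreement(toy, spec, pool6 = p)
})

test_that("oracle edge cases: saturating acceptance and empty lists", {
  toy <- makeToyAssembly(dp = 30)
  # all candidates acceptable with probability ~1 on the all-surface toy:
  # expectation equals budget * mean acceptance, close to the budget scale
  spec <- oracleSpec("BG", 0, 0); spec@iuPerG <- 20
  expect_equal(bruteForceEventExpectation(toy, spec,
                                          pool = c(0, 100, 0, 0, 0, 0)),
               maxBondsPerMinute(spec, glucoseCount(toy)))
  expect_equal(bruteForceEventExpectation(toy, spec), 0)  # empty pool
  expect_error(bruteForceEventExpectation(
    buildSubstrate(dpRange = c(300, 300), criRange = c(0.5, 0.6),
                   nMicrofibrils = 1, seed = 1),
    spec), "toy-size")
  expect_error(bruteForceEventExpectation(toy, enzymePreset("CBHI", 10)),
               "non-processive")
})
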