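# Shared fixtures. Heavy full-scale runs are computed lazily and cached so
# several test files can share them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# small all-amorphous single-EF toy
toyAmorphous <- function(dp = 30) makeToyAssembly(dp = dp)

# oracle-comparison parameters: every outcome costs one counter unit
unitCounters <- list(nNb = 1, nNp = 1, nInhibG = 1, nInhibG2 = 1.01)

# CBH spec with desorption disabled and near-neutral inhibition counters:
# processive runs complete, so alternate-cleavage arithmetic is exact
cbhNoDesorb <- function(cls = "CBH1_proc", loading = 100, activity = 0.8,
                        params = list())
  enzymeSpec(cls, loading = loading, activity = activity,
             params = c(list(pDesorbAmorphous = 0, pDesorbCrystalline = 0),
                        params,
                        unitCounters[setdiff(names(unitCounters),
                                             names(params))]))

# glucose-unit conservation over a whole trajectory: insoluble units plus
# mass-weighted soluble counts stay constant at every recorded interval
expectConserved <- function(res) {
  tr <- trajectory(res)
  total <- tr$insolubleUnits + tr$nGlu + 2 * tr$nG2 + 3 * tr$nG3 +
    4 * tr$nG4 + 5 * tr$nG5 + 6 * tr$nG6
  expect_true(all(total == total[1]))
  invisible(total)
}

# full-scale study-condition runs used by the acceptance criteria; one cache
# entry per (substrate, system, seed)
accAssembly <- function(substrate, seed) {
  key <- paste0("asm_", substrate, "_", seed)
  cached(key, switch(substrate,
    avicel = buildSubstrate("avicel", seed = seed),
    cotton = buildSubstrate("cotton", seed = seed, nMicrofibrils = 1,
                            minTotal = NA),
    bacterial_cellulose = buildSubstrate("bacterial_cellulose", seed = seed,
                                         nMicrofibrils = 1, minTotal = NA),
    filter_paper = buildSubstrate("filter_paper", seed = seed)))
}

accSystem <- function(name) {
  switch(name,
    EG = enzymeSystem(enzymePreset("EGI", 10)),
    CBH1 = enzymeSystem(enzymePreset("CBHI", 10)),
    CBH2 = enzymeSystem(enzymePreset("CBHII", 10)),
    EG_CBH1 = enzymeSystem(enzymePreset("EGI", 10), enzymePreset("CBHI", 10)),
    CBH1_BG = enzymeSystem(enzymePreset("CBHI", 10),
                           enzymePreset("BG", iuPerG = 200)),
    CBH2_BG = enzymeSystem(enzymePreset("CBHII", 10),
                           enzymePreset("BG", iuPerG = 200)),
    trees = treeseiMixture(20),
    trees_BG = treeseiMixture(20, bgIuPerG = 100),
    trees10_BG = treeseiMixture(10, bgIuPerG = 100),
    trees30_BG = treeseiMixture(30, bgIuPerG = 100))
}

accRun <- function(substrate, system, seed, recordInterval = 60) {
  key <- paste0("run_", substrate, "_", system, "_", seed, "_", recordInterval)
  cached(key, runHydrolysis(accAssembly(substrate, seed), accSystem(system),
                            durationMin = 2880, seed = seed,
                            recordInterval = recordInterval))
}

accConv <- function(substrate, system, seeds = 1:3) {
  mean(vapply(seeds, function(s)
    celluloseConversion(accRun(substrate, system, s)), numeric(1)))
}
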