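# S4 classes for substrates, enzymes, reactions and simulation results.

#' Substrate preset
#'
#' Describes a model cellulosic substrate by its degree-of-polymerization
#' range, crystallinity-index range and the number of microfibrils simulated.
#' The shipped presets (`avicel`, `filter_paper`, `bacterial_cellulose`,
#' `cotton`) mirror the standard model substrates used to study cellulase
#' action; see [substratePreset()].
#'
#' @slot name preset name.
#' @slot dpRange length-2 integer range of chain degree of polymerization.
#' @slot criRange length-2 numeric range of the crystallinity index in (0, 1].
#' @slot nMicrofibrils number of microfibrils to simulate.
#' @slot minTotal minimum total glucose units in the realized assembly
#'   (`NA` to disable the constraint).
#' @exportClass SubstratePreset
setClass("SubstratePreset",
  representation(name = "character", dpRange = "numeric",
                 criRange = "numeric", nMicrofibrils = "integer",
                 minTotal = "numeric"))

setValidity("SubstratePreset", function(object) {
  msg <- character()
  if (length(object@dpRange) != 2 || any(object@dpRange < 7))
    msg <- c(msg, "dpRange must be two values >= 7")
  if (length(object@criRange) != 2 || any(object@criRange <= 0) ||
      any(object@criRange > 1))
    msg <- c(msg, "criRange must lie in (0, 1]")
  if (object@nMicrofibrils < 1L)
    msg <- c(msg, "nMicrofibrils must be >= 1")
  if (length(msg)) msg else TRUE
})

#' In-silico cellulose assembly
#'
#' A hierarchical cellulose substrate: microfibrils of elementary fibrils,
#' each elementary fibril a 6 x 6 lattice of 36 glucose chains of equal
#' length. Chains are stored as a chain-level table; the crystalline/amorphous
#' banding is stored per glucose unit. Unit serial numbers run row-major over
#' (elementary fibril, chain, axial position); axial position 0 is the
#' reducing end of every chain (parallel-chain cellulose I-beta).
#'
#' @slot chains data.frame with one row per chain: `mf`, `ef`, `efRow`,
#'   `efCol`, `chainRow`, `chainCol`, `depth` (0 = elementary-fibril surface),
#'   `below` (0-based index of the chain exposed when this chain is removed,
#'   -1 if none), `mfSurface` (0/1), `dp`, `startUid` (0-based).
#' @slot crystalline raw vector, one byte per glucose unit (1 = crystalline).
#' @slot gSim total number of glucose units at time zero.
#' @slot nMicrofibrils number of microfibrils.
#' @slot solublePool numeric length-6 vector of free oligomer counts by DP
#'   (all zero for freshly built substrates).
#' @slot meta list of build metadata (preset, seed, ranges, realized CrI).
#' @exportClass CelluloseAssembly
setClass("CelluloseAssembly",
  representation(chains = "data.frame", crystalline = "raw", gSim = "numeric",
                 nMicrofibrils = "integer", solublePool = "numeric",
                 meta = "list"))

setValidity("CelluloseAssembly", function(object) {
  msg <- character()
  ch <- object@chains
  need <- c("mf", "ef", "efRow", "efCol", "chainRow", "chainCol", "depth",
            "below", "mfSurface", "dp", "startUid")
  if (!all(need %in% names(ch)))
    msg <- c(msg, paste("chains table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (sum(ch$dp) != object@gSim || length(object@crystalline) != object@gSim)
      msg <- c(msg, "gSim must equal the total chain length and the length of the crystalline vector")
    if (any(table(ch$ef) != 36))
      msg <- c(msg, "every elementary fibril must contain exactly 36 chains")
    if (max(ch$mf) != object@nMicrofibrils)
      msg <- c(msg, "nMicrofibrils inconsistent with chains table")
  }
  if (length(object@solublePool) != 6 || any(object@solublePool < 0))
    msg <- c(msg, "solublePool must be 6 non-negative counts (DP 1..6)")
  if (length(msg)) msg else TRUE
})

#' Enzyme specification
#'
#' One cellulolytic enzyme: its mechanistic class, loading, specific activity
#' and the probability/counter parameters governing its simulated action.
#' Eight classes are supported: non-processive endoglucanase with/without a
#' carbohydrate-binding module (`EG_nonproc_CBM`, `EG_nonproc_noCBM`),
#' processive endoglucanase (`EG_proc_CBM`), processive and non-processive
#' cellobiohydrolase I (`CBH1_proc`, `CBH1_nonproc`) and II (`CBH2_proc`,
#' `CBH2_nonproc`), and beta-glucosidase (`BG`).
#'
#' @slot name display name.
#' @slot enzymeClass one of the eight class labels.
#' @slot loading mg enzyme per g cellulose (ignored when `iuPerG` is set).
#' @slot activity specific activity, IU per mg enzyme.
#' @slot iuPerG direct activity dosing in IU per g glucan (used for
#'   beta-glucosidase, which is conventionally dosed this way); `NA` to dose
#'   by `loading * activity`.
#' @slot stability activity retention factor in `[0, 1]` under the current
#'   temperature/pH (1 = optimum conditions).
#' @slot params named numeric vector of action parameters; see
#'   [hydrolysisParams()].
#' @exportClass EnzymeSpec
setClass("EnzymeSpec",
  representation(name = "character", enzymeClass = "character",
                 loading = "numeric", activity = "numeric",
                 iuPerG = "numeric", stability = "numeric",
                 params = "numeric"))

.enzymeClasses <- c("EG_nonproc_CBM", "EG_nonproc_noCBM", "EG_proc_CBM",
                    "CBH1_proc", "CBH1_nonproc", "CBH2_proc", "CBH2_nonproc",
                    "BG")

.paramNames <- c("footprint", "minChainDp", "prefChainDp", "pLongChain",
                 "pCrystalline", "pBuried", "pGlucoseEnd",
                 "pDesorbAmorphous", "pDesorbCrystalline", "pSoluble",
                 "pBgG2", "pBgOligo", "nNb", "nNp", "nInhibG", "nInhibG2")

setValidity("EnzymeSpec", function(object) {
  msg <- character()
  if (!object@enzymeClass %in% .enzymeClasses)
    msg <- c(msg, paste("enzymeClass must be one of:",
                        paste(.enzymeClasses, collapse = ", ")))
  if (is.na(object@stability) || object@stability < 0 || object@stability > 1)
    msg <- c(msg, "stability must lie in [0, 1]")
  if (!is.na(object@loading) && object@loading < 0)
    msg <- c(msg, "loading must be non-negative")
  if (!is.na(object@activity) && object@activity < 0)
    msg <- c(msg, "activity must be non-negative")
  p <- object@params
  if (!all(.paramNames %in% names(p)))
    msg <- c(msg, paste("params must contain:", paste(.paramNames, collapse = ", ")))
  else {
    probs <- p[c("pLongChain", "pCrystalline", "pBuried", "pGlucoseEnd",
                 "pDesorbAmorphous", "pDesorbCrystalline", "pSoluble",
                 "pBgG2", "pBgOligo")]
    if (any(probs < 0 | probs > 1))
      msg <- c(msg, "all probability parameters must lie in [0, 1]")
    if (any(p[c("nNb", "nNp", "nInhibG", "nInhibG2")] <= 0))
      msg <- c(msg, "counter increments must be positive")
    if (p["footprint"] < 1 || p["minChainDp"] < 2)
      msg <- c(msg, "footprint must be >= 1 and minChainDp >= 2")
    if (grepl("^CBH", object@enzymeClass) && p["nInhibG2"] <= p["nInhibG"])
      msg <- c(msg, "cellobiose must be a stronger inhibitor than glucose for CBH classes (nInhibG2 > nInhibG)")
  }
  if (length(msg)) msg else TRUE
})

#' Enzyme system
#'
#' An ordered collection of [EnzymeSpec-class] objects acting simultaneously.
#'
#' @slot enzymes list of `EnzymeSpec`.
#' @exportClass EnzymeSystem
setClass("EnzymeSystem", representation(enzymes = "list"))

setValidity("EnzymeSystem", function(object) {
  if (!all(vapply(object@enzymes, is, TRUE, "EnzymeSpec")))
    return("all elements must be EnzymeSpec objects")
  TRUE
})

#' Reaction specification
#'
#' Macroscopic scaling from simulated glucose-unit counts to laboratory
#' concentrations: total solution mass, solid (biomass) fraction, cellulose
#' fraction of the solid, and solution volume.
#'
#' @slot wSample total solution weight, g.
#' @slot solidFraction solids fraction of the solution, dimensionless (0, 1].
#' @slot celluloseFraction cellulose fraction of the solid, dimensionless (0, 1].
#' @slot vActual solution volume, mL.
#' @exportClass ReactionSpec
setClass("ReactionSpec",
  representation(wSample = "numeric", solidFraction = "numeric",
                 celluloseFraction = "numeric", vActual = "numeric"))

setValidity("ReactionSpec", function(object) {
  msg <- character()
  if (object@wSample <= 0 || object@vActual <= 0)
    msg <- c(msg, "wSample and vActual must be positive")
  if (object@solidFraction < 0 || object@solidFraction > 1 ||
      object@celluloseFraction <= 0 || object@celluloseFraction > 1)
    msg <- c(msg, "solidFraction must lie in [0, 1] and celluloseFraction in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Hydrolysis simulation result
#'
#' Trajectory and final state of a Monte Carlo hydrolysis run.
#'
#' @slot trajectory data.frame of recorded observables (one row per record
#'   interval): soluble molecule counts by DP, insoluble units, crystalline
#'   insoluble units, fragment count, solubilized units and conversion.
#' @slot assembly the substrate at time zero.
#' @slot finalState list with per-unit end state (`removed`, `broken`,
#'   `surface` raw vectors), per-microfibril soluble pool and censuses.
#' @slot tallies matrix of per-enzyme event outcome counts (productive,
#'   no-binding, non-productive, inhibited).
#' @slot system the enzyme system used.
#' @slot durationMin simulated minutes.
#' @slot seed RNG seed used.
#' @slot recordInterval recording interval, minutes.
#' @exportClass HydrolysisResult
setClass("HydrolysisResult",
  representation(trajectory = "data.frame", assembly = "CelluloseAssembly",
                 finalState = "list", tallies = "matrix",
                 system = "EnzymeSystem", durationMin = "integer",
                 seed = "numeric", recordInterval = "integer"))
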