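# Enzyme specifications, presets, per-minute event budgets (bond-breaking
# capacity from loading and specific activity) and per-microfibril allocation.

.classCodes <- c(EG_nonproc_CBM = 1L, EG_nonproc_noCBM = 2L, EG_proc_CBM = 3L,
                 CBH1_proc = 4L, CBH1_nonproc = 5L, CBH2_proc = 6L,
                 CBH2_nonproc = 7L, BG = 8L)

#' Default action parameters for an enzyme class
#'
#' Probability and counter parameters controlling simulated binding and
#' catalysis. Desorption probabilities (5% amorphous, 2.5% crystalline), the
#' 25% accessibility penalty for chains on elementary-fibril-but-not-
#' microfibril surfaces, the 90% probability of glucose-producing terminal
#' cuts by endoglucanase and the cellobiohydrolase-I preference for chains of
#' at most 300 units are fixed model constants; the remaining values
#' (binding footprint, counter increments, endoglucanase crystalline-region
#' factor, acceptance on soluble oligomers) are calibration parameters whose
#' defaults were fixed once against published simulation behaviour of the
#' T. reesei system (see the package vignette) and can be overridden per
#' enzyme.
#'
#' @param enzymeClass one of the eight class labels (see
#'   [EnzymeSpec-class]).
#' @return named numeric vector of parameters:
#' \describe{
#'   \item{footprint}{contiguous unblocked surface glucose units required for
#'     binding (enzyme CBM + linker + catalytic domain size).}
#'   \item{minChainDp}{no action on chains/oligomers shorter than this.}
#'   \item{prefChainDp}{CBH I preferred chain length; above it, binding
#'     acceptance falls off inversely with chain length as
#'     `pLongChain * prefChainDp / length` (0 disables).}
#'   \item{pLongChain}{scale of the long-chain acceptance fall-off.}
#'   \item{pCrystalline}{endoglucanase acceptance multiplier for bonds in
#'     crystalline regions.}
#'   \item{pBuried}{acceptance on elementary-fibril-surface chains that are
#'     not on the microfibril surface (25% lower accessibility).}
#'   \item{pGlucoseEnd}{endoglucanase acceptance for terminal
#'     (glucose-producing) cuts.}
#'   \item{pDesorbAmorphous, pDesorbCrystalline}{processive desorption
#'     probability per cleavage.}
#'   \item{pSoluble}{CBH acceptance on soluble DP 5-6 oligomers.}
#'   \item{pBgG2, pBgOligo}{beta-glucosidase acceptance on cellobiose and on
#'     DP 3-6 oligomers (cellobiose is the preferred substrate).}
#'   \item{nNb, nNp, nInhibG, nInhibG2}{minute-counter increments for
#'     no-binding, non-productive binding, and glucose/cellobiose inhibitor
#'     encounters.}
#' }
#' @export
hydrolysisParams <- function(enzymeClass) {
  enzymeClass <- match.arg(enzymeClass, .enzymeClasses)
  isCBH <- grepl("^CBH", enzymeClass)
  isEG <- grepl("^EG", enzymeClass)
  c(footprint = if (isCBH) 6 else if (isEG) 20 else 10,
    minChainDp = if (isEG) 4 else 5,
    prefChainDp = if (isCBH) 300 else 0,
    pLongChain = 0.8,
    pCrystalline = if (isEG) 0.08 else 1,
    pBuried = 0.75,
    pGlucoseEnd = 0.9,
    pDesorbAmorphous = 0.05,
    pDesorbCrystalline = 0.025,
    pSoluble = 0.5,
    pBgG2 = 1,
    pBgOligo = 0.5,
    nNb = 1,
    nNp = if (isEG) 5 else 1,
    nInhibG = if (isCBH) 3.5 else if (isEG) 2 else 1,
    nInhibG2 = if (grepl("^CBH1", enzymeClass)) 115 else
      if (grepl("^CBH2", enzymeClass)) 70 else if (isEG) 10 else 1.5)
}

#' Create an enzyme specification
#'
#' @param enzymeClass one of the eight mechanistic classes (see
#'   [EnzymeSpec-class]).
#' @param loading enzyme loading, mg per g cellulose.
#' @param activity specific activity, IU per mg enzyme (one IU liberates one
#'   micromole of product per minute).
#' @param iuPerG direct dosing in IU per g glucan (bypasses
#'   `loading * activity`; the convention for beta-glucosidase).
#' @param stability activity retention in `[0, 1]` under current conditions;
#'   1 at optimal temperature and pH.
#' @param name display name.
#' @param params named list/vector of overrides for [hydrolysisParams()].
#' @return an [EnzymeSpec-class].
#' @examples
#' cbh1 <- enzymeSpec("CBH1_proc", loading = 10, activity = 0.8)
#' maxBondsPerMinute(cbh1, gSim = 1e6)
#' @export
enzymeSpec <- function(enzymeClass, loading = 0, activity = 0,
                       iuPerG = NA_real_, stability = 1,
                       name = enzymeClass, params = list()) {
  enzymeClass <- match.arg(enzymeClass, .enzymeClasses)
  p <- hydrolysisParams(enzymeClass)
  if (length(params)) {
    params <- unlist(params)
    bad <- setdiff(names(params), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(params)] <- params
  }
  obj <- new("EnzymeSpec", name = name, enzymeClass = enzymeClass,
             loading = as.numeric(loading), activity = as.numeric(activity),
             iuPerG = as.numeric(iuPerG), stability = as.numeric(stability),
             params = p)
  validObject(obj)
  obj
}

#' Enzyme presets
#'
#' Specifications for the Trichoderma reesei cellulase system: EG I
#' (non-processive endoglucanase with CBM, 0.4 IU/mg), CBH I (processive
#' cellobiohydrolase attacking reducing ends, 0.8 IU/mg), CBH II (processive,
#' non-reducing ends, 1.6 IU/mg) and beta-glucosidase (dosed in IU per g
#' glucan). `EGII` is an alias with EG I's activity. The table ships as plain
#' text in `inst/extdata/enzyme_presets.tsv`.
#'
#' @param name preset name: `"EGI"`, `"EGII"`, `"CBHI"`, `"CBHII"`, `"BG"`.
#' @param loading mg enzyme per g cellulose.
#' @param iuPerG IU per g glucan (BG dosing; ignored for other presets
#'   unless explicitly set).
#' @param params parameter overrides, as in [enzymeSpec()].
#' @return an [EnzymeSpec-class].
#' @examples
#' enzymePreset("CBHI", loading = 10)
#' @export
enzymePreset <- function(name, loading = 0, iuPerG = NA_real_,
                         params = list()) {
  tab <- read.delim(system.file("extdata", "enzyme_presets.tsv",
                                package = "cellulosim"),
                    stringsAsFactors = FALSE)
  i <- match(toupper(name), tab$name)
  if (is.na(i))
    stop("unknown enzyme preset '", name, "'; available: ",
         paste(tab$name, collapse = ", "))
  enzymeSpec(tab$enzyme_class[i], loading = loading,
             activity = tab$activity_iu_per_mg[i],
             iuPerG = if (tab$name[i] == "BG" && is.na(iuPerG)) 200 else iuPerG,
             name = tab$name[i], params = params)
}

#' Combine enzymes into a system
#'
#' @param ... `EnzymeSpec` objects (or a single list of them).
#' @return an [EnzymeSystem-class].
#' @export
enzymeSystem <- function(...) {
  specs <- list(...)
  if (length(specs) == 1 && is.list(specs[[1]]) && !is(specs[[1]], "EnzymeSpec"))
    specs <- specs[[1]]
  obj <- new("EnzymeSystem", enzymes = specs)
  validObject(obj)
  obj
}

#' The T. reesei enzyme-ratio mixture
#'
#' Protein mixture in the natural T. reesei cellulase proportions: 12% EG I,
#' 60% CBH I and 20% CBH II of the total protein loading, optionally with
#' excess beta-glucosidase.
#'
#' @param totalLoading total protein, mg per g glucan.
#' @param bgIuPerG beta-glucosidase dose in IU per g glucan (`NA` for none).
#' @return an [EnzymeSystem-class].
#' @export
treeseiMixture <- function(totalLoading = 20, bgIuPerG = NA_real_) {
  specs <- list(enzymePreset("EGI", loading = 0.12 * totalLoading),
                enzymePreset("CBHI", loading = 0.60 * totalLoading),
                enzymePreset("CBHII", loading = 0.20 * totalLoading))
  if (!is.na(bgIuPerG))
    specs <- c(specs, list(enzymePreset("BG", iuPerG = bgIuPerG)))
  enzymeSystem(specs)
}

#' Maximum bonds broken per minute
#'
#' Event budget of one enzyme on the simulated substrate: the simulated
#' cellulose mass is `gSim * 162 / 6.023e23` grams (162 g/mol per
#' anhydroglucose unit), the simulated enzyme mass is the loading times that,
#' and one IU liberates `6.023e17` product molecules (one micromole) per
#' minute, giving `loading * activity * stability * 162e-6 * gSim` bonds per
#' minute. When `iuPerG` is set the budget is
#' `iuPerG * stability * 162e-6 * gSim`. Fractional budgets are carried by
#' stochastic rounding inside the simulation engine so long-run event rates
#' match the real-valued budget.
#'
#' @param spec an [EnzymeSpec-class].
#' @param gSim total simulated glucose units.
#' @return expected hydrolysis events per minute (real-valued).
#' @examples
#' eg <- enzymeSpec("EG_nonproc_CBM", loading = 10, activity = 0.4)
#' maxBondsPerMinute(eg, 1e6)  # 648 bonds/min
#' @export
maxBondsPerMinute <- function(spec, gSim) {
  stopifnot(is(spec, "EnzymeSpec"), gSim > 0)
  if (!is.na(spec@iuPerG))
    return(spec@iuPerG * spec@stability * 162e-6 * gSim)
  spec@loading * spec@activity * spec@stability * 162e-6 * gSim
}

#' Allocate an enzyme's event budget across microfibrils
#'
#' The per-minute budget is split proportionally to each microfibril's count
#' of hydrolysable material for the enzyme's mode of action: surface glucose
#' units for endoglucanases, reducing ends for CBH I, non-reducing ends for
#' CBH II and soluble molecules for beta-glucosidase. Fractions form a
#' probability vector over microfibrils whenever the relevant census is
#' non-zero; an all-zero census yields zero budgets.
#'
#' @param spec an [EnzymeSpec-class].
#' @param census data.frame as returned by [surfaceCensus()].
#' @param gSim total simulated glucose units.
#' @return data.frame with columns `mf`, `fj` (allocation fraction) and
#'   `budget` (events/minute).
#' @examples
#' census <- data.frame(mf = 1:2, nS = c(100, 300), nR = c(10, 30),
#'                      nNR = c(10, 30), nSL = c(0, 0))
#' cbh1 <- enzymeSpec("CBH1_proc", loading = 10, activity = 0.8)
#' allocateEvents(cbh1, census, gSim = 1e6)
#' @export
allocateEvents <- function(spec, census, gSim) {
  w <- switch(sub("_.*", "", spec@enzymeClass),
              EG = census$nS,
              CBH1 = census$nR,
              CBH2 = census$nNR,
              BG = census$nSL)
  denom <- sum(w)
  fj <- if (denom > 0) w / denom else rep(0, length(w))
  data.frame(mf = census$mf, fj = fj,
             budget = maxBondsPerMinute(spec, gSim) * fj)
}

setMethod("show", "EnzymeSpec", function(object) {
  dose <- if (!is.na(object@iuPerG))
    paste0(object@iuPerG, " IU/g glucan")
  else paste0(object@loading, " mg/g x ", object@activity, " IU/mg")
  cat("EnzymeSpec '", object@name, "' [", object@enzymeClass, "]: ", dose,
      ", stability ", object@stability, "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "EnzymeSystem", function(object) {
  cat("EnzymeSystem with", length(object@enzymes), "enzyme(s):\n")
  for (e in object@enzymes) show(e)
  invisible(NULL)
})

# parameter row consumed by the C++ engine (column order fixed)
engineParams <- function(spec, gSim) {
  p <- spec@params
  c(.classCodes[[spec@enzymeClass]], maxBondsPerMinute(spec, gSim),
    p["footprint"], p["minChainDp"], p["prefChainDp"], p["pLongChain"],
    p["pCrystalline"], p["pBuried"], p["pGlucoseEnd"],
    p["pDesorbAmorphous"], p["pDesorbCrystalline"], p["pSoluble"],
    p["pBgG2"], p["pBgOligo"], p["nNb"], p["nNp"], p["nInhibG"],
    p["nInhibG2"])
}
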