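# Independent brute-force oracle for per-minute event expectations on toy
# substrates. Deliberately re-derives acceptance probabilities from the model
# rules by direct enumeration in R; it never calls the simulation engine.

#' Expected productive events per minute by exhaustive enumeration
#'
#' For a toy-sized assembly in its time-zero state, enumerates the enzyme's
#' candidate list (surface glucose units plus any seeded soluble pool for
#' endo/exo classes; the soluble pool alone for beta-glucosidase) and sums
#' per-candidate productive-acceptance probabilities. With all counter
#' increments equal to 1 every draw costs one counter unit, so a budget `b`
#' performs exactly `b` independent draws and the expected number of
#' productive events in one minute is `b * mean(p)`. Valid for comparison
#' against the engine when desorption is disabled, processivity is off
#' (non-processive classes) and all counter increments are 1; the minute is
#' treated in isolation (no state updates), matching the engine's
#' within-minute independence at budgets small relative to the candidate
#' list.
#'
#' @param assembly a toy [CelluloseAssembly-class] (at most 20000 units).
#' @param spec an [EnzymeSpec-class]; must be a non-processive class or BG.
#' @param budget events per minute to spend (defaults to the enzyme's
#'   [maxBondsPerMinute()]).
#' @param pool optional length-6 soluble pool (counts by DP).
#' @return expected productive events in one minute.
#' @export
bruteForceEventExpectation <- function(assembly, spec, budget = NULL,
                                       pool = NULL) {
  stopifnot(is(assembly, "CelluloseAssembly"), is(spec, "EnzymeSpec"))
  if (assembly@gSim > 20000)
    stop("assembly exceeds the toy-size limit for exhaustive enumeration")
  if (spec@enzymeClass %in% c("EG_proc_CBM", "CBH1_proc", "CBH2_proc"))
    stop("the enumeration oracle covers non-processive classes and BG only")
  if (is.null(budget)) budget <- maxBondsPerMinute(spec, assembly@gSim)
  if (is.null(pool)) pool <- numeric(6)
  p <- spec@params
  cls <- spec@enzymeClass
  kind <- sub("_.*", "", cls)

  solubleP <- function(d) {
    # productive probability for a drawn soluble molecule of DP d
    if (kind == "BG") {
      if (d == 1) return(0)
      if (d == 2) return(p[["pBgG2"]])
      return(p[["pBgOligo"]])
    }
    if (d < p[["minChainDp"]]) return(0)  # incl. glucose/cellobiose (inhibit)
    if (kind == "EG") {
      nb <- d - 1
      return((2 * p[["pGlucoseEnd"]] + (nb - 2)) / nb)
    }
    p[["pSoluble"]]
  }
  polProb <- sum(vapply(1:6, function(d) pool[d] * solubleP(d), numeric(1)))

  if (kind == "BG") {
    L <- sum(pool)
    if (L == 0) return(0)
    return(budget * polProb / L)
  }

  snap <- substrateSnapshot(assembly)
  s <- snap[snap$efSurface, ]
  probs <- numeric(nrow(s))
  dp <- assembly@chains$dp[1]
  for (i in seq_len(nrow(s))) {
    acc <- if (s$mfSurface[i]) 1 else p[["pBuried"]]
    if (kind == "EG") {
      if (dp < p[["footprint"]]) { probs[i] <- 0; next }
      cut <- if (s$axial[i] == dp - 1) s$axial[i] - 1 else s$axial[i]
      pr <- acc
      if (s$crystalline[i]) pr <- pr * p[["pCrystalline"]]
      if (cut == 0 || cut + 1 == dp - 1) pr <- pr * p[["pGlucoseEnd"]]
      probs[i] <- pr
    } else if (kind == "CBH1") {
      ok <- s$axial[i] == 0 && dp >= p[["footprint"]]
      pr <- if (ok) acc else 0
      if (ok && p[["prefChainDp"]] > 0 && dp > p[["prefChainDp"]])
        pr <- pr * min(1, p[["pLongChain"]] * p[["prefChainDp"]] / dp)
      probs[i] <- pr
    } else { # CBH2
      ok <- s$axial[i] == dp - 1 && dp >= p[["footprint"]]
      pr <- if (ok) acc else 0
      if (ok && p[["prefChainDp"]] > 0 && dp > p[["prefChainDp"]])
        pr <- pr * min(1, p[["pLongChain"]] * p[["prefChainDp"]] / dp)
      probs[i] <- pr
    }
  }
  L <- nrow(s) + sum(pool)
  if (L == 0) return(0)
  budget * (sum(probs) + polProb) / L
}
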