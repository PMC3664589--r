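# R-side driver for the per-minute Monte Carlo hydrolysis engine.

#' Run a hydrolysis simulation
#'
#' Simulates `durationMin` one-minute Monte Carlo steps of the enzyme system
#' acting on the assembly. Each minute, every enzyme's event budget (see
#' [maxBondsPerMinute()]) is allocated across microfibrils by the current
#' censuses (see [allocateEvents()]); the resulting (enzyme, microfibril)
#' work units are processed in randomized order. Within a work unit, targets
#' are drawn uniformly: for endoglucanases and cellobiohydrolases from the
#' microfibril's elementary-fibril-surface units plus its soluble products,
#' for beta-glucosidase from soluble molecules only. Outcomes advance the
#' minute counter by 1 (productive), `nNb` (no binding), `nNp`
#' (non-productive binding) or `nInhibG`/`nInhibG2` (glucose/cellobiose
#' inhibitor encounter) until the budget is exhausted. Bond cleavages
#' reassign chain-end properties, solubilize fragments of DP 6 and below
#' (exposing the chain layer beneath) and update all censuses. Identical
#' inputs and seed give a bit-identical trajectory.
#'
#' @param assembly a [CelluloseAssembly-class].
#' @param system an [EnzymeSystem-class] (or a single [EnzymeSpec-class]).
#' @param durationMin simulated minutes (48 h = 2880).
#' @param seed integer RNG seed.
#' @param recordInterval minutes between recorded observables.
#' @param initialPool optional seeded soluble pool: numeric length-6 vector
#'   (counts by DP, assigned to microfibril 1) or an
#'   `nMicrofibrils x 6` matrix.
#' @return a [HydrolysisResult-class].
#' @examples
#' toy <- makeToyAssembly(dp = 20)
#' cbh <- enzymeSpec("CBH1_proc", loading = 40, activity = 0.8)
#' res <- runHydrolysis(toy, cbh, durationMin = 30, seed = 1)
#' celluloseConversion(res)
#' @export
runHydrolysis <- function(assembly, system, durationMin, seed = 1L,
                          recordInterval = 60L, initialPool = NULL) {
  stopifnot(is(assembly, "CelluloseAssembly"), durationMin >= 1)
  if (is(system, "EnzymeSpec")) system <- enzymeSystem(system)
  stopifnot(is(system, "EnzymeSystem"))
  nMf <- assembly@nMicrofibrils
  if (length(system@enzymes) == 0)
    warning("empty enzyme system: trajectory will be a no-op")
  pm <- if (length(system@enzymes))
    do.call(rbind, lapply(system@enzymes, engineParams, gSim = assembly@gSim))
  else matrix(0, 0, 18)
  ip <- matrix(0, nMf, 6)
  if (!is.null(initialPool)) {
    if (is.matrix(initialPool)) {
      stopifnot(nrow(initialPool) == nMf, ncol(initialPool) == 6)
      ip <- initialPool
    } else {
      stopifnot(length(initialPool) == 6)
      ip[1, ] <- initialPool
    }
  } else if (any(assembly@solublePool > 0)) {
    ip[1, ] <- assembly@solublePool
  }
  ch <- assembly@chains
  res <- withSeed(seed, .cpp_run_engine(
    as.integer(ch$startUid), as.integer(ch$dp), as.integer(ch$mf),
    as.integer(ch$below), as.integer(ch$mfSurface), as.integer(ch$depth),
    assembly@crystalline, as.integer(nMf), pm,
    as.integer(durationMin), as.integer(recordInterval), ip))
  traj <- as.data.frame(res$trajectory)
  colnames(traj) <- c("minute", "nGlu", "nG2", "nG3", "nG4", "nG5", "nG6",
                      "insolubleUnits", "crystallineInsoluble", "fragments",
                      "solubilizedUnits")
  traj$conversion <- 100 * traj$solubilizedUnits / assembly@gSim
  tl <- res$tallies
  dimnames(tl) <- list(
    vapply(system@enzymes, function(e) e@name, character(1)),
    c("productive", "noBinding", "nonProductive", "inhibited"))
  census <- as.data.frame(res$census)
  colnames(census) <- c("nS", "nR", "nNR", "nSL")
  census <- cbind(mf = seq_len(nMf), census)
  new("HydrolysisResult", trajectory = traj, assembly = assembly,
      finalState = list(removed = res$removed, broken = res$broken,
                        surface = res$surface, poolByMf = res$poolByMf,
                        census = census),
      tallies = tl, system = system, durationMin = as.integer(durationMin),
      seed = as.numeric(seed), recordInterval = as.integer(recordInterval))
}

#' @describeIn trajectory recorded observables of a run.
#' @export
setMethod("trajectory", "HydrolysisResult", function(x) x@trajectory)

#' Per-enzyme event outcome tallies
#'
#' Counts of productive cleavages, failed bindings, non-productive bindings
#' and inhibitor (glucose/cellobiose) encounters accumulated by each enzyme
#' over the whole run.
#'
#' @param x a [HydrolysisResult-class].
#' @return matrix, one row per enzyme.
#' @export
eventTallies <- function(x) {
  stopifnot(is(x, "HydrolysisResult"))
  x@tallies
}

#' @describeIn celluloseConversion final or full-trajectory conversion.
#' @export
setMethod("celluloseConversion", "HydrolysisResult",
  function(x, at = c("final", "trajectory"), ...) {
    at <- match.arg(at)
    conv <- x@trajectory$conversion
    if (at == "final") conv[length(conv)] else conv
  })

#' @describeIn crystallinityIndex end-of-run crystallinity of the remaining
#'   insoluble cellulose.
#' @export
setMethod("crystallinityIndex", "HydrolysisResult", function(x, ...) {
  last <- x@trajectory[nrow(x@trajectory), ]
  if (last$insolubleUnits <= 0) {
    warning("all cellulose solubilized: crystallinity index undefined")
    return(NA_real_)
  }
  last$crystallineInsoluble / last$insolubleUnits
})

#' @describeIn glucoseCount units of the underlying assembly.
#' @export
setMethod("glucoseCount", "HydrolysisResult", function(x) x@assembly@gSim)

#' @describeIn surfaceCensus end-of-run census.
#' @export
setMethod("surfaceCensus", "HydrolysisResult", function(x, ...)
  x@finalState$census)

# fragment bookkeeping on the end state: per-unit fragment ids for alive
# units, NA for solubilized ones
fragmentIds <- function(x) {
  ch <- x@assembly@chains
  n <- x@assembly@gSim
  alive <- as.integer(x@finalState$removed) == 0L
  broken <- as.integer(x@finalState$broken) == 1L
  chainId <- rep(seq_len(nrow(ch)), ch$dp)
  prevSame <- c(FALSE, chainId[-n] == chainId[-1])
  prevConn <- prevSame & c(FALSE, !broken[-n]) & c(FALSE, alive[-n]) & alive
  fid <- cumsum(alive & !prevConn)
  fid[!alive] <- NA_integer_
  fid
}

#' @describeIn chainLengthDistribution end-of-run distribution over insoluble
#'   fragments and the soluble pool.
#' @export
setMethod("chainLengthDistribution", "HydrolysisResult", function(x, ...) {
  fid <- fragmentIds(x)
  lens <- tabulate(tabulate(fid[!is.na(fid)]))
  ins <- data.frame(dp = seq_along(lens), count = as.numeric(lens),
                    phase = "insoluble")
  ins <- ins[ins$count > 0, ]
  pool <- colSums(x@finalState$poolByMf)
  sol <- data.frame(dp = 1:6, count = as.numeric(pool), phase = "soluble")
  out <- rbind(sol[sol$count > 0, ], ins)
  rownames(out) <- NULL
  out[order(out$dp), ]
})

#' @describeIn substrateSnapshot end-of-run snapshot with fragment-resolved
#'   end states and distances.
#' @export
setMethod("substrateSnapshot", "HydrolysisResult", function(x, ...) {
  u <- unitFrame(x@assembly@chains)
  fid <- fragmentIds(x)
  u$soluble <- is.na(fid)
  u$crystalline <- as.integer(x@assembly@crystalline) == 1L
  u$efSurface <- as.integer(x@finalState$surface) == 1L
  alive <- !u$soluble
  minAx <- rep(NA_real_, nrow(u)); maxAx <- rep(NA_real_, nrow(u))
  if (any(alive)) {
    minAx[alive] <- ave(u$axial[alive], fid[alive], FUN = min)
    maxAx[alive] <- ave(u$axial[alive], fid[alive], FUN = max)
  }
  u$endState <- ifelse(!alive, NA_integer_,
                       ifelse(u$axial == minAx, 1L,
                              ifelse(u$axial == maxAx, -1L, 0L)))
  u$distanceNR <- maxAx - u$axial
  u$mfSurface <- u$mfSurface & alive
  u$blocked <- FALSE
  u$dp <- NULL
  u
})

setMethod("show", "HydrolysisResult", function(object) {
  tr <- object@trajectory
  cat("HydrolysisResult:", object@durationMin, "min,",
      length(object@system@enzymes), "enzyme(s), seed", object@seed, "\n")
  cat(sprintf("  conversion %.2f%%, soluble pool (Glu..G6): %s\n",
              tr$conversion[nrow(tr)],
              paste(format(unlist(tr[nrow(tr), 2:7]), trim = TRUE),
                    collapse = ", ")))
  invisible(NULL)
})
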