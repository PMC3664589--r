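# Generics shared across substrate, result and observable methods.

#' Crystallinity index
#'
#' Fraction of insoluble glucose units that lie in crystalline regions
#' (crystalline insoluble units divided by total insoluble units; solubilized
#' units are excluded from the denominator). For a [HydrolysisResult-class]
#' the value refers to the end of the run; if the substrate was completely
#' solubilized the index is undefined and `NA` is returned with a warning.
#'
#' @param x a `CelluloseAssembly` or `HydrolysisResult`.
#' @param ... unused.
#' @return numeric fraction in `[0, 1]`, or `NA` if nothing insoluble remains.
#' @export
setGeneric("crystallinityIndex", function(x, ...)
  standardGeneric("crystallinityIndex"))

#' Chain-end fraction
#'
#' Percentage of glucose units that are chain ends of the queried polarity,
#' 100 * (number of ends) / (total glucose units). For intact uniform chains
#' of length DP this is 100/DP: 0.33% at DP 300, 0.05% at DP 2000.
#'
#' @param x a `CelluloseAssembly`.
#' @param polarity `"reducing"` or `"nonreducing"`.
#' @param ... unused.
#' @return percentage.
#' @export
setGeneric("chainEndFraction", function(x, polarity = "reducing", ...)
  standardGeneric("chainEndFraction"))

#' Per-microfibril surface census
#'
#' Counts used to apportion enzyme event budgets across microfibrils: `nS`
#' (glucose units on elementary-fibril surfaces), `nR` (reducing ends), `nNR`
#' (non-reducing ends) and `nSL` (soluble molecules originating from the
#' microfibril).
#'
#' @param x a `CelluloseAssembly` (time-zero census) or `HydrolysisResult`
#'   (end-of-run census).
#' @param ... unused.
#' @return data.frame with one row per microfibril.
#' @export
setGeneric("surfaceCensus", function(x, ...) standardGeneric("surfaceCensus"))

#' Total simulated glucose units
#'
#' @param x a `CelluloseAssembly` or `HydrolysisResult`.
#' @return number of glucose units at time zero (symbolically, the simulated
#'   glucose count used in event-budget and concentration scaling).
#' @export
setGeneric("glucoseCount", function(x) standardGeneric("glucoseCount"))

#' Per-unit substrate snapshot
#'
#' Columnar table with one row per glucose unit: location (microfibril,
#' elementary fibril, chain, axial position), serial number, end state
#' (1 = reducing end, -1 = non-reducing end, 0 = interior), surface flags,
#' crystallinity, solubility and the distance to the chain's non-reducing
#' end. For a result the fragmented end-of-run state is reported.
#'
#' @param x a `CelluloseAssembly` or `HydrolysisResult`.
#' @param ... unused.
#' @return data.frame, one row per glucose unit.
#' @export
setGeneric("substrateSnapshot", function(x, ...)
  standardGeneric("substrateSnapshot"))

#' Chain-length distribution
#'
#' Number of chains/molecules at each degree of polymerization, covering both
#' insoluble fragments and the soluble pool. The mass-weighted sum
#' `sum(dp * count)` always equals the total simulated glucose count.
#'
#' @param x a `CelluloseAssembly` or `HydrolysisResult`.
#' @param ... unused.
#' @return data.frame with columns `dp`, `count`, `phase`.
#' @export
setGeneric("chainLengthDistribution", function(x, ...)
  standardGeneric("chainLengthDistribution"))

#' Recorded trajectory of a hydrolysis run
#'
#' @param x a `HydrolysisResult`.
#' @return data.frame of recorded observables.
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' Cellulose conversion
#'
#' Percentage of the simulated glucose units solubilized (moved into soluble
#' species of DP 6 and below), 100 * (1 - insoluble/total).
#'
#' @param x a `HydrolysisResult`.
#' @param at `"final"` for the end-of-run value or `"trajectory"` for the
#'   whole recorded series.
#' @param ... unused.
#' @return percentage (scalar) or numeric vector.
#' @export
setGeneric("celluloseConversion", function(x, at = c("final", "trajectory"), ...)
  standardGeneric("celluloseConversion"))
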