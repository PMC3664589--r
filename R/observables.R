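# Macroscopic observables: concentrations, conversion, hydrolysis rate and
# degree of synergism.

.AVOGADRO <- 6.023e23
.MW_ANHYDRO <- 162   # anhydroglucose unit in a cellulose chain
.MW_GLUCOSE <- 180
.MW_CELLOBIOSE <- 342

#' Create a reaction specification
#'
#' @param wSample total solution weight, g.
#' @param solidFraction solids (biomass) fraction of the solution.
#' @param celluloseFraction cellulose fraction of the solid.
#' @param vActual solution volume, mL.
#' @return a [ReactionSpec-class].
#' @examples
#' reactionSpec(100, 0.1, 1, 100)  # 10 g cellulose in 100 mL: 100 g/L
#' @export
reactionSpec <- function(wSample = 100, solidFraction = 0.1,
                         celluloseFraction = 1, vActual = 100) {
  obj <- new("ReactionSpec", wSample = wSample, solidFraction = solidFraction,
             celluloseFraction = celluloseFraction, vActual = vActual)
  validObject(obj)
  obj
}

#' Reaction at a given cellulose loading
#'
#' Convenience constructor for a pure-cellulose hydrolysis at a g/L solid
#' loading (1 L of solution, solution density taken as 1 g/mL).
#'
#' @param solidLoading cellulose loading, g/L.
#' @return a [ReactionSpec-class].
#' @export
standardReaction <- function(solidLoading = 100) {
  reactionSpec(wSample = 1000, solidFraction = solidLoading / 1000,
               celluloseFraction = 1, vActual = 1000)
}

#' Glucose units in the actual (laboratory-scale) sample
#'
#' `G_actual = wSample * solidFraction * celluloseFraction * 6.023e23 / 162`:
#' the number of anhydroglucose units in the real reaction that the simulated
#' units stand for.
#'
#' @param rxn a [ReactionSpec-class].
#' @return molecule count.
#' @examples
#' actualGlucoseCount(reactionSpec(100, 0.1, 1, 100))  # 3.718e22
#' @export
actualGlucoseCount <- function(rxn) {
  stopifnot(is(rxn, "ReactionSpec"))
  rxn@wSample * rxn@solidFraction * rxn@celluloseFraction * .AVOGADRO /
    .MW_ANHYDRO
}

# molecular weight of a soluble oligomer of DP n: hydrated chain ends add one
# water (18) to n anhydro units, giving glucose 180 and cellobiose 342
oligomerMw <- function(n) .MW_ANHYDRO * n + 18

#' Concentration profiles of a hydrolysis run
#'
#' Converts recorded molecule counts into g/L: each simulated molecule stands
#' for `G_actual / gSim` real molecules, so
#' `C = N * (G_actual/gSim) * MW / 6.023e23 * 1000 / vActual` with molecular
#' weights 180 (glucose), 342 (cellobiose), `162 n + 18` (soluble DP 3-6) and
#' 162 per anhydroglucose unit for the insoluble DP 6+ fraction.
#'
#' @param x a [HydrolysisResult-class].
#' @param rxn a [ReactionSpec-class].
#' @return data.frame with columns `minute`, `hours`, `cGlu`, `cG2` ... `cG6`,
#'   `cG6plus` (g/L) and `conversion` (%).
#' @export
concentrationProfiles <- function(x, rxn) {
  stopifnot(is(x, "HydrolysisResult"), is(rxn, "ReactionSpec"))
  tr <- x@trajectory
  scale <- actualGlucoseCount(rxn) / glucoseCount(x) / .AVOGADRO *
    1000 / rxn@vActual
  out <- data.frame(minute = tr$minute, hours = tr$minute / 60,
                    cGlu = tr$nGlu * .MW_GLUCOSE * scale,
                    cG2 = tr$nG2 * .MW_CELLOBIOSE * scale,
                    cG3 = tr$nG3 * oligomerMw(3) * scale,
                    cG4 = tr$nG4 * oligomerMw(4) * scale,
                    cG5 = tr$nG5 * oligomerMw(5) * scale,
                    cG6 = tr$nG6 * oligomerMw(6) * scale,
                    cG6plus = tr$insolubleUnits * .MW_ANHYDRO * scale,
                    conversion = tr$conversion)
  out
}

#' Hydrolysis rate series
#'
#' Rate of cellulose (insoluble, DP 6+) consumption over consecutive time
#' windows, expressed as g cellulose per hour:
#' `-(delta cG6plus) * vActual / 1000` per window, scaled to hourly units.
#'
#' @param x a [HydrolysisResult-class].
#' @param rxn a [ReactionSpec-class].
#' @param windowMin window width in minutes; must be a multiple of the
#'   record interval.
#' @return data.frame with columns `hours` (window end) and `rate` (g/h).
#' @export
hydrolysisRate <- function(x, rxn, windowMin = 60) {
  stopifnot(is(x, "HydrolysisResult"), is(rxn, "ReactionSpec"))
  cp <- concentrationProfiles(x, rxn)
  if (nrow(cp) < 2) stop("need at least two recorded intervals for a rate")
  if (windowMin %% x@recordInterval != 0)
    stop("windowMin must be a multiple of the record interval (",
         x@recordInterval, " min)")
  stride <- windowMin %/% x@recordInterval
  idx <- seq(1, nrow(cp), by = stride)
  if (idx[length(idx)] != nrow(cp)) idx <- c(idx, nrow(cp))
  sub <- cp[idx, ]
  dC <- diff(sub$cG6plus)            # g/L per window
  dH <- diff(sub$hours)              # h per window
  data.frame(hours = sub$hours[-1],
             rate = -dC * rxn@vActual / 1000 / dH)
}

#' Degree of synergism
#'
#' Conversion achieved by an enzyme mixture divided by the sum of the
#' conversions achieved by its components acting alone:
#' `DS = conv_mixed / sum(conv_individual)`. Values above 1 indicate
#' synergistic action (e.g. endoglucanase creating new chain ends for
#' cellobiohydrolase).
#'
#' @param convMixed conversion (%) of the mixture run.
#' @param convIndividual numeric vector of conversions (%) of the individual
#'   runs.
#' @return dimensionless ratio.
#' @examples
#' degreeOfSynergism(36, c(10, 10))  # 1.8
#' @export
degreeOfSynergism <- function(convMixed, convIndividual) {
  s <- sum(convIndividual)
  if (!is.finite(s) || s <= 0)
    stop("degree of synergism undefined: individual conversions sum to zero")
  convMixed / s
}

setMethod("show", "ReactionSpec", function(object) {
  cat(sprintf(
    "ReactionSpec: %g g solution, %.3g solids fraction, %.3g cellulose, %g mL (%.3g g/L glucan)\n",
    object@wSample, object@solidFraction, object@celluloseFraction,
    object@vActual,
    object@wSample * object@solidFraction * object@celluloseFraction /
      (object@vActual / 1000)))
  invisible(NULL)
})
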