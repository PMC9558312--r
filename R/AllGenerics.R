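#' Per-atom interpolated charges
#'
#' Charge-interpolation scheme: atoms outside any lambda-group keep their
#' fixed charge; a member atom of a group carries the state-weighted sum
#' `sum_k lambda_k q^(k)` (which for a two-state site reduces to
#' `(1 - lambda) q^A + lambda q^B`); every buffer atom carries
#' `qMin + collectiveLambda * (qMax - qMin)`.
#'
#' @param x a [TitratableSystem-class].
#' @return numeric vector of per-atom charges, e.
#' @seealso [totalCharge()], [coulombEnergy()]
#' @export
setGeneric("interpolatedCharges", function(x) standardGeneric("interpolatedCharges"))

#' Total interpolated system charge
#'
#' @param x a [TitratableSystem-class].
#' @return total charge, e, including buffers.
#' @export
setGeneric("totalCharge", function(x) standardGeneric("totalCharge"))

#' Number of titratable sites (lambda-groups)
#'
#' @param x a [TitratableSystem-class].
#' @return integer count.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Get or set the stacked lambda-coordinate vector
#'
#' Coordinates are stacked group-major (all states of group 1, then group 2,
#' ...), with the collective buffer coordinate last when buffers are present.
#'
#' @param x a [TitratableSystem-class].
#' @param value replacement vector, same length and order.
#' @return `lambdaValues` returns a named numeric vector.
#' @export
setGeneric("lambdaValues", function(x) standardGeneric("lambdaValues"))

#' @rdname lambdaValues
#' @export
setGeneric("lambdaValues<-", function(x, value) standardGeneric("lambdaValues<-"))

#' Names of the stacked lambda-coordinates
#'
#' @param x a [TitratableSystem-class].
#' @return character vector, `<group>.<state>` plus `"buffer"` if present.
#' @export
setGeneric("coordinateNames", function(x) standardGeneric("coordinateNames"))

#' Fitted pKa estimates of a titration result
#'
#' @param object a [TitrationResult-class].
#' @return data.frame with one row per species (`site`, or `macro` plus the
#'   microscopic tautomers) and columns `pKa`, `ci95`, `se`, `nPoints`.
#' @export
setGeneric("pKaEstimates", function(object) standardGeneric("pKaEstimates"))

#' Per-pH deprotonated fractions of a titration result
#'
#' @param object a [TitrationResult-class].
#' @return data.frame with columns `pH`, `species`, `S`, `sem`, `framesUsed`,
#'   `framesExcluded`, `nReplicas`.
#' @export
setGeneric("deprotonatedFractions", function(object) standardGeneric("deprotonatedFractions"))
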