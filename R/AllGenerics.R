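#' @name lprosy-accessors
#' @title Accessor generics
#' @description Accessors for the formal classes of the package.  Slots are
#'   never meant to be reached with `@` by user code.
#' @param object a package object.
#' @param ... passed to methods.
NULL

#' @rdname lprosy-accessors
#' @export
setGeneric("poolNames", function(object) standardGeneric("poolNames"))

#' @rdname lprosy-accessors
#' @export
setGeneric("nPools", function(object) standardGeneric("nPools"))

#' @rdname lprosy-accessors
#' @export
setGeneric("pools", function(object) standardGeneric("pools"))

#' @rdname lprosy-accessors
#' @export
setGeneric("exchangeRates", function(object) standardGeneric("exchangeRates"))

#' @rdname lprosy-accessors
#' @export
setGeneric("crossRelaxation",
           function(object) standardGeneric("crossRelaxation"))

#' @rdname lprosy-accessors
#' @export
setGeneric("jCouplings", function(object) standardGeneric("jCouplings"))

#' Thermal-equilibrium magnetization of a spin system
#'
#' Returns the vector of equilibrium magnetizations in pool order.  This is
#' the unique fixed point of the longitudinal generator built by
#' [buildGenerator()]: applying the affine evolution to it yields a zero time
#' derivative.
#'
#' @param object a [SpinSystem-class].
#' @return named numeric vector.
#' @examples
#' sys <- spinSystem(list(
#'   spinPool("OH", "labile"),
#'   spinPool("W", "water", M0 = 1000, R1 = 0.3)),
#'   exchange = data.frame(from = "OH", to = "W", k = 100))
#' thermalEquilibrium(sys)
#' @export
setGeneric("thermalEquilibrium",
           function(object) standardGeneric("thermalEquilibrium"))

#' @rdname lprosy-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname lprosy-accessors
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))

#' @rdname lprosy-accessors
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))

#' @rdname lprosy-accessors
#' @export
setGeneric("frameCoords", function(object, ...) standardGeneric("frameCoords"))
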