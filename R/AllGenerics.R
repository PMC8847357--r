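#' @rdname PlateLayout-class
#' @param object a `PlateLayout`.
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))

#' @rdname PlateLayout-class
#' @export
setGeneric("plateFormat", function(object) standardGeneric("plateFormat"))

#' @rdname PlateLayout-class
#' @export
setGeneric("layoutWells", function(object) standardGeneric("layoutWells"))

#' @rdname PlateLayout-class
#' @export
setGeneric("compoundQuartets",
           function(object) standardGeneric("compoundQuartets"))

#' @rdname PlateLayout-class
#' @export
setGeneric("dmsoPairs", function(object) standardGeneric("dmsoPairs"))

#' @rdname WellImage-class
#' @param object a `WellImage`.
#' @export
setGeneric("intensityMatrix",
           function(object) standardGeneric("intensityMatrix"))

#' @rdname WellImage-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname WellImage-class
#' @export
setGeneric("wellName", function(object) standardGeneric("wellName"))

#' @rdname ScreenTruth-class
#' @param object a `ScreenTruth`.
#' @export
setGeneric("truthWells", function(object) standardGeneric("truthWells"))

#' @rdname ScreenTruth-class
#' @export
setGeneric("truthCompounds",
           function(object) standardGeneric("truthCompounds"))

#' @rdname ScreenTruth-class
#' @export
setGeneric("truthBeads", function(object) standardGeneric("truthBeads"))
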