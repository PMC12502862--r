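#' @rdname ChainConfiguration-class
#' @param object,x an object
#' @export
setGeneric("joints", function(x) standardGeneric("joints"))

#' @rdname ChainConfiguration-class
#' @export
setGeneric("nBonds", function(x) standardGeneric("nBonds"))

#' @rdname ChainConfiguration-class
#' @export
setGeneric("bondLength", function(x) standardGeneric("bondLength"))

#' @rdname tangentVectors
#' @export
setGeneric("tangentVectors", function(x) standardGeneric("tangentVectors"))

#' @rdname conformationVariables
#' @export
setGeneric("conformationVariables",
           function(x) standardGeneric("conformationVariables"))

#' @rdname chainEnergy
#' @export
setGeneric("energyTerms",
           function(config, params) standardGeneric("energyTerms"))

#' @rdname chainEnergy
#' @export
setGeneric("totalEnergy",
           function(config, params) standardGeneric("totalEnergy"))

#' @rdname QGrid-class
#' @export
setGeneric("qxValues", function(x) standardGeneric("qxValues"))

#' @rdname QGrid-class
#' @export
setGeneric("qzValues", function(x) standardGeneric("qzValues"))

#' @rdname ScatteringMap-class
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname ScatteringMap-class
#' @export
setGeneric("qGrid", function(x) standardGeneric("qGrid"))

#' @rdname flattenMap
#' @export
setGeneric("flattenMap", function(x) standardGeneric("flattenMap"))

#' @rdname ScatteringDataset-class
#' @export
setGeneric("scatteringMatrix", function(x) standardGeneric("scatteringMatrix"))

#' @rdname ScatteringDataset-class
#' @export
setGeneric("targetTable", function(x) standardGeneric("targetTable"))

#' @rdname MCResult-class
#' @export
setGeneric("observables", function(x) standardGeneric("observables"))

#' @rdname MCResult-class
#' @export
setGeneric("chainSamples", function(x) standardGeneric("chainSamples"))

#' @rdname MCResult-class
#' @export
setGeneric("acceptanceRates", function(x) standardGeneric("acceptanceRates"))

#' @rdname MCResult-class
#' @export
setGeneric("energyTrace", function(x) standardGeneric("energyTrace"))

#' @rdname SVDResult-class
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname SVDResult-class
#' @export
setGeneric("rightVectors", function(x) standardGeneric("rightVectors"))
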