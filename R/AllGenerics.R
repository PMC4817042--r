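#' @rdname tsData
#' @export
setGeneric("tsData", function(x) standardGeneric("tsData"))

#' @rdname tsData
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname tsData
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname tsData
#' @export
setGeneric("motionParams", function(x) standardGeneric("motionParams"))

#' @rdname fdValues
#' @export
setGeneric("fdValues", function(x) standardGeneric("fdValues"))

#' @rdname fdValues
#' @export
setGeneric("spikeFlags", function(x) standardGeneric("spikeFlags"))

#' @rdname corValues
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname corValues
#' @export
setGeneric("adjValues", function(x) standardGeneric("adjValues"))

#' @rdname corValues
#' @export
setGeneric("sparsity", function(x) standardGeneric("sparsity"))

#' @rdname phenotype
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname phenotype
#' @export
setGeneric("cohortSeries", function(x) standardGeneric("cohortSeries"))

#' @rdname phenotype
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname nbsComponents
#' @export
setGeneric("nbsComponents", function(x) standardGeneric("nbsComponents"))

#' @rdname nbsComponents
#' @export
setGeneric("correctedP", function(x) standardGeneric("correctedP"))

#' @rdname aucValues
#' @export
setGeneric("aucValues", function(x) standardGeneric("aucValues"))
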