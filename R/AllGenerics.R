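#' @rdname GenotypeExperiment-accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeExperiment-accessors
#' @export
setGeneric("imputedMask", function(x) standardGeneric("imputedMask"))

#' @rdname GenotypeExperiment-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname GenotypeExperiment-accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname GenotypeExperiment-accessors
#' @export
setGeneric("population", function(x) standardGeneric("population"))

#' @rdname GenotypeExperiment-accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname weightMatrix
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname scoreTable
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname scoreTable
#' @export
setGeneric("groupSummary", function(x) standardGeneric("groupSummary"))

#' @rdname modelSnps
#' @export
setGeneric("modelSnps", function(x, keptOnly = TRUE) standardGeneric("modelSnps"))
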