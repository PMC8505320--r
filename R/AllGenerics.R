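#' @rdname abundanceMatrix
#' @export
setGeneric("abundanceMatrix", function(x, ...) standardGeneric("abundanceMatrix"))

#' @rdname census-accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname census-accessors
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname census-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname census-accessors
#' @export
setGeneric("censusUnits", function(x) standardGeneric("censusUnits"))

#' @rdname census-accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname census-accessors
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname pairwiseComponents
#' @export
setGeneric("pairwiseComponents",
  function(x, j, k, ...) standardGeneric("pairwiseComponents"))

#' @rdname multiUnitComponents
#' @export
setGeneric("multiUnitComponents",
  function(x, ...) standardGeneric("multiUnitComponents"))

#' @rdname intervalFlows
#' @export
setGeneric("intervalFlows", function(x, ...) standardGeneric("intervalFlows"))

#' @rdname pairwise-indices
#' @export
setGeneric("dSor", function(x, ...) standardGeneric("dSor"))

#' @rdname pairwise-indices
#' @export
setGeneric("dBC", function(x, ...) standardGeneric("dBC"))

#' @rdname pairwise-indices
#' @export
setGeneric("dMR", function(x, ...) standardGeneric("dMR"))

#' @rdname pairwise-indices
#' @export
setGeneric("vS", function(x, ...) standardGeneric("vS"))

#' @rdname multiunit-indices
#' @export
setGeneric("dSorMu", function(x, ...) standardGeneric("dSorMu"))

#' @rdname multiunit-indices
#' @export
setGeneric("dBCMu", function(x, ...) standardGeneric("dBCMu"))

#' @rdname multiunit-indices
#' @export
setGeneric("dMRMu", function(x, ...) standardGeneric("dMRMu"))

#' @rdname multiunit-indices
#' @export
setGeneric("vSMu", function(x, ...) standardGeneric("vSMu"))
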