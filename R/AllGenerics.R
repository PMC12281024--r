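#' @rdname ReplicateCounts
#' @export
setGeneric("motuMeta", function(x) standardGeneric("motuMeta"))

#' @rdname ReplicateCounts
#' @export
setGeneric("replicateSamples", function(x) standardGeneric("replicateSamples"))

#' @rdname CurationResult-class
#' @export
setGeneric("keptReplicates", function(x) standardGeneric("keptReplicates"))

#' @rdname CurationResult-class
#' @export
setGeneric("removedReplicates", function(x) standardGeneric("removedReplicates"))

#' @rdname CurationResult-class
#' @export
setGeneric("removedSamples", function(x) standardGeneric("removedSamples"))

#' @rdname CurationResult-class
#' @export
setGeneric("filterThresholds", function(x) standardGeneric("filterThresholds"))

#' @rdname PathModelResult-class
#' @export
setGeneric("pathCoefficients", function(x) standardGeneric("pathCoefficients"))

#' @rdname SyntheticStudy-class
#' @export
setGeneric("dietReplicates", function(x) standardGeneric("dietReplicates"))

#' @rdname SyntheticStudy-class
#' @export
setGeneric("microbiomeCounts", function(x) standardGeneric("microbiomeCounts"))

#' @rdname SyntheticStudy-class
#' @export
setGeneric("hostData", function(x) standardGeneric("hostData"))

#' @rdname SyntheticStudy-class
#' @export
setGeneric("truthRegistry", function(x) standardGeneric("truthRegistry"))

#' @rdname PermanovaResult-class
#' @export
setGeneric("permanovaTable", function(x) standardGeneric("permanovaTable"))
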