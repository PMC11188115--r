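#' @rdname taggedChromosome
#' @param x a TaggedChromosome (or object with genes).
#' @export
setGeneric("tags", function(x) standardGeneric("tags"))

#' @rdname taggedChromosome
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname taggedChromosome
#' @export
setGeneric("nTagged", function(x) standardGeneric("nTagged"))

#' @rdname Segmentation-class
#' @param x a Segmentation.
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' @rdname Segmentation-class
#' @export
setGeneric("segTable", function(x) standardGeneric("segTable"))

#' @rdname Segmentation-class
#' @export
setGeneric("segBIC", function(x) standardGeneric("segBIC"))

#' @rdname Segmentation-class
#' @export
setGeneric("segLogLik", function(x) standardGeneric("segLogLik"))

#' @rdname PresenceMatrix-class
#' @param x a PresenceMatrix.
#' @export
setGeneric("assemblyIds", function(x) standardGeneric("assemblyIds"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))
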