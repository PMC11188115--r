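#' @import methods
NULL

#' Genus-wide assembly-by-cluster presence matrix
#'
#' A boolean table recording, for every genome assembly of a genus, which
#' protein clusters have at least one member encoded in that assembly.
#' Presence is boolean regardless of paralog count. The matrix is the input
#' boundary of the gene-age pipeline: protein clustering itself (e.g. at 0.5
#' sequence similarity) is performed upstream.
#'
#' @slot presence logical matrix; rows are assemblies, columns are protein
#'   clusters, with unique dimnames. Every assembly contains at least one
#'   cluster and every cluster is present in at least one assembly.
#'
#' @seealso [presenceMatrix()], [curateAssemblies()], [clusterCommonality()]
#' @export
setClass("PresenceMatrix", representation(presence = "matrix"))

setValidity("PresenceMatrix", function(object) {
    p <- object@presence
    if (!is.logical(p))
        return("'presence' must be a logical matrix")
    if (nrow(p) < 1L || ncol(p) < 1L)
        return("presence matrix must have at least one assembly and one cluster")
    if (is.null(rownames(p)) || is.null(colnames(p)))
        return("presence matrix must carry assembly and cluster identifiers as dimnames")
    if (anyDuplicated(rownames(p)))
        return("duplicated assembly identifiers")
    if (anyDuplicated(colnames(p)))
        return("duplicated cluster identifiers")
    if (anyNA(p))
        return("presence matrix must not contain NA")
    if (any(rowSums(p) == 0L))
        return("every assembly must contain at least one cluster")
    if (any(colSums(p) == 0L))
        return("every cluster must be present in at least one assembly")
    TRUE
})

#' Construct a PresenceMatrix
#'
#' @param presence a logical or 0/1 numeric matrix (assemblies x clusters)
#'   with dimnames identifying assemblies (rows) and clusters (columns).
#'
#' @return a [PresenceMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 1, 1, 0, 1, 1, 0, 0, 1), nrow = 3,
#'             dimnames = list(paste0("asm", 1:3), c("A", "B", "C")))
#' presenceMatrix(m)
#' @export
presenceMatrix <- function(presence) {
    if (is.numeric(presence)) {
        storage.mode(presence) <- "logical"
    }
    new("PresenceMatrix", presence = presence)
}

#' Circular binary-tagged chromosome
#'
#' The universal analysis substrate: an ordered, circular sequence of genes,
#' each carrying a binary attribute (tag) such as "young", "ancient" or
#' "essential". All index arithmetic on the sequence is modulo the gene count.
#'
#' @slot tags integer vector of 0/1 attribute values in gene order.
#'
#' @seealso [taggedChromosome()], [segmentChromosome()], [mscProfile()]
#' @export
setClass("TaggedChromosome", representation(tags = "integer"))

setValidity("TaggedChromosome", function(object) {
    a <- object@tags
    if (length(a) < 1L)
        return("chromosome must contain at least one gene")
    if (anyNA(a) || !all(a %in% c(0L, 1L)))
        return("tags must be 0 or 1 with no NA")
    TRUE
})

#' Construct a TaggedChromosome
#'
#' @param tags a vector of 0/1 (or logical) gene attributes in chromosomal
#'   order; the sequence is treated as circular.
#'
#' @return a [TaggedChromosome-class] object.
#' @examples
#' taggedChromosome(c(1, 1, 0, 0, 1, 0))
#' @export
taggedChromosome <- function(tags) {
    new("TaggedChromosome", tags = as.integer(tags))
}

#' Circular segmentation of a tagged chromosome
#'
#' A tiling of the circular gene string into contiguous segments, each with a
#' gene count and a tagged-gene count, together with the binomial
#' log-likelihood and BIC bookkeeping used by the greedy merge procedure.
#' Segment coordinates are 0-based half-open gene-index intervals
#' `[start, start + length)` taken modulo `N`.
#'
#' @slot start integer, 0-based start gene index of each segment.
#' @slot n integer, segment lengths in genes; sums to `N`.
#' @slot m integer, tagged genes per segment; sums to `M`.
#' @slot N integer, chromosome length in genes.
#' @slot M integer, total tagged genes.
#' @slot logLik numeric, total binomial log-likelihood of the tiling.
#' @slot bic numeric, `(2k - 1) * log(N) - 2 * logLik`.
#'
#' @seealso [segmentChromosome()], [mergeSegments()], [chisqUniformity()],
#'   [enrichmentSummary()]
#' @export
setClass("Segmentation", representation(
    start = "integer", n = "integer", m = "integer",
    N = "integer", M = "integer",
    logLik = "numeric", bic = "numeric"))

setValidity("Segmentation", function(object) {
    k <- length(object@n)
    if (k < 1L) return("segmentation must contain at least one segment")
    if (length(object@start) != k || length(object@m) != k)
        return("'start', 'n' and 'm' must have equal length")
    if (any(object@n < 1L)) return("segment lengths must be >= 1")
    if (any(object@m < 0L) || any(object@m > object@n))
        return("tagged counts must satisfy 0 <= m <= n")
    if (sum(object@n) != object@N) return("segment lengths must sum to N")
    if (sum(object@m) != object@M) return("tagged counts must sum to M")
    if (any(object@start < 0L) || any(object@start >= object@N))
        return("segment starts must be 0-based gene indices in [0, N)")
    nxt <- (object@start + object@n) %% object@N
    if (k > 1L && any(nxt != object@start[c(2:k, 1L)]))
        return("segments must tile the circle contiguously")
    TRUE
})
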