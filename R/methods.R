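#' @describeIn PresenceMatrix-class assembly identifiers (row names).
#' @export
setMethod("assemblyIds", "PresenceMatrix", function(x) rownames(x@presence))

#' @describeIn PresenceMatrix-class cluster identifiers (column names).
#' @export
setMethod("clusterIds", "PresenceMatrix", function(x) colnames(x@presence))

#' @describeIn PresenceMatrix-class the logical presence matrix.
#' @export
setMethod("presence", "PresenceMatrix", function(x) x@presence)

setMethod("show", "PresenceMatrix", function(object) {
    p <- object@presence
    cat("PresenceMatrix:", nrow(p), "assemblies x", ncol(p), "clusters\n")
    cat("  fill:", round(mean(p), 3),
        " clusters/assembly (median):", stats::median(rowSums(p)), "\n")
})

#' @describeIn taggedChromosome gene attribute vector (0/1).
#' @export
setMethod("tags", "TaggedChromosome", function(x) x@tags)

#' @describeIn taggedChromosome number of genes N.
#' @export
setMethod("nGenes", "TaggedChromosome", function(x) length(x@tags))

#' @describeIn taggedChromosome number of tagged genes M.
#' @export
setMethod("nTagged", "TaggedChromosome", function(x) sum(x@tags))

setMethod("show", "TaggedChromosome", function(object) {
    N <- length(object@tags)
    M <- sum(object@tags)
    cat("TaggedChromosome: ", N, " genes, ", M, " tagged (density ",
        round(M / N, 3), ")\n", sep = "")
})

#' @describeIn Segmentation-class number of segments k.
#' @export
setMethod("nSegments", "Segmentation", function(x) length(x@n))

#' @describeIn Segmentation-class chromosome length in genes.
#' @export
setMethod("nGenes", "Segmentation", function(x) x@N)

#' @describeIn Segmentation-class total tagged genes.
#' @export
setMethod("nTagged", "Segmentation", function(x) x@M)

#' @describeIn Segmentation-class total binomial log-likelihood.
#' @export
setMethod("segLogLik", "Segmentation", function(x) x@logLik)

#' @describeIn Segmentation-class BIC score `(2k - 1) log N - 2 L`.
#' @export
setMethod("segBIC", "Segmentation", function(x) x@bic)

#' @describeIn Segmentation-class one row per segment: start (0-based),
#'   length, tagged count, density, and class ("enriched" when density
#'   exceeds the chromosome average, otherwise "depleted").
#' @export
setMethod("segTable", "Segmentation", function(x) {
    dens <- x@m / x@n
    data.frame(
        segment = seq_along(x@n),
        start = x@start,
        length = x@n,
        tagged = x@m,
        density = dens,
        class = ifelse(dens > x@M / x@N, "enriched", "depleted"),
        stringsAsFactors = FALSE)
})

setMethod("show", "Segmentation", function(object) {
    k <- length(object@n)
    cat("Segmentation: k = ", k, " segments over ", object@N, " genes (",
        object@M, " tagged)\n", sep = "")
    cat("  logLik = ", format(object@logLik, digits = 6),
        ", BIC = ", format(object@bic, digits = 6), "\n", sep = "")
    if (k <= 12L) {
        print(segTable(object), row.names = FALSE)
    } else {
        cat("  segment lengths: ", paste(utils::head(object@n, 10L),
            collapse = ", "), ", ...\n", sep = "")
    }
})
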