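#' Curate a genus-wide assembly set
#'
#' Removes redundant assemblies (identical cluster content) and filters
#' outlier assemblies using the rightmost peak of the gene commonality curve.
#' With `k` deduplicated assemblies and `n_i` the number of clusters present
#' in exactly `i` assemblies, the peak `i* = argmax_{i in ceiling(k/2)..k} n_i`
#' is located (ties broken toward larger `i`, preferring the stricter core
#' set); only assemblies containing at least one member of every cluster whose
#' count equals `i*` are retained. Clusters left with no carrier are dropped.
#' The operation is idempotent.
#'
#' @param pm a [PresenceMatrix-class].
#'
#' @return a curated [PresenceMatrix-class].
#' @examples
#' m <- matrix(c(1,1,1,1,1, 1,1,1,1,0, 1,0,0,0,0), nrow = 5,
#'             dimnames = list(paste0("asm", 1:5), c("A", "B", "C")))
#' curateAssemblies(presenceMatrix(m))
#' @export
curateAssemblies <- function(pm) {
    stopifnot(is(pm, "PresenceMatrix"))
    p <- pm@presence
    if (nrow(p) >= 2L) {
        key <- apply(p, 1L, function(r) paste(as.integer(r), collapse = ""))
        p <- p[!duplicated(key), , drop = FALSE]
    }
    k <- nrow(p)
    counts <- colSums(p)
    lo <- as.integer(ceiling(k / 2))
    ni <- tabulate(counts, nbins = k)
    upper <- ni[lo:k]
    if (all(upper == 0L))
        stop("no-core-peak: no cluster is present in the upper half of assemblies")
    # argmax with ties broken toward larger i
    istar <- lo + max(which(upper == max(upper))) - 1L
    peak <- counts == istar
    keep <- rowSums(p[, peak, drop = FALSE]) == sum(peak)
    if (!any(keep))
        stop("no-core-peak: no assembly carries the full peak-bin cluster set")
    p <- p[keep, , drop = FALSE]
    p <- p[, colSums(p) > 0L, drop = FALSE]
    new("PresenceMatrix", presence = p)
}

#' Per-cluster commonality across a genus
#'
#' For each protein cluster, the number of assemblies harboring at least one
#' member, and the same as a fraction of the assembly count. Commonality is
#' the operational proxy for gene age: clusters shared by most of the genus
#' likely descend from its last common ancestor, rare clusters are likely
#' recent acquisitions.
#'
#' @param pm a [PresenceMatrix-class] (usually curated).
#'
#' @return a data.frame with columns `cluster_id`, `count`, `fraction`.
#' @examples
#' m <- matrix(c(1,1,1, 1,1,0, 1,0,0), nrow = 3,
#'             dimnames = list(paste0("asm", 1:3), c("A", "B", "C")))
#' clusterCommonality(presenceMatrix(m))
#' @export
clusterCommonality <- function(pm) {
    stopifnot(is(pm, "PresenceMatrix"))
    counts <- colSums(pm@presence)
    data.frame(
        cluster_id = colnames(pm@presence),
        count = as.integer(counts),
        fraction = as.numeric(counts) / nrow(pm@presence),
        stringsAsFactors = FALSE)
}

# inclusive tertile thresholds for a vector of commonality values:
# q_low is the ceiling(n/3)-th smallest value, q_high the ceiling(n/3)-th
# largest, so that the bottom and top thirds (boundary values included)
# each cover at least a third of the list.
.tertiles <- function(v) {
    n <- length(v)
    if (n < 3L)
        stop("degenerate-quantile: need at least 3 commonality values, got ", n)
    s <- sort(v)
    i <- as.integer(ceiling(n / 3))
    c(qLow = s[i], qHigh = s[n - i + 1L])
}

#' Genus and per-genome commonality thresholds
#'
#' Compiles, for each genome, the list of commonality fractions of the
#' clusters it encodes, and takes the inclusive tertile thresholds: `qLow` is
#' the smallest value such that at least a third of the list is at or below
#' it, `qHigh` the largest value such that at least a third of the list is at
#' or above it. Genus-wide thresholds are computed identically from the
#' pooled per-genome lists (a cluster contributes once per genome carrying
#' it).
#'
#' @param pm a curated [PresenceMatrix-class].
#' @param ct optional commonality table from [clusterCommonality()]; computed
#'   from `pm` when missing.
#'
#' @return an object of class `genus_thresholds`: a list with `qLow`, `qHigh`
#'   (genus-wide) and `perGenome` (data.frame genome/qLow/qHigh).
#' @export
genusThresholds <- function(pm, ct = clusterCommonality(pm)) {
    stopifnot(is(pm, "PresenceMatrix"))
    frac <- ct$fraction[match(colnames(pm@presence), ct$cluster_id)]
    if (anyNA(frac))
        stop("commonality table does not cover all clusters in the matrix")
    per <- apply(pm@presence, 1L, function(row) .tertiles(frac[row]))
    pooled <- unlist(apply(pm@presence, 1L, function(row) frac[row],
                           simplify = FALSE), use.names = FALSE)
    g <- .tertiles(pooled)
    out <- list(
        qLow = unname(g["qLow"]),
        qHigh = unname(g["qHigh"]),
        perGenome = data.frame(
            genome = rownames(pm@presence),
            qLow = unname(per["qLow", ]),
            qHigh = unname(per["qHigh", ]),
            stringsAsFactors = FALSE))
    class(out) <- "genus_thresholds"
    out
}

#' @export
print.genus_thresholds <- function(x, ...) {
    cat("Genus commonality thresholds: qLow =", round(x$qLow, 4),
        " qHigh =", round(x$qHigh, 4), "\n")
    cat("  per-genome thresholds for", nrow(x$perGenome), "genomes\n")
    invisible(x)
}

#' Classify genes into young / intermediate / ancient
#'
#' A gene is `ancient` when the commonality fraction of its cluster is at or
#' above `qHigh` (inclusive), `young` when strictly below `qLow`, and
#' `intermediate` otherwise.
#'
#' @param genes a named character vector mapping gene identifiers to cluster
#'   identifiers, or a data.frame with columns `gene_id` and `cluster_id`.
#' @param ct commonality table from [clusterCommonality()].
#' @param th thresholds from [genusThresholds()] (genus-wide values are used).
#'
#' @return a data.frame with columns `gene_id`, `cluster_id`,
#'   `commonality_fraction`, `label` (factor young/intermediate/ancient).
#' @export
classifyGeneAges <- function(genes, ct, th) {
    if (is.data.frame(genes)) {
        gid <- as.character(genes$gene_id)
        cid <- as.character(genes$cluster_id)
    } else {
        gid <- names(genes)
        if (is.null(gid)) gid <- paste0("gene", seq_along(genes))
        cid <- as.character(genes)
    }
    idx <- match(cid, ct$cluster_id)
    if (anyNA(idx))
        stop("unmapped-gene: cluster(s) absent from the commonality table: ",
             paste(utils::head(unique(cid[is.na(idx)]), 5L), collapse = ", "))
    f <- ct$fraction[idx]
    lab <- ifelse(f >= th$qHigh, "ancient", ifelse(f < th$qLow, "young", "intermediate"))
    data.frame(
        gene_id = gid,
        cluster_id = cid,
        commonality_fraction = f,
        label = factor(lab, levels = c("young", "intermediate", "ancient")),
        stringsAsFactors = FALSE)
}

#' Select the representative genome of a genus
#'
#' The genome whose individual tertile thresholds are closest (Euclidean
#' distance over the pair) to the genus-wide thresholds; ties are broken by
#' lexicographic genome identifier.
#'
#' @param th thresholds from [genusThresholds()].
#'
#' @return the genome identifier (character scalar).
#' @export
representativeGenome <- function(th) {
    pg <- th$perGenome
    if (nrow(pg) < 1L) stop("no per-genome thresholds available")
    d <- sqrt((th$qLow - pg$qLow)^2 + (th$qHigh - pg$qHigh)^2)
    cand <- pg$genome[d == min(d)]
    sort(cand)[1L]
}
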