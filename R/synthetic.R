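# Synthetic-data generators: blocky tagged chromosomes with realistic
# segment statistics, permuted and block-shuffled null controls, and
# U-shaped pangenome presence matrices. All generators are deterministic
# under a fixed seed.

#' Specify a blocky chromosome layout
#'
#' Alternating enriched/depleted blocks tile `n_genes`; the final depleted
#' block absorbs the remainder so the circular alternation is clean. Block
#' lengths and densities are drawn uniformly from the given ranges,
#' independently per block. The `"realistic"` preset mirrors the
#' young-gene segment statistics typical of prokaryotic chromosomes:
#' enriched blocks of 120-210 genes with tagged-gene density 0.50-0.67,
#' depleted blocks of 180-320 genes with density chosen so the enrichment
#' factor falls in 2.6-4.2, giving an overall tagged fraction near 1/3.
#'
#' @param n_genes chromosome length in genes.
#' @param enriched_length,depleted_length length ranges `c(min, max)` in genes.
#' @param enriched_density density range of tagged genes in enriched blocks.
#' @param enrichment_factor range of the ratio enriched/depleted density from
#'   which each depleted block's density is derived.
#' @param depleted_density optional explicit density range for depleted
#'   blocks; overrides `enrichment_factor` (use `c(0, 0)` with
#'   `enriched_density = c(1, 1)` for deterministic solid blocks).
#' @param preset `"realistic"` fills all defaults; `"none"` uses the supplied
#'   values as-is.
#'
#' @return a list of class `block_spec`.
#' @export
blockySpec <- function(n_genes = 3000,
                       enriched_length = c(120, 210),
                       depleted_length = c(180, 320),
                       enriched_density = c(0.50, 0.67),
                       enrichment_factor = c(2.6, 4.2),
                       depleted_density = NULL,
                       preset = c("realistic", "none")) {
    preset <- match.arg(preset)
    stopifnot(n_genes >= 4, enriched_length[1L] >= 1, depleted_length[1L] >= 1,
              all(enriched_density >= 0 & enriched_density <= 1),
              all(enrichment_factor >= 1),
              is.null(depleted_density) ||
                  all(depleted_density >= 0 & depleted_density <= 1))
    structure(list(n_genes = as.integer(n_genes),
                   enriched_length = enriched_length,
                   depleted_length = depleted_length,
                   enriched_density = enriched_density,
                   enrichment_factor = enrichment_factor,
                   depleted_density = depleted_density),
              class = "block_spec")
}

#' Generate a blocky tagged chromosome
#'
#' Tiles the circle with alternating enriched and depleted blocks per the
#' spec and draws each gene's tag independently from its block's Bernoulli
#' density. The ground-truth block table is returned for recovery tests.
#'
#' @param spec a `block_spec` from [blockySpec()].
#' @param seed optional integer seed.
#'
#' @return a list with `chromosome` (a [TaggedChromosome-class]) and `blocks`
#'   (data.frame: start (0-based), length, density, class).
#' @examples
#' out <- synthBlocky(blockySpec(2000), seed = 1)
#' nSegments(segmentChromosome(out$chromosome))
#' @export
synthBlocky <- function(spec, seed = NULL) {
    stopifnot(inherits(spec, "block_spec"))
    if (!is.null(seed)) set.seed(seed)
    N <- spec$n_genes
    drawEnr <- function() list(
        l = as.integer(round(stats::runif(1, spec$enriched_length[1L],
                                          spec$enriched_length[2L]))),
        d = stats::runif(1, spec$enriched_density[1L], spec$enriched_density[2L]))
    drawDep <- function() {
        l <- as.integer(round(stats::runif(1, spec$depleted_length[1L],
                                           spec$depleted_length[2L])))
        if (!is.null(spec$depleted_density)) {
            d <- stats::runif(1, spec$depleted_density[1L],
                              spec$depleted_density[2L])
        } else {
            de <- stats::runif(1, spec$enriched_density[1L],
                               spec$enriched_density[2L])
            d <- de / stats::runif(1, spec$enrichment_factor[1L],
                                   spec$enrichment_factor[2L])
        }
        list(l = l, d = d)
    }
    # tile with enriched/depleted pairs; the final depleted block absorbs the
    # remainder so the circle always alternates cleanly (first block enriched,
    # last depleted) and no sliver blocks are produced
    start <- integer(0); len <- integer(0); dens <- numeric(0); cls <- character(0)
    pos <- 0L
    minTail <- min(120L, max(2L, N %/% 4L))
    repeat {
        e <- drawEnr(); dp <- drawDep()
        rem <- N - pos
        if (length(len) > 0L && rem < e$l + minTail) {
            # extend the last (depleted) block to close the circle
            len[length(len)] <- len[length(len)] + rem
            break
        }
        if (rem < e$l + minTail) {           # chromosome shorter than one pair
            e$l <- max(1L, rem %/% 2L)
        }
        if (rem < e$l + dp$l) dp$l <- rem - e$l
        start <- c(start, pos, pos + e$l)
        len <- c(len, e$l, dp$l)
        dens <- c(dens, e$d, dp$d)
        cls <- c(cls, "enriched", "depleted")
        pos <- pos + e$l + dp$l
        if (pos >= N) break
    }
    tags <- unlist(mapply(function(l, d) stats::rbinom(l, 1L, d), len, dens,
                          SIMPLIFY = FALSE))
    # degenerate draws: ensure a non-constant chromosome
    if (sum(tags) == 0L) tags[1L] <- 1L
    if (sum(tags) == length(tags)) tags[1L] <- 0L
    list(chromosome = taggedChromosome(tags),
         blocks = data.frame(start = start, length = len, density = dens,
                             class = cls, stringsAsFactors = FALSE))
}

#' Random permutation control
#'
#' Uniformly permutes the gene order, preserving the tagged-gene count but
#' destroying all positional structure. Segmenting such a control yields a
#' single uniform segment in the vast majority of draws.
#'
#' @param chrom a [TaggedChromosome-class].
#' @param seed optional integer seed.
#'
#' @return a permuted [TaggedChromosome-class].
#' @export
synthPermute <- function(chrom, seed = NULL) {
    stopifnot(is(chrom, "TaggedChromosome"))
    if (!is.null(seed)) set.seed(seed)
    taggedChromosome(sample(chrom@tags))
}

#' Block-shuffle control
#'
#' Extracts the maximal runs of equal tags and re-concatenates them in random
#' order, shuffling tagged runs among themselves and untagged runs among
#' themselves while preserving the alternation, so both the run count and the
#' per-class run-length multisets are exactly conserved. This destroys
#' long-range arrangement while keeping local cluster sizes.
#'
#' @param chrom a non-constant [TaggedChromosome-class].
#' @param seed optional integer seed.
#'
#' @return a block-shuffled [TaggedChromosome-class].
#' @export
synthBlockShuffle <- function(chrom, seed = NULL) {
    stopifnot(is(chrom, "TaggedChromosome"))
    a <- chrom@tags
    if (sum(a) == 0L || sum(a) == length(a))
        stop("constant-attribute: cannot block-shuffle a constant sequence")
    if (!is.null(seed)) set.seed(seed)
    r <- rle(a)
    # circular: merge first and last runs if they share a value
    nr <- length(r$values)
    if (nr > 1L && r$values[1L] == r$values[nr]) {
        r$lengths[1L] <- r$lengths[1L] + r$lengths[nr]
        r$lengths <- r$lengths[-nr]
        r$values <- r$values[-nr]
        nr <- nr - 1L
    }
    ones <- r$lengths[r$values == 1L]
    zeros <- r$lengths[r$values == 0L]
    ones <- ones[sample.int(length(ones))]
    zeros <- zeros[sample.int(length(zeros))]
    firstVal <- r$values[1L]
    lens <- integer(nr); vals <- integer(nr)
    io <- 1L; iz <- 1L
    for (i in seq_len(nr)) {
        v <- if (i %% 2L == 1L) firstVal else 1L - firstVal
        vals[i] <- v
        if (v == 1L) { lens[i] <- ones[io]; io <- io + 1L }
        else { lens[i] <- zeros[iz]; iz <- iz + 1L }
    }
    taggedChromosome(rep(vals, lens))
}

#' Generate a U-shaped pangenome presence matrix
#'
#' Each cluster draws a carriage probability from a mixture of components
#' (e.g. a core component near 1, a cloud component near `1/n_assemblies`,
#' and optionally a shell component in between); presence is then sampled
#' independently per assembly. Clusters present in no assembly and assemblies
#' carrying no cluster are resampled. The resulting commonality histogram has
#' the asymmetrical U-shape typical of genus pangenomes.
#'
#' The `"tertile"` preset balances the expected per-genome gene complement
#' across the three components (cloud : shell : core cluster counts in
#' proportion 10 : 2 : 1 at carriage ~0.1 / ~0.5 / 1), so that roughly a
#' third of each genome's genes falls in each commonality tertile.
#'
#' @param n_assemblies number of assemblies (`>= 5`).
#' @param n_clusters number of protein clusters.
#' @param mixture a list of components, each `list(weight =, p = c(lo, hi))`;
#'   carriage probabilities are drawn uniformly from `p`. Ignored when a
#'   preset is chosen.
#' @param preset `"tertile"` (balanced thirds), `"ushape"` (generic
#'   asymmetric U), or `"custom"` (use `mixture`).
#' @param seed optional integer seed.
#'
#' @return a [PresenceMatrix-class].
#' @examples
#' pm <- synthPangenome(30, 650, seed = 1)
#' hist(clusterCommonality(pm)$fraction, breaks = 20)
#' @export
synthPangenome <- function(n_assemblies, n_clusters,
                           mixture = NULL,
                           preset = c("tertile", "ushape", "custom"),
                           seed = NULL) {
    preset <- match.arg(preset)
    n_assemblies <- as.integer(n_assemblies)
    n_clusters <- as.integer(n_clusters)
    stopifnot(n_assemblies >= 5L, n_clusters >= 3L)
    if (!is.null(seed)) set.seed(seed)
    if (preset == "tertile") {
        mixture <- list(
            list(weight = 10 / 13, p = c(0.05, 0.15)),
            list(weight = 2 / 13, p = c(0.45, 0.55)),
            list(weight = 1 / 13, p = c(1, 1)))
    } else if (preset == "ushape") {
        mixture <- list(
            list(weight = 0.60, p = c(1 / n_assemblies, 0.10)),
            list(weight = 0.15, p = c(0.20, 0.80)),
            list(weight = 0.25, p = c(0.90, 1.00)))
    }
    if (is.null(mixture)) stop("a mixture must be supplied for preset = 'custom'")
    wts <- vapply(mixture, `[[`, numeric(1L), "weight")
    comp <- sample.int(length(mixture), n_clusters, replace = TRUE,
                       prob = wts / sum(wts))
    pr <- vapply(seq_len(n_clusters), function(i) {
        rng <- mixture[[comp[i]]]$p
        stats::runif(1, rng[1L], rng[2L])
    }, numeric(1L))
    draw <- function(p) stats::runif(n_assemblies) < p
    mat <- vapply(pr, function(p) {
        col <- draw(p)
        while (!any(col)) col <- draw(p)   # resample empty clusters
        col
    }, logical(n_assemblies))
    # resample assemblies that ended up empty (vanishingly rare)
    empty <- rowSums(mat) == 0L
    while (any(empty)) {
        i <- which(empty)[1L]
        mat[i, ] <- stats::runif(n_clusters) < pr
        empty <- rowSums(mat) == 0L
    }
    dimnames(mat) <- list(sprintf("asm%03d", seq_len(n_assemblies)),
                          sprintf("cl%05d", seq_len(n_clusters)))
    new("PresenceMatrix", presence = mat)
}
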