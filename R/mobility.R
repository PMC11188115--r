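# Model 2: gene-order evolution with differential gene mobility and
# translocation attractors. Genes are low-mobility (relative translocation
# rate 1) or high-mobility (rate 1 + beta); a few high-mobility genes are
# attractors that bias translocation destinations toward their neighborhood.

#' Construct a mobility-model genome
#'
#' A circular chromosome of `N` genes: `M` low-mobility, `N - M`
#' high-mobility, of which `a` are attractors. By default genes are arranged
#' uniformly at random; explicit `classes`/`attractors` vectors may be given.
#' Attractors are intrinsic labels on specific high-mobility genes and travel
#' with them when they translocate.
#'
#' @param N total genes.
#' @param M low-mobility genes, `0 < M < N`.
#' @param a attractor genes among the `N - M` high-mobility genes, `>= 1`.
#' @param classes optional 0/1 vector (1 = high mobility) of length `N`.
#' @param attractors optional 0/1 vector flagging attractor genes; must be a
#'   subset of the high-mobility genes.
#'
#' @return an object of class `mobility_genome`: list with integer vectors
#'   `high` (1 = high mobility) and `attractor`.
#' @export
mobilityGenome <- function(N, M, a, classes = NULL, attractors = NULL) {
    N <- as.integer(N); M <- as.integer(M); a <- as.integer(a)
    stopifnot(N >= 3L, M >= 1L, M < N, a >= 1L, a <= N - M)
    if (is.null(classes)) {
        high <- integer(N)
        high[sample.int(N, N - M)] <- 1L
    } else {
        high <- as.integer(classes)
        stopifnot(length(high) == N, sum(high) == N - M)
    }
    if (is.null(attractors)) {
        att <- integer(N)
        att[sample(which(high == 1L), a)] <- 1L
    } else {
        att <- as.integer(attractors)
        stopifnot(length(att) == N, sum(att) == a, all(high[att == 1L] == 1L))
    }
    structure(list(high = high, attractor = att), class = "mobility_genome")
}

#' @export
print.mobility_genome <- function(x, ...) {
    N <- length(x$high)
    cat("MobilityGenome:", N, "genes;", N - sum(x$high), "low-mobility,",
        sum(x$high), "high-mobility,", sum(x$attractor), "attractor(s)\n")
    invisible(x)
}

#' Gene selection probabilities under differential mobility
#'
#' Low-mobility genes have relative translocation rate 1, high-mobility genes
#' `1 + beta`; probabilities are the normalized rates.
#'
#' @param genome a `mobility_genome`.
#' @param beta mobility bonus, `>= 0`.
#'
#' @return numeric probability vector over the `N` genes (sums to 1).
#' @export
mobilityWeights <- function(genome, beta) {
    stopifnot(inherits(genome, "mobility_genome"), beta >= 0)
    w <- 1 + beta * genome$high
    w / sum(w)
}

# circular gene-distance from each intergenic position to the nearest
# attractor gene: IR i sits between gene i and gene i+1 (1-based, circular);
# the two IRs flanking an attractor have distance 0.
.irAttractorDistance <- function(attractor) {
    n <- length(attractor)
    att <- which(attractor == 1L)
    if (length(att) == 0L) return(NULL)
    ir <- seq_len(n)
    d <- rep(Inf, n)
    for (j in att) {
        fwd <- (j - ir - 1L) %% n   # genes strictly between IR i and gene j, clockwise
        bwd <- (ir - j) %% n        # counter-clockwise
        d <- pmin(d, pmin(fwd, bwd))
    }
    d
}

#' Destination probabilities over intergenic regions
#'
#' Each of the `N` intergenic regions (IRs) receives translocations with
#' relative attraction `1 + alpha * exp(-d/gamma)`, where `d` is the circular
#' gene-distance from the IR to the nearest attractor gene (the two IRs
#' flanking an attractor have `d = 0`). Probabilities are the normalized
#' attractions.
#'
#' @param genome a `mobility_genome` with at least one attractor.
#' @param alpha attractor strength, `> -1`; positive values attract, values
#'   in `(-1, 0)` repel (the attraction multiplier `1 + alpha` at `d = 0`
#'   stays positive). The fitting search explores both regimes through the
#'   parameterization `alpha = exp(alpha') - 1`.
#' @param gamma attraction basin width in genes, `> 0` (default 1).
#'
#' @return numeric probability vector over the `N` IRs; IR `i` lies between
#'   genes `i` and `i + 1`.
#' @export
attractionWeights <- function(genome, alpha, gamma = 1) {
    stopifnot(inherits(genome, "mobility_genome"), alpha > -1, gamma > 0)
    d <- .irAttractorDistance(genome$attractor)
    if (is.null(d)) stop("genome has no attractor gene")
    w <- 1 + alpha * exp(-d / gamma)
    w / sum(w)
}

#' One translocation step
#'
#' Samples a gene by the mobility weights, closes its vacated position, then
#' samples a destination IR of the `N - 1`-gene intermediate by the
#' attraction weights and reinserts the gene there. Mobility class and
#' attractor flag travel with the gene, so `N`, `M` and the attractor count
#' are conserved. If the translocating gene was the only attractor, the
#' destination is drawn uniformly.
#'
#' @param genome a `mobility_genome`.
#' @param beta,alpha,gamma model parameters (see [mobilityWeights()] and
#'   [attractionWeights()]).
#'
#' @return the updated `mobility_genome`.
#' @export
translocateStep <- function(genome, beta, alpha, gamma = 1) {
    n <- length(genome$high)
    gi <- sample.int(n, 1L, prob = mobilityWeights(genome, beta))
    high <- genome$high[-gi]
    att <- genome$attractor[-gi]
    d <- .irAttractorDistance(att)
    w <- if (is.null(d)) rep(1, n - 1L) else 1 + alpha * exp(-d / gamma)
    ir <- sample.int(n - 1L, 1L, prob = w)
    # IR ir lies after position ir of the intermediate -> insert at ir + 1
    ins <- function(v, val, pos) append(v, val, after = pos)
    structure(list(high = as.integer(ins(high, genome$high[gi], ir %% (n - 1L))),
                   attractor = as.integer(ins(att, genome$attractor[gi], ir %% (n - 1L)))),
              class = "mobility_genome")
}

#' Simulate the differential-mobility / attractor model
#'
#' Runs `n_epochs` epochs of `epoch_steps` single-gene translocation steps
#' each, recording the binary low/high-mobility sequence (1 = high mobility)
#' at the end of every epoch. With 5-20 attractors, destination bias of 1-2
#' orders of magnitude and low-mobility genes several-fold less mobile, the
#' equilibrium chromosomes segment into alternating regions enriched and
#' depleted in mobile (young) genes.
#'
#' @param genome a `mobility_genome` (e.g. from [mobilityGenome()]).
#' @param beta mobility bonus, `>= 0`.
#' @param alpha attractor strength, `> -1` (see [attractionWeights()]).
#' @param gamma basin width, `> 0` (default 1).
#' @param epoch_steps translocation steps per epoch (default 5000).
#' @param n_epochs number of epochs (default 500).
#' @param seed optional integer seed.
#'
#' @return an object of class `mobility_record`: list with `snapshots`
#'   (matrix `n_epochs` x `N` of 0/1 high-mobility indicators), `final` (the
#'   final `mobility_genome`) and `params`.
#' @examples
#' g <- mobilityGenome(200, 100, a = 2)
#' rec <- simulateMobility(g, beta = 5, alpha = 100,
#'                         epoch_steps = 500, n_epochs = 20, seed = 1)
#' dim(rec$snapshots)
#' @export
simulateMobility <- function(genome, beta, alpha, gamma = 1,
                             epoch_steps = 5000, n_epochs = 500, seed = NULL) {
    stopifnot(inherits(genome, "mobility_genome"),
              beta >= 0, alpha > -1, gamma > 0,
              epoch_steps >= 1, n_epochs >= 1,
              sum(genome$attractor) >= 1L)
    if (!is.null(seed)) set.seed(seed)
    res <- simulate_mobility_cpp(genome$high, genome$attractor,
                                 as.numeric(beta), as.numeric(alpha),
                                 as.numeric(gamma),
                                 as.integer(epoch_steps), as.integer(n_epochs))
    structure(list(
        snapshots = res$snapshots,
        final = structure(list(high = as.integer(res$high),
                               attractor = as.integer(res$attractor)),
                          class = "mobility_genome"),
        params = list(N = length(genome$high),
                      M = length(genome$high) - sum(genome$high),
                      a = sum(genome$attractor), beta = beta, alpha = alpha,
                      gamma = gamma, epoch_steps = epoch_steps,
                      n_epochs = n_epochs)),
        class = "mobility_record")
}

#' @export
print.mobility_record <- function(x, ...) {
    p <- x$params
    cat("Mobility-model record: N =", p$N, " M(low) =", p$M, " a =", p$a,
        " beta =", p$beta, " alpha =", p$alpha, " gamma =", p$gamma, "\n")
    cat("  ", p$n_epochs, "epochs x", p$epoch_steps, "steps\n")
    invisible(x)
}
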