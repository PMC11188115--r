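# Model 1: gene-order evolution under selection against multi-gene disruption
# of essential genes, with origin-fixation (Moran) acceptance dynamics.

#' Construct a disruption-model genome
#'
#' A circular chromosome of `N` genes with `M` marked essential. With
#' `arrangement = "random"` the essential genes are placed uniformly at
#' random; `"block"` places them in one contiguous block; `"spread"` places
#' them (approximately) evenly around the circle.
#'
#' @param N total genes.
#' @param M essential genes, `0 < M < N`.
#' @param arrangement one of "random", "block", "spread", or an explicit 0/1
#'   vector of length `N` with `M` ones.
#'
#' @return an integer 0/1 vector of length `N` (1 = essential) with class
#'   `disruption_genome`.
#' @export
disruptionGenome <- function(N, M, arrangement = "random") {
    N <- as.integer(N); M <- as.integer(M)
    stopifnot(N >= 2L, M >= 1L, M < N)
    if (is.numeric(arrangement) && length(arrangement) == N) {
        g <- as.integer(arrangement)
        stopifnot(all(g %in% c(0L, 1L)), sum(g) == M)
    } else {
        g <- integer(N)
        pos <- switch(match.arg(arrangement, c("random", "block", "spread")),
            random = sample.int(N, M),
            block = seq_len(M),
            spread = unique(as.integer(round(seq(1L, N, length.out = M + 1L)[-(M + 1L)]))))
        g[pos] <- 1L
    }
    structure(g, class = "disruption_genome")
}

#' Fraction of lethal k-gene disruption windows
#'
#' The fraction `f` of the `N` circular windows of `k` adjacent genes that
#' contain at least one essential gene. Disruption events landing in such
#' windows are lethal. Closed forms at the extremes: a single contiguous
#' block of `M` essential genes gives `f = (M + k - 1)/N`; maximally
#' dispersed essential genes (pairwise separation at least `k-1`) give
#' `f = M k / N`.
#'
#' @param genome 0/1 essentiality vector (1 = essential), circular.
#' @param k disruption width in genes, `2 <= k <= N`.
#'
#' @return `f` in `[0, 1]`.
#' @examples
#' g <- disruptionGenome(100, 30, "block")
#' lethalFraction(g, 2)  # (30 + 2 - 1) / 100
#' @export
lethalFraction <- function(genome, k) {
    e <- as.integer(genome)
    N <- length(e)
    k <- as.integer(k)
    stopifnot(k >= 1L, k <= N)
    if (sum(e) == 0L) return(0)
    cs <- cumsum(c(0L, e, e[seq_len(k - 1L)]))
    wins <- cs[seq_len(N) + k] - cs[seq_len(N)]
    mean(wins > 0L)
}

#' Moran fixation probability
#'
#' `P = (1 - exp(-s)) / (1 - exp(-Ne * s))` for a configuration with
#' selection coefficient `s` arising in a population of effective size `Ne`
#' under the low-mutation (origin-fixation) regime. The neutral limit
#' `s -> 0` returns exactly `1/Ne`.
#'
#' @param s selection coefficient.
#' @param Ne effective population size, `>= 2`.
#'
#' @return fixation probability in `[0, 1]`.
#' @examples
#' moranFixation(0, 1e4)            # 1/Ne
#' moranFixation(-3.5e-4, 1e4)      # ~10-fold below neutral
#' @export
moranFixation <- function(s, Ne) {
    stopifnot(Ne >= 2)
    if (abs(Ne * s) < 1e-8) return(1 / Ne)
    if (Ne * s < -700) {
        # deep in the deleterious tail: P ~ exp((Ne - 1) s)
        return(exp((Ne - 1) * s) * max(-expm1(-s), 0))
    }
    (-expm1(-s)) / (-expm1(-Ne * s))
}

#' Fixation probability of a gene-order rearrangement
#'
#' Configurations `G0` and `G1` with lethal fractions `f0` and `f1` under a
#' disruption rate of `r` events per genome per generation have survival
#' probabilities `exp(-r f)`; the selection coefficient of the transition is
#' `s = exp(r (f0 - f1)) - 1` and fixation follows the Moran formula.
#'
#' @param f0,f1 lethal fractions of the current and proposed configurations.
#' @param r disruption events per genome per generation, `> 0`.
#' @param Ne effective population size, `>= 2`.
#'
#' @return fixation probability.
#' @export
fixationProbability <- function(f0, f1, r, Ne) {
    stopifnot(r > 0)
    moranFixation(expm1(r * (f0 - f1)), Ne)
}

#' Number of contiguous essential-gene blocks
#'
#' Maximal circular runs of essential genes; positions `N` and `1` are
#' adjacent, so a run spanning the origin counts once.
#'
#' @param genome 0/1 essentiality vector.
#'
#' @return integer block count (0 when no gene is essential).
#' @export
countBlocks <- function(genome) {
    e <- as.integer(genome)
    n <- length(e)
    if (sum(e) == 0L) return(0L)
    if (sum(e) == n) return(1L)
    # starts of runs of 1s on the circle
    prev <- e[c(n, seq_len(n - 1L))]
    sum(e == 1L & prev == 0L)
}

#' Simulate gene-order evolution under the disruption model
#'
#' Origin-fixation dynamics: at each step a uniformly chosen gene is removed
#' and reinserted at a uniformly chosen position of the circle (identity
#' moves allowed); the proposal is accepted with the Moran fixation
#' probability computed from the lethal fractions of the current and proposed
#' arrangements. Genome size `N` and essential count `M` are conserved.
#' Snapshots (and their contiguous-block counts) are recorded every
#' `record_every` steps, including the initial state.
#'
#' @param genome a `disruption_genome` (or 0/1 vector).
#' @param k disruption width in genes (`>= 2`).
#' @param r disruption events per genome per generation (`> 0`).
#' @param Ne effective population size (`>= 2`).
#' @param steps number of proposal steps.
#' @param record_every steps between snapshots (default 100000).
#' @param seed optional integer seed for reproducibility.
#'
#' @return an object of class `disruption_trajectory`: list with `step`
#'   (snapshot steps), `block_count`, `snapshots` (matrix, one row per
#'   snapshot), `accepted`, `final` (final 0/1 arrangement) and `params`.
#' @examples
#' tr <- evolveDisruption(disruptionGenome(60, 18, "spread"),
#'                        k = 2, r = 10, Ne = 1e4,
#'                        steps = 2e4, record_every = 5e3, seed = 1)
#' tr$block_count
#' @export
evolveDisruption <- function(genome, k, r, Ne, steps,
                             record_every = 1e5, seed = NULL) {
    e <- as.integer(genome)
    N <- length(e)
    M <- sum(e)
    stopifnot(M > 0L, M < N, k >= 2L, k <= N, r > 0, Ne >= 2, steps >= 1)
    if (!is.null(seed)) set.seed(seed)
    res <- evolve_disruption_cpp(e, as.integer(k), as.numeric(r),
                                 as.numeric(Ne), as.numeric(steps),
                                 as.numeric(record_every))
    structure(list(
        step = res$step,
        block_count = res$block_count,
        snapshots = res$snapshots,
        accepted = res$accepted,
        final = as.integer(res$final),
        params = list(N = N, M = M, k = k, r = r, Ne = Ne, steps = steps,
                      record_every = record_every)),
        class = "disruption_trajectory")
}

#' @export
print.disruption_trajectory <- function(x, ...) {
    p <- x$params
    cat("Disruption-model trajectory: N =", p$N, " M =", p$M, " k =", p$k,
        " r =", p$r, " Ne =", p$Ne, "\n")
    cat("  ", length(x$step), "snapshots over", format(p$steps, big.mark = ","),
        "steps;", x$accepted, "accepted moves; final block count",
        x$block_count[length(x$block_count)], "\n")
    invisible(x)
}
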