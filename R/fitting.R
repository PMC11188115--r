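# Staged random + grid search fitting of the differential-mobility model to
# a target chromosome, with complexity-profile distance as the objective.

#' Goodness of fit of a mobility-model record to a target chromosome
#'
#' Computes, for every recorded epoch snapshot, the complexity-profile
#' distance to the target chromosome, and returns the inclusive 0.1-quantile
#' (the `ceiling(0.1 * n_epochs)`-th smallest distance; with 500 epochs, the
#' 50th smallest). Using a low quantile rather than the mean rewards
#' parameter sets whose equilibrium visits the target's pattern, without
#' penalizing burn-in epochs.
#'
#' @param record a `mobility_record` from [simulateMobility()].
#' @param target a binary vector or [TaggedChromosome-class] of the same
#'   length as the simulated chromosomes.
#' @param quantile which lower order-quantile of the per-epoch distances to
#'   report (default 0.1).
#'
#' @return a nonnegative scalar; zero only if some snapshots match the
#'   target's profile exactly.
#' @export
goodnessOfFit <- function(record, target, quantile = 0.1) {
    stopifnot(inherits(record, "mobility_record"))
    tg <- .asBinary(target)
    if (length(tg) != ncol(record$snapshots))
        stop("target and simulated chromosomes have different lengths")
    tp <- mscProfile(tg)
    dists <- apply(record$snapshots, 1L, function(row)
        profileDistance(mscProfile(row), tp))
    sort(dists)[max(1L, ceiling(quantile * length(dists)))]
}

.evalParams <- function(a, beta, alpha, gamma, N, M,
                        epoch_steps, n_epochs, target) {
    g <- mobilityGenome(N, M, a)
    rec <- simulateMobility(g, beta = beta, alpha = alpha, gamma = gamma,
                            epoch_steps = epoch_steps, n_epochs = n_epochs)
    goodnessOfFit(rec, target)
}

#' Fit the mobility model to a target chromosome
#'
#' Three-stage search with the complexity-profile distance objective. The
#' chromosome size `N` and the low-mobility gene count `M` are taken from the
#' target (low-mobility genes correspond to the untagged class); the basin
#' width `gamma` is fixed at 1. Parameters use the logarithmic
#' reparameterization `beta = exp(beta')`, `alpha = exp(alpha') - 1` with
#' `beta'` uniform over `[log 1e-4, log 30]` and `alpha'` over
#' `[log 0.1, log 1000]`.
#'
#' Stage 1 samples `n_samples` uniform `(a, beta', alpha')` triples
#' (`a` integer in `[1, 30]`), each scored by a fresh simulation. Stage 2
#' fixes `a` to the minimum attractor count among near-best stage-1 solutions
#' (within 5% of the best goodness) and scores a `grid_n x grid_n`
#' log-spaced grid over `(beta, alpha)`. Because the stage-2 landscape shows
#' hyperbola-like valleys of near-equivalent `(beta, alpha)` trade-offs,
#' stage 3 fixes `alpha = 100` and performs a 1-D log-spaced search over
#' `beta`, whose optimum is returned.
#'
#' Search sizes default to `n_samples = 2000`, 500 epochs of 5000 steps and a
#' 30x30 grid, and are configurable downward for small studies.
#'
#' @param target binary vector or [TaggedChromosome-class]; 1 marks the
#'   mobile/young class.
#' @param n_samples stage-1 random samples.
#' @param epoch_steps,n_epochs simulation schedule for every evaluation.
#' @param grid_n grid resolution for stages 2 and 3.
#' @param a_max upper bound of the attractor-count range.
#' @param alpha_fixed attractor strength fixed in stage 3 (default 100).
#' @param seed optional integer seed.
#'
#' @return an object of class `mobility_fit`: list with `best` (list `a`,
#'   `beta`, `alpha`, `gamma`, `goodness`), `stage1`, `stage2`, `stage3`
#'   (data.frames of evaluated parameter sets and goodness), and `grid`
#'   (stage-2 goodness matrix, beta rows x alpha columns).
#' @export
fitMobilityModel <- function(target, n_samples = 2000,
                             epoch_steps = 5000, n_epochs = 500,
                             grid_n = 30, a_max = 30, alpha_fixed = 100,
                             seed = NULL) {
    tg <- .asBinary(target)
    N <- length(tg)
    M <- as.integer(N - sum(tg))   # low-mobility count from the target
    stopifnot(M >= 1L, M < N)
    if (!is.null(seed)) set.seed(seed)
    bprange <- log(c(1e-4, 30))
    aprange <- log(c(0.1, 1000))

    # stage 1: random search
    a1 <- sample.int(a_max, n_samples, replace = TRUE)
    bp <- stats::runif(n_samples, bprange[1L], bprange[2L])
    ap <- stats::runif(n_samples, aprange[1L], aprange[2L])
    g1 <- vapply(seq_len(n_samples), function(i)
        .evalParams(a1[i], exp(bp[i]), exp(ap[i]) - 1, 1, N, M,
                    epoch_steps, n_epochs, tg), numeric(1L))
    stage1 <- data.frame(a = a1, beta = exp(bp), alpha = exp(ap) - 1,
                         goodness = g1)
    near <- g1 <= min(g1) * 1.05
    aFix <- min(a1[near])

    # stage 2: log-spaced grid over (beta, alpha) at fixed a
    betas <- exp(seq(bprange[1L], bprange[2L], length.out = grid_n))
    alphas <- exp(seq(aprange[1L], aprange[2L], length.out = grid_n)) - 1
    grid <- expand.grid(beta = betas, alpha = alphas)
    g2 <- vapply(seq_len(nrow(grid)), function(i)
        .evalParams(aFix, grid$beta[i], grid$alpha[i], 1, N, M,
                    epoch_steps, n_epochs, tg), numeric(1L))
    stage2 <- data.frame(a = aFix, beta = grid$beta, alpha = grid$alpha,
                         goodness = g2)
    gridMat <- matrix(g2, nrow = grid_n,
                      dimnames = list(beta = signif(betas, 4),
                                      alpha = signif(alphas, 4)))

    # stage 3: 1-D search over beta at fixed alpha
    g3 <- vapply(betas, function(b)
        .evalParams(aFix, b, alpha_fixed, 1, N, M,
                    epoch_steps, n_epochs, tg), numeric(1L))
    stage3 <- data.frame(a = aFix, beta = betas, alpha = alpha_fixed,
                         goodness = g3)
    i3 <- which.min(g3)

    structure(list(
        best = list(a = aFix, beta = betas[i3], alpha = alpha_fixed,
                    gamma = 1, goodness = g3[i3]),
        stage1 = stage1, stage2 = stage2, stage3 = stage3, grid = gridMat,
        target_n = N, target_m_low = M),
        class = "mobility_fit")
}

#' @export
print.mobility_fit <- function(x, ...) {
    b <- x$best
    cat("Mobility-model fit (N =", x$target_n, ", low-mobility M =",
        x$target_m_low, ")\n")
    cat("  best: a =", b$a, " beta =", signif(b$beta, 4),
        " alpha =", b$alpha, " gamma =", b$gamma,
        " goodness =", signif(b$goodness, 4), "\n")
    invisible(x)
}
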