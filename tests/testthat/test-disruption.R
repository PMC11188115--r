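# Disruption model: lethal windows, Moran fixation, evolution dynamics.

test_that("lethal fractions match brute-force enumeration and closed forms", {
    # single block: f = (M + k - 1)/N; maximally dispersed: f = M k / N
    gBlock <- disruptionGenome(100, 30, "block")
    expect_equal(lethalFraction(gBlock, 2), (30 + 2 - 1) / 100)
    gSpread <- disruptionGenome(100, 30, "spread")
    expect_equal(lethalFraction(gSpread, 2), 30 * 2 / 100)
    expect_equal(lethalFraction(rep(0L, 50), 3), 0)

    set.seed(37)
    for (i in 1:25) {
        N <- sample(20:200, 1)
        e <- rbinom(N, 1, runif(1, 0.1, 0.5))
        for (k in 2:5)
            expect_equal(lethalFraction(e, k), bruteLethalFraction(e, k))
    }
})

test_that("for k = 2 the lethal window count equals M plus the block count", {
    set.seed(43)
    for (i in 1:20) {
        N <- sample(30:150, 1)
        e <- rbinom(N, 1, 0.3)
        if (sum(e) == 0 || sum(e) == N) next
        expect_equal(round(lethalFraction(e, 2) * N), sum(e) + countBlocks(e))
    }
})

test_that("a single essential block minimizes the lethal fraction", {
    set.seed(51)
    for (i in 1:10) {
        N <- 80
        M <- sample(10:40, 1)
        e <- integer(N); e[sample.int(N, M)] <- 1L
        for (k in 2:4) {
            expect_gte(lethalFraction(e, k), (M + k - 1) / N)
            expect_lte(lethalFraction(e, k), min(1, M * k / N))
        }
    }
})

test_that("Moran fixation is continuous at 0, monotone, and correct in the tails", {
    expect_equal(moranFixation(0, 1e4), 1e-4)
    expect_equal(fixationProbability(0.3, 0.3, r = 5, Ne = 50), 1 / 50)
    # continuity across the small-s branch
    expect_equal(moranFixation(1e-12, 1e4), 1e-4, tolerance = 1e-6)
    expect_equal(moranFixation(-1e-12, 1e4), 1e-4, tolerance = 1e-6)
    # monotone increasing in s
    s <- seq(-0.01, 0.01, length.out = 101)
    p <- vapply(s, moranFixation, numeric(1), Ne = 1000)
    expect_true(all(diff(p) > 0))
    # strong positive selection ~ 1 - exp(-s)
    expect_equal(moranFixation(10, 100), 1 - exp(-10), tolerance = 1e-6)
    # the printed deleterious case: ~10-fold reduction below neutral
    expect_equal((1 / 1e4) / moranFixation(-3.5e-4, 1e4), 9.17, tolerance = 0.01)
})

test_that("block counting is circular", {
    expect_equal(countBlocks(c(1, 1, 0, 1, 0, 0)), 2L)
    expect_equal(countBlocks(c(1, 0, 0, 1)), 1L)   # wraps
    expect_equal(countBlocks(rep(1, 5)), 1L)
    expect_equal(countBlocks(rep(0, 5)), 0L)
})

test_that("evolution conserves N and M and is seed-reproducible", {
    g <- disruptionGenome(60, 20, "random")
    t1 <- evolveDisruption(g, k = 2, r = 5, Ne = 100, steps = 2e4,
                           record_every = 5e3, seed = 7)
    t2 <- evolveDisruption(g, k = 2, r = 5, Ne = 100, steps = 2e4,
                           record_every = 5e3, seed = 7)
    expect_identical(t1$snapshots, t2$snapshots)
    expect_identical(t1$block_count, t2$block_count)
    expect_true(all(rowSums(t1$snapshots) == 20))
    expect_true(all(ncol(t1$snapshots) == 60))
    # block counts recomputed from snapshots agree
    expect_equal(t1$block_count,
                 apply(t1$snapshots, 1, countBlocks))
})

test_that("near-neutral dynamics accept at about the neutral rate", {
    g <- disruptionGenome(100, 30, "random")
    tr <- evolveDisruption(g, k = 2, r = 1e-9, Ne = 100, steps = 2e5,
                           record_every = 5e4, seed = 3)
    rate <- tr$accepted / 2e5
    expect_lt(abs(rate - 1 / 100), 0.002)
    # equilibrium block count stays near the random expectation, far above 1
    expect_gt(tail(tr$block_count, 1), 10)
})

test_that("strong selection makes block counts almost monotonically decrease", {
    tr <- evolveDisruption(disruptionGenome(100, 30, "random"),
                           k = 2, r = 10, Ne = 1e4, steps = 4e6,
                           record_every = 1e5, seed = 19)
    d <- diff(tr$block_count)
    expect_gte(mean(d <= 0), 0.9)
    expect_lt(tail(tr$block_count, 1), tr$block_count[1])
})
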