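# Skew profile, smoothing, extrema segmentation and greedy BIC merging.

test_that("the skew profile follows the duplicated-circle recursion", {
    # [1,1,0,0]: duplicated order 3,4,1,2,3,4,1,2 -> a = 0,0,1,1,0,0,1,1
    p <- skewProfile(taggedChromosome(c(1, 1, 0, 0)))
    expect_equal(p$raw, c(-.5, -1, -.5, 0, -.5, -1, -.5, 0))

    # telescoping: s_N = s_2N = 0 for any input
    set.seed(5)
    for (i in 1:5) {
        a <- rbinom(50 + i, 1, 0.4)
        if (sum(a) == 0 || sum(a) == length(a)) next
        p <- skewProfile(taggedChromosome(a))
        N <- length(a)
        expect_equal(p$raw[N], 0)
        expect_equal(p$raw[2 * N], 0)
    }

    # alternating tags keep the profile within +/- 0.5
    p <- skewProfile(taggedChromosome(rep(c(0, 1), 30)))
    expect_true(all(abs(p$raw) <= 0.5 + 1e-12))

    expect_error(skewProfile(taggedChromosome(rep(1, 10))), "constant-attribute")
    expect_error(skewProfile(taggedChromosome(rep(0, 10))), "constant-attribute")
})

test_that("Gaussian smoothing preserves constants and rejects short inputs", {
    chrom <- taggedChromosome(rep(c(1, 0), 300))
    p <- skewProfile(chrom)
    sm <- smoothSkewProfile(p, bandwidth = 20)
    expect_equal(length(sm$smoothed), length(p$raw))
    # smoothing a (near-)constant stretch reproduces it: feed a constant raw
    pc <- p
    pc$raw <- rep(1.5, length(p$raw))
    smc <- smoothSkewProfile(pc, bandwidth = 20)
    expect_equal(smc$smoothed, pc$raw, tolerance = 1e-12)
    # duplicated profile shorter than the kernel support
    expect_error(smoothSkewProfile(skewProfile(taggedChromosome(rep(c(1, 0), 10))),
                                   bandwidth = 40),
                 "chromosome-too-short")
})

test_that("initial segmentation places boundaries at smoothed-profile extrema", {
    # clean two-block chromosome: one maximum, one minimum -> 2 segments
    chrom <- taggedChromosome(c(rep(1, 200), rep(0, 200)))
    p <- smoothSkewProfile(skewProfile(chrom), 20)
    seg <- initialSegmentation(p, chrom)
    expect_equal(nSegments(seg), 2L)
    expect_equal(sum(seg@n), 400L)
    expect_equal(sum(seg@m), 200L)
    # boundaries near the block edges (0 and 200)
    expect_true(all(vapply(seg@start, function(s)
        min(circDist(s, c(0, 200), 400)) <= 40, logical(1))))
})

test_that("greedy merging matches the exhaustive adjacent-merge oracle", {
    set.seed(13)
    for (rep in 1:20) {
        N <- sample(20:60, 1)
        a <- rbinom(N, 1, runif(1, 0.2, 0.6))
        if (sum(a) == 0 || sum(a) == N) next
        k <- sample(2:6, 1)
        cuts <- sort(sample(0:(N - 1), k))
        seg <- segFromCuts(a, cuts)
        got <- mergeSegments(seg)
        want <- bruteGreedyMerge(seg)
        expect_equal(got@start, want$start)
        expect_equal(got@n, want$n)
        expect_equal(got@m, want$m)
        expect_lte(segBIC(got), segBIC(seg))
    }
})

test_that("merging preserves totals and converges on canonical cases", {
    # uniform density over-segmented into 10 equal parts -> single segment
    tags <- rep(c(1, 1, 1, rep(0, 7)), 10)
    seg <- segFromCuts(tags, seq(0, 90, 10))
    m <- mergeSegments(seg)
    expect_equal(nSegments(m), 1L)

    # two-block 0.9/0.1 chromosome over-segmented -> k = 2 at the block edges
    set.seed(31)
    tb <- c(rbinom(400, 1, 0.9), rbinom(400, 1, 0.1))
    m2 <- mergeSegments(segFromCuts(tb, seq(0, 700, 100)))
    expect_equal(nSegments(m2), 2L)
    expect_equal(m2@start, c(0L, 400L))
    expect_equal(sum(m2@n), 800L)
    expect_equal(sum(m2@m), sum(tb))

    # k = 1 input is a fixed point
    one <- segFromCuts(tb, 0)
    expect_equal(mergeSegments(one)@n, one@n)
})

test_that("end-to-end segmentation recovers blocks and is rotation-covariant", {
    set.seed(9)
    out <- synthBlocky(blockySpec(2500), seed = 21)
    tg <- tags(out$chromosome)
    seg <- segmentChromosome(out$chromosome)
    expect_lte(abs(nSegments(seg) - nrow(out$blocks)), 1L)

    r <- 137L
    rot <- taggedChromosome(c(tg[(r + 1):length(tg)], tg[1:r]))
    segR <- segmentChromosome(rot)
    expect_equal(sort((segR@start + r) %% length(tg)), sort(seg@start))

    expect_error(segmentChromosome(taggedChromosome(rep(1, 500))),
                 "constant-attribute")
})

test_that("random permutations yield a single uniform segment", {
    set.seed(17)
    ks <- replicate(8, {
        chrom <- taggedChromosome(sample(c(rep(1, 700), rep(0, 1400))))
        nSegments(segmentChromosome(chrom))
    })
    expect_gte(mean(ks == 1L), 0.95)
})

test_that("the chi-square uniformity test follows the printed formula", {
    tags <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
    seg <- segFromCuts(tags, c(0, 50))
    ut <- chisqUniformity(seg)
    expect_equal(ut$statistic, 18)
    expect_equal(ut$df, 1L)
    expect_equal(ut$p_value, pchisq(18, 1, lower.tail = FALSE))

    # perfectly uniform -> statistic 0, p = 1
    u <- segFromCuts(rep(c(1, 0), 50), c(0, 50))
    expect_equal(chisqUniformity(u)$statistic, 0)
    expect_equal(chisqUniformity(u)$p_value, 1)

    # invariant under rotation of the segment list
    set.seed(2)
    a <- rbinom(120, 1, 0.3); a[1] <- 1
    s1 <- segFromCuts(a, c(0, 40, 80))
    s2 <- segFromCuts(a, c(40, 80, 0))
    expect_equal(chisqUniformity(s1)$statistic, chisqUniformity(s2)$statistic)

    expect_error(chisqUniformity(segFromCuts(a, 0)), "untestable")
})

test_that("enrichment summaries report densities, factor and capture", {
    tags <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
    es <- enrichmentSummary(segFromCuts(tags, c(0, 50)))
    expect_equal(es$mean_density_enriched, 0.8)
    expect_equal(es$mean_density_depleted, 0.2)
    expect_equal(es$enrichment_factor, 4)
    expect_equal(es$tagged_capture, 0.8)

    # equal densities: tie rule puts everything in the depleted class
    eq <- segFromCuts(rep(c(1, 0), 50), c(0, 50))
    expect_equal(enrichmentSummary(eq)$n_enriched, 0L)
    expect_true(is.na(enrichmentSummary(eq)$enrichment_factor))
})

test_that("blocky synthetic chromosomes show the generated enrichment factor", {
    set.seed(4)
    out <- synthBlocky(blockySpec(4000, enriched_density = c(0.6, 0.6),
                                  enrichment_factor = c(3, 3),
                                  preset = "none"), seed = 8)
    seg <- segmentChromosome(out$chromosome)
    es <- enrichmentSummary(seg)
    expect_gt(es$enrichment_factor, 2)
    expect_lt(es$enrichment_factor, 4.5)
})
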