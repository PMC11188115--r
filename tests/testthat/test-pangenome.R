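# Gene-age classification from pangenome commonality.

pmFromList <- function(lst, clusters) {
    m <- t(vapply(lst, function(cl) clusters %in% cl, logical(length(clusters))))
    dimnames(m) <- list(names(lst), clusters)
    presenceMatrix(m)
}

test_that("assembly curation deduplicates and applies the commonality-peak filter", {
    # four identical assemblies collapse to one; the peak filter is then identity
    pm <- pmFromList(setNames(rep(list(c("A", "B")), 4), paste0("asm", 1:4)),
                     c("A", "B"))
    cur <- curateAssemblies(pm)
    expect_equal(length(assemblyIds(cur)), 1L)

    # 5 distinct assemblies: A in all 5, B in 4, C in 1 -> n_5 = n_4 = 1,
    # tie broken to i* = 5, retained = assemblies containing A = all 5
    lst <- list(asm1 = c("A", "B", "C"), asm2 = c("A", "B", "u2"),
                asm3 = c("A", "B", "u3"), asm4 = c("A", "B", "u4"),
                asm5 = c("A", "u5"))
    cur <- curateAssemblies(pmFromList(lst, unique(unlist(lst))))
    expect_setequal(assemblyIds(cur), paste0("asm", 1:5))

    # 6 assemblies; A,B,C shared by the same 5, assembly 6 lacks all three
    lst <- c(setNames(rep(list(c("A", "B", "C", "X")), 5), paste0("asm", 1:5)),
             list(asm6 = "X"))
    lst <- lapply(seq_along(lst), function(i) unique(c(lst[[i]], paste0("u", i))))
    names(lst) <- c(paste0("asm", 1:5), "asm6")
    cur <- curateAssemblies(pmFromList(lst, unique(unlist(lst))))
    expect_setequal(assemblyIds(cur), paste0("asm", 1:5))

    # no commonality peak in the upper half -> error
    lst <- list(a1 = "A", a2 = "B", a3 = "C", a4 = "D")
    expect_error(curateAssemblies(pmFromList(lst, c("A", "B", "C", "D"))),
                 "no-core-peak")
})

test_that("curation is idempotent", {
    for (seed in 1:5) {
        pm <- synthPangenome(20, 200, preset = "ushape", seed = seed)
        c1 <- curateAssemblies(pm)
        c2 <- curateAssemblies(c1)
        expect_identical(presence(c1), presence(c2))
    }
})

test_that("commonality counts and fractions follow the definitions", {
    pm <- pmFromList(list(a1 = c("A", "B", "C")), c("A", "B", "C"))
    expect_true(all(clusterCommonality(pm)$fraction == 1))

    lst <- c(setNames(rep(list(c("X", "Y")), 3), paste0("a", 1:3)),
             setNames(rep(list("Y"), 7), paste0("b", 1:7)))
    ct <- clusterCommonality(pmFromList(lst, c("X", "Y")))
    expect_equal(ct$fraction[ct$cluster_id == "X"], 0.3)
    # total counts equal total presence entries
    pm2 <- synthPangenome(15, 100, preset = "ushape", seed = 3)
    ct2 <- clusterCommonality(pm2)
    expect_equal(sum(ct2$count), sum(presence(pm2)))
})

test_that("tertile thresholds are inclusive order statistics", {
    # all clusters ubiquitous -> thresholds collapse at 1
    pm <- pmFromList(setNames(rep(list(c("A", "B", "C")), 3), paste0("a", 1:3)),
                     c("A", "B", "C"))
    th <- genusThresholds(pm)
    expect_equal(th$qLow, 1)
    expect_equal(th$qHigh, 1)

    # genome g1 carries clusters with commonalities exactly {0.1, 0.5, 0.9}:
    # bottom third ends at 0.1, top third starts at 0.9
    p <- matrix(FALSE, 10, 6,
                dimnames = list(paste0("g", sprintf("%02d", 1:10)),
                                c("A", "B", "C", "X", "Y", "Z")))
    p[1, "A"] <- TRUE             # A in g1 only (0.1)
    p[1:5, "B"] <- TRUE           # B in 5/10
    p[1:9, "C"] <- TRUE           # C in 9/10
    p[2:10, c("X", "Y", "Z")] <- TRUE  # padding so every genome has >= 3
    pm <- presenceMatrix(p)
    ct <- clusterCommonality(pm)
    expect_equal(sort(unique(ct$fraction)), c(0.1, 0.5, 0.9))
    th <- genusThresholds(pm, ct)
    g1 <- th$perGenome[th$perGenome$genome == "g01", ]
    expect_equal(g1$qLow, 0.1)
    expect_equal(g1$qHigh, 0.9)
})

test_that("thresholds require at least three commonality values per genome", {
    p <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("A", "B", "C")))
    expect_error(genusThresholds(presenceMatrix(p)), "degenerate-quantile")
})

test_that("classification respects inclusive/exclusive threshold boundaries", {
    ct <- data.frame(cluster_id = c("lo", "mid", "hi"),
                     count = c(1L, 5L, 9L),
                     fraction = c(0.1, 0.5, 0.9))
    th <- structure(list(qLow = 0.5, qHigh = 0.9, perGenome = NULL),
                    class = "genus_thresholds")
    lab <- classifyGeneAges(c(g1 = "lo", g2 = "mid", g3 = "hi"), ct, th)
    # exactly at qHigh -> ancient (inclusive); exactly at qLow -> intermediate
    expect_equal(as.character(lab$label), c("young", "intermediate", "ancient"))

    # qLow below every fraction -> nothing is young
    th0 <- structure(list(qLow = 0, qHigh = 0.9), class = "genus_thresholds")
    lab0 <- classifyGeneAges(c(g1 = "lo", g2 = "mid", g3 = "hi"), ct, th0)
    expect_false(any(lab0$label == "young"))

    expect_error(classifyGeneAges(c(g1 = "absent"), ct, th), "unmapped-gene")
})

test_that("raising qHigh never grows the ancient set (monotonicity)", {
    set.seed(7)
    ct <- data.frame(cluster_id = paste0("c", 1:200), count = 1L,
                     fraction = runif(200))
    genes <- setNames(paste0("c", 1:200), paste0("g", 1:200))
    sizes <- vapply(seq(0.2, 0.9, by = 0.1), function(qh) {
        th <- structure(list(qLow = 0.1, qHigh = qh), class = "genus_thresholds")
        sum(classifyGeneAges(genes, ct, th)$label == "ancient")
    }, numeric(1))
    expect_true(all(diff(sizes) <= 0))
})

test_that("the representative genome minimizes threshold distance, ties lexicographic", {
    mk <- function(df) structure(list(qLow = 0.3, qHigh = 0.7, perGenome = df),
                                 class = "genus_thresholds")
    one <- mk(data.frame(genome = "only", qLow = 0.5, qHigh = 0.5))
    expect_equal(representativeGenome(one), "only")

    three <- mk(data.frame(genome = c("gA", "gB", "gC"),
                           qLow = c(0.3, 0.2, 0.35),
                           qHigh = c(0.7, 0.9, 0.65)))
    expect_equal(representativeGenome(three), "gA")

    tie <- mk(data.frame(genome = c("zz", "aa"),
                         qLow = c(0.3, 0.3), qHigh = c(0.7, 0.7)))
    expect_equal(representativeGenome(tie), "aa")
})

test_that("tertile-balanced synthetic genera classify to about a third per class", {
    pm <- curateAssemblies(synthPangenome(24, 650, seed = 11))
    ct <- clusterCommonality(pm)
    th <- genusThresholds(pm, ct)
    p <- presence(pm)
    fr <- vapply(rownames(p), function(g) {
        cl <- colnames(p)[p[g, ]]
        lab <- classifyGeneAges(setNames(cl, cl), ct, th)$label
        c(mean(lab == "ancient"), mean(lab == "young"))
    }, numeric(2))
    expect_gt(nrow(th$perGenome), 19)
    expect_lt(abs(mean(fr[1, ]) - 1 / 3), 0.05)
    expect_lt(abs(mean(fr[2, ]) - 1 / 3), 0.05)
})
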