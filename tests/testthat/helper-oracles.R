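# Independent oracles used across test files. These deliberately re-derive
# quantities by the most literal route available (enumeration, naive loops)
# and must stay independent of the package implementations they check.

# lethal fraction by explicit enumeration of all N circular windows
bruteLethalFraction <- function(e, k) {
    n <- length(e)
    hits <- 0L
    for (st in seq_len(n)) {
        idx <- ((st - 1L + seq_len(k) - 1L) %% n) + 1L
        if (any(e[idx] == 1L)) hits <- hits + 1L
    }
    hits / n
}

# multiscale complexity by naive loops
naiveMsc <- function(x) {
    n <- length(x)
    roll <- function(lam) {
        vapply(seq_len(n), function(k)
            mean(x[((k - 1L + seq_len(lam) - 1L) %% n) + 1L]), numeric(1))
    }
    vapply(seq_len(n %/% 2L), function(lam)
        mean(abs(roll(lam) - roll(2L * lam))), numeric(1))
}

# circular autocorrelation at one lag via cor() on the shifted vector
naiveAutocorr <- function(x, t) {
    n <- length(x)
    y <- x[((seq_len(n) - 1L + t) %% n) + 1L]
    suppressWarnings(stats::cor(x, y))
}

# binomial segment log-likelihood with the 0*log(0) convention
segLL <- function(n, m) {
    p <- m / n
    sum(ifelse(m > 0, m * log(p), 0) + ifelse(n - m > 0, (n - m) * log(1 - p), 0))
}

# build a Segmentation object from tags and sorted 0-based cut positions
segFromCuts <- function(tags, cuts) {
    N <- length(tags)
    cuts <- sort(unique(as.integer(cuts %% N)))
    k <- length(cuts)
    n <- if (k == 1L) N else as.integer(diff(c(cuts, cuts[1L] + N)))
    m <- vapply(seq_len(k), function(i)
        sum(tags[((cuts[i] + seq_len(n[i]) - 1L) %% N) + 1L]), numeric(1))
    L <- segLL(n, as.integer(m))
    new("Segmentation", start = cuts, n = n, m = as.integer(m),
        N = as.integer(N), M = as.integer(sum(tags)),
        logLik = L, bic = (2 * k - 1) * log(N) - 2 * L)
}

# exhaustive greedy BIC merging: at every iteration score all k adjacent
# merges directly from the definition and apply the best improving one
bruteGreedyMerge <- function(seg) {
    st <- seg@start; n <- seg@n; m <- seg@m; N <- seg@N
    repeat {
        k <- length(n)
        if (k == 1L) break
        L <- segLL(n, m)
        B <- (2 * k - 1) * log(N) - 2 * L
        Bi <- vapply(seq_len(k), function(i) {
            j <- if (i == k) 1L else i + 1L
            n2 <- n; m2 <- m
            n2[i] <- n[i] + n[j]; m2[i] <- m[i] + m[j]
            n2 <- n2[-j]; m2 <- m2[-j]
            (2 * k - 3) * log(N) - 2 * segLL(n2, m2)
        }, numeric(1))
        i <- which.min(Bi)
        if (Bi[i] >= B) break
        j <- if (i == k) 1L else i + 1L
        n[i] <- n[i] + n[j]; m[i] <- m[i] + m[j]
        st <- st[-j]; n <- n[-j]; m <- m[-j]
    }
    list(start = st, n = n, m = m)
}

# circular distance between two 0-based positions on an N-circle
circDist <- function(a, b, N) {
    d <- abs(a - b) %% N
    pmin(d, N - d)
}
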