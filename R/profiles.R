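# Multiscale structural complexity and circular autocorrelation of binary
# chromosomes. Both constructions are invariant under rotation of the gene
# string and under complementing the tags (0 <-> 1).

.asBinary <- function(x) {
    if (is(x, "TaggedChromosome")) x@tags else as.numeric(x)
}

#' Circular rolling mean
#'
#' `y_k` is the mean of the `lambda` consecutive elements starting at `k`,
#' wrapping around the circle.
#'
#' @param x a numeric/binary vector or a [TaggedChromosome-class].
#' @param lambda window length in genes, `1 <= lambda <= length(x)`.
#'
#' @return numeric vector of the same length as `x`.
#' @export
rollingMeanCircular <- function(x, lambda) {
    x <- .asBinary(x)
    n <- length(x)
    lambda <- as.integer(lambda)
    if (lambda < 1L || lambda > n)
        stop("window length must be in [1, ", n, "]")
    cs <- cumsum(c(0, x, x))
    (cs[seq_len(n) + lambda] - cs[seq_len(n)]) / lambda
}

#' Multiscale structural complexity profile
#'
#' For each scale `lambda` in `1..floor(n/2)`, the profile value is the mean
#' absolute difference between the chromosome smoothed by circular rolling
#' means of window `lambda` and window `2*lambda`. A coin-flip sequence is
#' smoothed to near-uniformity already at small windows, so its profile peaks
#' at small `lambda`; a sequence of large blocks has its maximum near the
#' characteristic block size.
#'
#' @param x a binary vector or [TaggedChromosome-class] with `n >= 4` genes.
#'
#' @return an object of class `msc_profile`: list with `scale` (1..floor(n/2)),
#'   `value`, and `n`.
#' @examples
#' p <- mscProfile(c(rep(1, 50), rep(0, 50)))
#' p$scale[which.max(p$value)]  # near the block size
#' @export
mscProfile <- function(x) {
    x <- .asBinary(x)
    n <- length(x)
    if (n < 4L) stop("sequence too short for a complexity profile (n >= 4)")
    v <- msc_profile_cpp(as.numeric(x))
    structure(list(scale = seq_len(n %/% 2L), value = v, n = n),
              class = "msc_profile")
}

#' @export
print.msc_profile <- function(x, ...) {
    cat("Multiscale complexity profile: n =", x$n,
        " peak at scale", x$scale[which.max(x$value)], "\n")
    invisible(x)
}

#' Distance between complexity profiles
#'
#' The mean absolute difference between two profiles computed on chromosomes
#' of equal length; symmetric and zero only for identical profiles. Used as
#' the goodness-of-fit objective when fitting the mobility model.
#'
#' @param p,q `msc_profile` objects with equal `n`.
#'
#' @return a nonnegative scalar.
#' @export
profileDistance <- function(p, q) {
    stopifnot(inherits(p, "msc_profile"), inherits(q, "msc_profile"))
    if (p$n != q$n)
        stop("profiles were computed on chromosomes of different lengths")
    mean(abs(p$value - q$value))
}

#' Circular autocorrelation of a binary chromosome
#'
#' `R_t` is the Pearson correlation between the sequence and its circular
#' shift by lag `t`, for all `t` in `0..n-1`. The zero-correlation lag is the
#' smallest `t >= 1` with `R_t` non-positive; at that distance tags become
#' approximately independent, so it serves as a rough characteristic cluster
#' size.
#'
#' @param x a non-constant binary vector or [TaggedChromosome-class].
#'
#' @return an object of class `autocorrelation_series`: list with `lag`
#'   (0..n-1), `r`, `zero_lag`, `n`.
#' @export
circularAutocorrelation <- function(x) {
    x <- .asBinary(x)
    n <- length(x)
    mu <- mean(x)
    v <- mean(x^2) - mu^2
    if (v == 0)
        stop("zero-variance: constant sequence has no autocorrelation")
    fx <- stats::fft(x)
    # circular cross-products sum(x_i * x_{i+t}); exact integers for 0/1 input
    cp <- round(Re(stats::fft(fx * Conj(fx), inverse = TRUE)) / n)
    r <- (cp / n - mu^2) / v
    zl <- which(r[-1L] <= 0)
    structure(list(lag = 0:(n - 1L), r = r,
                   zero_lag = if (length(zl)) zl[1L] else NA_integer_,
                   n = n),
              class = "autocorrelation_series")
}

#' @export
print.autocorrelation_series <- function(x, ...) {
    cat("Circular autocorrelation: n =", x$n,
        " zero-correlation lag =", x$zero_lag, "\n")
    invisible(x)
}

#' Zero-correlation lag
#'
#' Convenience accessor: the smallest lag `t >= 1` at which the circular
#' autocorrelation becomes non-positive.
#'
#' @param x a binary vector, [TaggedChromosome-class], or an
#'   `autocorrelation_series`.
#'
#' @return integer lag.
#' @export
zeroCorrelationLag <- function(x) {
    if (inherits(x, "autocorrelation_series")) return(x$zero_lag)
    circularAutocorrelation(x)$zero_lag
}
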