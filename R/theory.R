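# Closed-form probability theory for the sequential basis-building
# procedure, plus an exhaustive enumerator that verifies the bounds on
# small instances.

#' Lower bound on the fraction of multiplicity vectors outside a plane
#'
#' If every genome's copy number ranges over a set of `s` values, the
#' fraction of all multiplicity vectors that lie outside any linear
#' subspace of codimension `p` is at least \eqn{1 - s^{-p}}. With `p = 1`
#' and `s = 2` this is the worst case 0.5: at least half of all samples
#' fall outside any hyperplane, so each new sample has at least an even
#' chance of enlarging the basis.
#'
#' @param s size of each copy-number value set (>= 2).
#' @param p codimension of the plane (>= 1).
#' @return the bound \eqn{1 - s^{-p}}.
#' @export
independenceProbabilityBound <- function(s, p) {
    if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 2 ||
        s != round(s))
        stop("s must be a single integer >= 2", call. = FALSE)
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 1 ||
        p != round(p))
        stop("p must be a single integer >= 1", call. = FALSE)
    1 - s^(-p)
}

#' Tail-to-mode probability ratio lambda of a multiplicity measure
#'
#' For per-genome copy-number probabilities sorted non-increasingly within
#' each genome, lambda is the minimum over genomes of the total probability
#' of the non-modal values divided by the modal probability. It governs the
#' measure-weighted hyperplane bound [measureBound()] and the expected
#' sampling length \eqn{(1+\lambda) n / \lambda}.
#'
#' @param probs a numeric matrix (one genome per row) or a list of numeric
#'   vectors; each row must be non-increasing and sum to 1.
#' @return lambda.
#' @examples
#' lambdaFromProbs(rbind(c(0.5, 0.5), c(0.9, 0.1)))  # 1/9
#' @export
lambdaFromProbs <- function(probs) {
    if (is.matrix(probs)) probs <- asplit(probs, 1L)
    if (!is.list(probs) || length(probs) == 0L)
        stop("probs must be a matrix or a nonempty list of rows",
             call. = FALSE)
    ratios <- vapply(probs, function(pr) {
        pr <- as.numeric(pr)
        if (length(pr) < 2L || anyNA(pr) || any(pr < 0))
            stop("each probability row needs >= 2 nonnegative entries",
                 call. = FALSE)
        if (abs(sum(pr) - 1) > 1e-8)
            stop("each probability row must sum to 1", call. = FALSE)
        if (any(diff(pr) > 1e-12))
            stop("each probability row must be sorted non-increasingly",
                 call. = FALSE)
        sum(pr[-1L]) / pr[1L]
    }, numeric(1))
    min(ratios)
}

#' Measure-weighted hyperplane bound
#'
#' The probability mass of multiplicity vectors outside any hyperplane is
#' at least \eqn{1 - 1/(1+\lambda) = \lambda/(1+\lambda)}. With the uniform
#' measure, \eqn{\lambda = s - 1} and the bound coincides with
#' [independenceProbabilityBound()] at codimension 1.
#'
#' @param lambda positive tail-to-mode ratio, see [lambdaFromProbs()].
#' @return the bound \eqn{\lambda/(1+\lambda)}.
#' @export
measureBound <- function(lambda) {
    if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
        lambda <= 0)
        stop("lambda must be a single positive number", call. = FALSE)
    1 - 1 / (1 + lambda)
}

#' Lambda for normally distributed multiplicities
#'
#' For integer copy numbers with a Normal(m, sigma) profile, the ratio of
#' adjacent-value probabilities gives \eqn{\lambda =
#' \exp(-1/(2\sigma_0^2))} with \eqn{\sigma_0} the smallest copy-number
#' standard deviation across genomes; lambda approaches 1 as the scatter
#' grows (0.995 at \eqn{\sigma_0 = 10}).
#'
#' @param sigma0 minimal copy-number standard deviation, positive.
#' @return lambda.
#' @export
lambdaNormal <- function(sigma0) {
    if (!is.numeric(sigma0) || length(sigma0) != 1L || is.na(sigma0) ||
        sigma0 <= 0)
        stop("sigma0 must be a single positive number", call. = FALSE)
    exp(-1 / (2 * sigma0^2))
}

#' Expected number of samples to collect the full basis
#'
#' With per-draw probability `p` of a new sample being linearly
#' independent of the basis found so far, the mean number of samples
#' needed to collect all `n` basis vectors is `n / p` (negative-binomial
#' waiting time). At the worst-case uniform bound `p = 0.5` this is `2n`.
#'
#' @param n number of basis vectors (genomes), >= 1.
#' @param p per-draw success probability in (0, 1].
#' @return mean sampling length `n / p`.
#' @export
expectedSampleCount <- function(n, p) {
    if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
        stop("n must be a single number >= 1", call. = FALSE)
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
        stop("p must be in (0, 1]", call. = FALSE)
    n / p
}

#' Confidence of the termination rule
#'
#' If `m` consecutive samples have all been linearly dependent on the
#' current basis, and each sample would have been independent with
#' probability at least `pIndependent` were the basis incomplete, then the
#' probability that the basis is already complete is at least
#' \eqn{1 - (1 - p)^m}. At the uniform worst case `p = 0.5` this is
#' \eqn{1 - 2^{-m}} (about 94% at m = 4).
#'
#' @param mConsecutive number of consecutive dependent samples, >= 1.
#' @param pIndependent per-draw independence probability in (0, 1].
#' @return probability that the full basis has been found.
#' @export
terminationConfidence <- function(mConsecutive, pIndependent = 0.5) {
    if (!is.numeric(mConsecutive) || length(mConsecutive) != 1L ||
        is.na(mConsecutive) || mConsecutive < 1 ||
        mConsecutive != round(mConsecutive))
        stop("mConsecutive must be a single integer >= 1", call. = FALSE)
    if (!is.numeric(pIndependent) || length(pIndependent) != 1L ||
        is.na(pIndependent) || pIndependent <= 0 || pIndependent > 1)
        stop("pIndependent must be in (0, 1]", call. = FALSE)
    1 - (1 - pIndependent)^mConsecutive
}

#' Expected absolute deviation of an integer-rounded normal copy number
#'
#' For X ~ Normal(m, sigma), computes E|round(X) - m| as the series
#' \deqn{\sum_{d \ge 1} 2 d \,[\Phi((d+0.5)/\sigma) - \Phi((d-0.5)/\sigma)],}
#' truncated once terms fall below 1e-12. This is the expected scatter of
#' integer genome copy numbers around their mean; at sigma = 1, 2, 3 it
#' evaluates to 0.764, 1.579, 2.383.
#'
#' @param sigma copy-number standard deviation, >= 0 (0 gives 0).
#' @return expected absolute deviation in copies.
#' @export
roundedNormalMeanAbsDeviation <- function(sigma) {
    if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) ||
        sigma < 0)
        stop("sigma must be a single nonnegative number", call. = FALSE)
    if (sigma == 0) return(0)
    total <- 0
    d <- 1
    repeat {
        term <- 2 * d * (pnorm((d + 0.5) / sigma) - pnorm((d - 0.5) / sigma))
        total <- total + term
        if (term < 1e-12 && d > sigma) break
        d <- d + 1
    }
    total
}

#' Monte-Carlo check of the expected sampling length
#'
#' Simulates drawing samples until `n` successes (new basis vectors) with
#' per-draw success probability `p`, and returns the empirical mean of the
#' total number of draws — a stochastic counterpart of
#' [expectedSampleCount()].
#'
#' @param n number of successes required.
#' @param p per-draw success probability in (0, 1].
#' @param trials number of Monte-Carlo replicates.
#' @param seed optional integer seed.
#' @return list with `mean` (empirical mean draws), `se` (its standard
#'   error) and `expected` (`n / p`).
#' @export
negativeBinomialMeanCheck <- function(n, p, trials = 1e5, seed = NULL) {
    stopifnot(trials >= 1)
    if (!is.null(seed)) set.seed(seed)
    if (p >= 1) {
        draws <- rep(n, trials)
    } else {
        draws <- n + rnbinom(trials, size = n, prob = p)
    }
    list(mean = mean(draws), se = sd(draws) / sqrt(trials),
         expected = expectedSampleCount(n, p))
}

#' Exhaustively enumerate the fraction of multiplicity vectors outside a span
#'
#' Enumerates the full direct-product set
#' \eqn{M = a_1 \otimes \ldots \otimes a_n} of multiplicity vectors and
#' tests each for membership in the linear span of the given vectors by
#' exact integer rank comparison (no floating-point tolerance). Small
#' instances only; this is the ground-truth oracle the codimension bounds
#' are checked against.
#'
#' @param valueSets list of n integer value sets (or one vector recycled to
#'   length `n`).
#' @param span numeric matrix with the spanning vectors in rows (integer
#'   entries, linearly independent), n columns.
#' @param n required when `valueSets` is a single vector.
#' @return the fraction of vectors of M outside the span, along with the
#'   attribute `counts` = c(inside, outside, total).
#' @examples
#' sp <- diag(5)[1:4, ]               # e1..e4 in 5-space
#' enumerateFractionOutside(c(0, 1), sp, n = 5)   # 0.5
#' @export
enumerateFractionOutside <- function(valueSets, span, n = NULL) {
    span <- as.matrix(span)
    if (!is.list(valueSets)) {
        if (is.null(n)) n <- ncol(span)
        valueSets <- rep(list(as.numeric(valueSets)), n)
    }
    n <- length(valueSets)
    if (n > 16L)
        stop("enumeration limited to n <= 16", call. = FALSE)
    sizes <- vapply(valueSets, length, integer(1))
    if (prod(sizes) > 1e6)
        stop("instance too large: |M| = ", prod(sizes), " > 1e6",
             call. = FALSE)
    if (ncol(span) != n)
        stop("span must have n = ", n, " columns", call. = FALSE)
    if (anyNA(span) || any(span != round(span)))
        stop("span must have integer entries", call. = FALSE)
    r0 <- exactIntegerRank(span)
    if (r0 < nrow(span))
        stop("spanning vectors must be linearly independent", call. = FALSE)
    grid <- as.matrix(expand.grid(valueSets, KEEP.OUT.ATTRS = FALSE))
    outside <- vapply(seq_len(nrow(grid)), function(i) {
        exactIntegerRank(rbind(span, grid[i, ])) > r0
    }, logical(1))
    frac <- mean(outside)
    attr(frac, "counts") <- c(inside = sum(!outside),
                              outside = sum(outside),
                              total = length(outside))
    frac
}
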