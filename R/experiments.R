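# Scripted reproductions of the package's simulation experiments at
# configurable (desk) scale: dependence probabilities of random
# multiplicity matrices, reliability of genome-count recovery as samples
# accumulate, and the virtual-sample design comparison.

#' Probability that n random samples of an n-genome metagenome are dependent
#'
#' For each n, draws n random multiplicity vectors (entries uniform over
#' `valueSet`) and tests the n x n integer matrix for linear dependence by
#' exact rank over the rationals. When the genome spectra themselves are
#' linearly independent, dependence of the samples is equivalent to
#' dependence of their multiplicity matrix, so the test runs on the small
#' integer matrix instead of the \eqn{4^k}-dimensional spectra.
#'
#' @param nValues integer vector of metagenome sizes n to evaluate.
#' @param valueSet copy-number value set (default \{0, 1\}).
#' @param replicates Monte-Carlo replicates per n (a warning is issued
#'   below 100, where the estimate is noisy).
#' @param seed optional integer seed.
#' @return data.frame with columns `nGenomes`, `pDependent`, `replicates`.
#' @export
runDependenceCurve <- function(nValues, valueSet = c(0, 1),
                               replicates = 1000L, seed = NULL) {
    if (replicates < 100L)
        warning("fewer than 100 replicates gives a noisy estimate")
    if (!is.null(seed)) set.seed(seed)
    valueSet <- as.numeric(valueSet)
    p <- vapply(nValues, function(n) {
        dep <- 0L
        for (r in seq_len(replicates)) {
            m <- matrix(valueSet[sample.int(length(valueSet), n * n,
                                            replace = TRUE)], n, n)
            if (exactIntegerRank(m) < n) dep <- dep + 1L
        }
        dep / replicates
    }, numeric(1))
    data.frame(nGenomes = as.integer(nValues), pDependent = p,
               replicates = as.integer(replicates))
}

#' Exact dependence probability by exhaustive enumeration
#'
#' Enumerates every n x n matrix with entries in `valueSet` and returns
#' the exact fraction with rank below n — the ground truth the
#' Monte-Carlo curve is checked against on small instances.
#'
#' @param n matrix size (number of genomes = number of samples).
#' @param valueSet copy-number value set.
#' @return exact probability of linear dependence.
#' @examples
#' exactDependenceProbability(2, c(0, 1))  # 10/16
#' @export
exactDependenceProbability <- function(n, valueSet = c(0, 1)) {
    valueSet <- as.numeric(valueSet)
    s <- length(valueSet)
    total <- s^(n * n)
    if (total > 70000)
        stop("enumeration limited to |valueSet|^(n^2) <= 70000",
             call. = FALSE)
    dep <- 0L
    digits <- n * n
    for (code in 0:(total - 1L)) {
        idx <- integer(digits)
        c0 <- code
        for (d in seq_len(digits)) {
            idx[d] <- c0 %% s
            c0 <- c0 %/% s
        }
        m <- matrix(valueSet[idx + 1L], n, n)
        if (exactIntegerRank(m) < n) dep <- dep + 1L
    }
    dep / total
}

#' Fit the three-parameter logistic to a dependence curve
#'
#' Least-squares fit of \eqn{y = a / (1 + \exp(-k (x - x_c)))} via
#' Levenberg-Marquardt. Dependence curves over the metagenome size follow
#' this sigmoid closely.
#'
#' @param x,y numeric vectors (at least 4 points, y in `[0, 1]`); `x` may
#'   also be the data.frame returned by [runDependenceCurve()].
#' @return list with `a`, `k`, `xc`, `residualNorm`, `converged`,
#'   `degenerate` and the underlying `fit` object (NULL on failure).
#' @export
fitLogistic <- function(x, y = NULL) {
    if (is.data.frame(x)) {
        y <- x$pDependent
        x <- x$nGenomes
    }
    if (length(x) < 4L || length(x) != length(y))
        stop("need at least 4 (x, y) points", call. = FALSE)
    if (any(y < -1e-9) || any(y > 1 + 1e-9))
        stop("y values must lie in [0, 1]", call. = FALSE)
    if (sd(y) < 1e-12)
        return(list(a = NA_real_, k = NA_real_, xc = NA_real_,
                    residualNorm = 0, converged = FALSE, degenerate = TRUE,
                    fit = NULL))
    a0 <- max(y)
    xc0 <- x[which.min(abs(y - a0 / 2))]
    df <- data.frame(x = x, y = y)
    fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a / (1 + exp(-k * (x - xc))), data = df,
                          start = list(a = a0, k = 1, xc = xc0),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    if (is.null(fit))
        return(list(a = NA_real_, k = NA_real_, xc = NA_real_,
                    residualNorm = NA_real_, converged = FALSE,
                    degenerate = FALSE, fit = NULL))
    cf <- stats::coef(fit)
    list(a = unname(cf["a"]), k = unname(cf["k"]), xc = unname(cf["xc"]),
         residualNorm = sqrt(sum(stats::resid(fit)^2)), converged = TRUE,
         degenerate = FALSE, fit = fit)
}

#' Recovery reliability as samples accumulate
#'
#' For each sample count N, simulates `replicates` fresh metagenomes of
#' `nGenomes` synthetic genomes, estimates the genome count from the
#' first N samples, and records the fraction of runs whose estimate is
#' within +/-1 of the truth. Within one replicate the same metagenome and
#' sample sequence are reused across N, mirroring the sequential addition
#' of samples in a real experiment.
#'
#' @param nGenomes number of distinct genomes p.
#' @param nSamplesValues integer vector of sample counts N to evaluate.
#' @param replicates metagenomes simulated per N.
#' @param m,sigma copy-number mean and standard deviation (Normal model).
#' @param genomeLength synthetic genome length (default 50 kb).
#' @param coverage,nFragments,letterErrorRate fragment-model settings, see
#'   [makeFragmentSet()].
#' @param k word length.
#' @param seed optional integer seed.
#' @return data.frame with columns `nSamples`, `fractionCorrect`,
#'   `replicates`.
#' @export
runReliabilityCurve <- function(nGenomes = 10L,
                                nSamplesValues = c(10L, 15L, 20L),
                                replicates = 20L, m = 10, sigma = 3,
                                genomeLength = 50000L, coverage = 0.75,
                                nFragments = 20L, letterErrorRate = 0.001,
                                k = 6L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    nMax <- max(nSamplesValues)
    hits <- matrix(FALSE, nrow = replicates, ncol = length(nSamplesValues))
    for (r in seq_len(replicates)) {
        genomes <- generateSyntheticGenomes(nGenomes, genomeLength)
        ss <- generateSampleSet(genomes, normalModel(m, sigma),
                                nSamples = nMax, coverage = coverage,
                                nFragments = nFragments,
                                letterErrorRate = letterErrorRate, k = k)
        for (j in seq_along(nSamplesValues)) {
            est <- tryCatch(
                estimateGenomeCount(ss[seq_len(nSamplesValues[j])]),
                error = function(e) NULL)
            hits[r, j] <- !is.null(est) &&
                abs(est@genomeCount - nGenomes) <= 1L
        }
    }
    data.frame(nSamples = as.integer(nSamplesValues),
               fractionCorrect = colMeans(hits),
               replicates = as.integer(replicates))
}

#' Compare virtual-sample designs
#'
#' The library-augmentation protocol: a metagenome of `nMetagenome`
#' genomes, of which `nShared` also sit in a library selection that
#' additionally holds `nLibraryOnly` genomes absent from the metagenome.
#' Virtual samples built from the selection are appended to the real
#' samples and the unknown-genome count is compared with the truth
#' (`nMetagenome - nShared`), counting a run correct when within +/-1.
#'
#' @param designs integer vector of virtual designs to test (1-4).
#' @param sigmas copy-number standard deviations to test.
#' @param nSamplesValues real-sample counts N to test.
#' @param replicates simulations per table cell.
#' @param nMetagenome,nShared,nLibraryOnly protocol sizes (defaults 15,
#'   10, 10: expected answer 5 unknown genomes).
#' @param m mean copy number.
#' @param genomeLength,coverage,nFragments,letterErrorRate,k as in
#'   [runReliabilityCurve()].
#' @param seed optional integer seed.
#' @return data.frame with columns `design`, `sigma`, `nSamples`,
#'   `percentCorrect`, `replicates`.
#' @export
runVirtualTable <- function(designs = 1:4, sigmas = 3,
                            nSamplesValues = 20L, replicates = 20L,
                            nMetagenome = 15L, nShared = 10L,
                            nLibraryOnly = 10L, m = 10,
                            genomeLength = 50000L, coverage = 0.75,
                            nFragments = 20L, letterErrorRate = 0.001,
                            k = 6L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(nShared <= nMetagenome)
    truth <- nMetagenome - nShared
    grid <- expand.grid(design = designs, sigma = sigmas,
                        nSamples = nSamplesValues,
                        KEEP.OUT.ATTRS = FALSE)
    nTotal <- nMetagenome + nLibraryOnly
    pct <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
        ok <- 0L
        for (r in seq_len(replicates)) {
            genomes <- generateSyntheticGenomes(nTotal, genomeLength)
            meta <- genomes[seq_len(nMetagenome)]
            selIds <- names(genomes)[(nMetagenome - nShared + 1L):nTotal]
            real <- generateSampleSet(meta, normalModel(m, grid$sigma[g]),
                nSamples = grid$nSamples[g], coverage = coverage,
                nFragments = nFragments,
                letterErrorRate = letterErrorRate, k = k)
            lib <- spectraLibrary(genomes[selIds], real@dictionary)
            virt <- buildVirtualSamples(lib, selIds,
                virtualDesign(grid$design[g], coverage = coverage,
                              errorRate = letterErrorRate),
                genomes = genomes)
            res <- tryCatch(
                countUnknownGenomes(real, virt, length(selIds)),
                warning = function(w) NULL, error = function(e) NULL)
            if (!is.null(res) && abs(res$nUnknown - truth) <= 1L)
                ok <- ok + 1L
        }
        pct[g] <- 100 * ok / replicates
    }
    data.frame(design = as.integer(grid$design), sigma = grid$sigma,
               nSamples = as.integer(grid$nSamples), percentCorrect = pct,
               replicates = as.integer(replicates))
}
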