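test_that("incremental rank detects exact dependences", {
    g <- generateSyntheticGenomes(4, 4000, seed = 50)
    sp <- do.call(rbind, lapply(seq_along(g), function(i)
        unname(bsCounts(computeBS(g[i], buildDictionary(4))))))
    expect_identical(incrementalRank(sp), 4L)
    b <- sp[1, ]; c0 <- sp[2, ]
    expect_identical(incrementalRank(rbind(b, 2 * b, b + c0)), 2L)
    expect_identical(incrementalRank(matrix(0, 3, 10)), 0L)
    expect_identical(incrementalRank(sp[0, , drop = FALSE]), 0L)
})

test_that("incremental rank equals the exact integer rank on count data", {
    set.seed(51)
    ss <- makeCleanSampleSet(8, 20)
    m <- ss@counts
    expect_identical(incrementalRank(m), 8L)
    expect_identical(incrementalRank(m), exactIntegerRank(m))
})

test_that("sequential basis building stops by the termination rule", {
    set.seed(52)
    d <- buildDictionary(4)
    one <- unname(bsCounts(computeBS(generateSyntheticGenome(3000), d)))
    stream <- matrix(rep(one, 7), nrow = 7, byrow = TRUE)
    res <- sequentialBasis(stream, stopM = 4)
    expect_identical(res$estimate@genomeCount, 1L)
    expect_identical(res$estimate@nSamplesUsed, 5L)  # 1 + stopM
    expect_true(res$estimate@terminated)
    expect_match(res$estimate@confidenceNote, "0.9375")

    # error-free stream over p genomes with {0,1} multiplicities
    g <- generateSyntheticGenomes(5, 4000, seed = 53)
    ss <- generateSampleSet(g, discreteModel(c(0, 1)), nSamples = 60,
                            coverage = 1, letterErrorRate = 0, k = 4,
                            seed = 54)
    res2 <- sequentialBasis(ss, stopM = 8)
    expect_identical(res2$estimate@genomeCount, 5L)

    # exhausted stream is flagged
    res3 <- sequentialBasis(ss@counts[1:2, ], stopM = 4)
    expect_false(res3$estimate@terminated)
})

test_that("mean consumed samples tracks the waiting-time theory", {
    set.seed(55)
    g <- generateSyntheticGenomes(3, 3000)
    used <- replicate(40, {
        ss <- generateSampleSet(g, discreteModel(c(0, 1)), nSamples = 60,
                                coverage = 1, letterErrorRate = 0, k = 4)
        sequentialBasis(ss, stopM = 4)$estimate@nSamplesUsed
    })
    # per-draw independence probability is at least 0.5, so the mean lies
    # between n + stopM and n/0.5 + stopM (plus Monte-Carlo slack)
    expect_gte(mean(used), 3 + 4 - 0.5)
    expect_lte(mean(used), expectedSampleCount(3, 0.5) + 4 +
                   3 * sd(used) / sqrt(length(used)))
})

test_that("PCA residual curves are monotone and vanish at the exact rank", {
    set.seed(56)
    g <- generateSyntheticGenomes(3, 4000)
    sp <- do.call(rbind, lapply(seq_along(g), function(i)
        unname(bsCounts(computeBS(g[i], buildDictionary(4))))))
    coefs <- matrix(sample(1:5, 30, replace = TRUE), 10, 3)
    x <- coefs %*% sp                      # exact rank 3
    cv <- pcaResidualCurve(x)
    expect_true(all(diff(cv@f) <= 1e-8 * cv@f[1]))
    expect_lt(cv@f[3] / cv@f[1], 1e-6)     # numerically zero: rank <= 3
    expect_error(pcaResidualCurve(x[1:2, ]), "at least 3")

    ss <- generateSampleSet(g, normalModel(8, 3), nSamples = 12,
                            coverage = 0.75, letterErrorRate = 0.001,
                            k = 4, seed = 57)
    cvn <- pcaResidualCurve(ss)
    expect_identical(cvn@nMax, 10L)   # min(N - 1, 4^k) - 1 with N = 12
    expect_true(all(cvn@f > 0))
    expect_true(all(diff(cvn@f) <= 0))
    expect_true(all(cvn@d1 >= 0 & cvn@d1 <= 1))
})

test_that("marker detection reads the second-derivative peak", {
    # hand-built curve: fast geometric decay through n = 9, slow beyond.
    # d1 = 0.5 for n <= 8 and 0.05 from n = 9 on, so d2 = (d1(n) -
    # d1(n+1))/d1(n) is 0.9 at n = 8 and ~0 elsewhere: the peak sits one
    # before the knee, by direct evaluation of the formulas
    f <- c(100 * 0.5^(1:9), 100 * 0.5^9 * 0.95^(1:9))
    cv <- new("MarkerCurves", f = f,
              d1 = (f[-length(f)] - f[-1]) / f[-length(f)],
              d2 = numeric(length(f) - 2), nMax = length(f))
    d1 <- cv@d1
    cv@d2 <- (d1[-length(d1)] - d1[-1]) / d1[-length(d1)]
    est <- detectMarkerPattern(cv)
    expect_identical(est@peakIndex, 8L)
    expect_identical(est@genomeCount, 9L)
    expect_identical(est@method, "pca_marker")

    # adjacent tied peaks resolve to the lower n, flagged ambiguous
    cv2 <- cv
    cv2@d2[c(5, 6)] <- max(cv@d2) + 1
    est2 <- detectMarkerPattern(cv2)
    expect_identical(est2@peakIndex, 5L)
    expect_true(est2@ambiguous)

    # exactly geometric decay has a flat d2: no marker pattern
    fg <- 100 * 0.8^(1:12)
    d1g <- (fg[-12] - fg[-1]) / fg[-12]
    cvg <- new("MarkerCurves", f = fg, d1 = d1g,
               d2 = (d1g[-11] - d1g[-1]) / d1g[-11], nMax = 12L)
    expect_error(detectMarkerPattern(cvg), "no marker pattern")
})

test_that("the estimator dispatches between exact and noisy paths", {
    set.seed(58)
    ss <- makeCleanSampleSet(10, 25)
    est <- estimateGenomeCount(ss)
    expect_identical(est@method, "exact_rank")
    expect_identical(genomeCount(est), 10L)

    expect_warning(e1 <- estimateGenomeCount(ss@counts[1, , drop = FALSE]),
                   "single sample")
    expect_identical(genomeCount(e1), 1L)

    g <- generateSyntheticGenomes(6, 30000)
    noisy <- generateSampleSet(g, normalModel(10, 3), nSamples = 14,
                               coverage = 0.75, letterErrorRate = 0.001)
    en <- estimateGenomeCount(noisy)
    expect_identical(en@method, "pca_marker")
    expect_true(abs(genomeCount(en) - 6L) <= 1L)
    expect_s4_class(markerCurves(en), "MarkerCurves")

    # scale invariance: counts are raw, a global rescaling changes nothing
    scaled <- noisy@counts * 3.7
    expect_identical(genomeCount(estimateGenomeCount(scaled)),
                     genomeCount(en))
    # row-permutation invariance of the PCA path
    perm <- sample(nrow(noisy@counts))
    expect_identical(genomeCount(estimateGenomeCount(noisy@counts[perm, ])),
                     genomeCount(en))
    # too few samples for marker detection
    expect_error(estimateGenomeCount(noisy@counts[1:4, ], method = "pca"),
                 "at least 5")
})
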