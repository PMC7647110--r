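test_that("synthetic genome generation is reproducible and exact-length", {
    g1 <- generateSyntheticGenome(1000, seed = 5)
    g2 <- generateSyntheticGenome(1000, seed = 5)
    expect_identical(as.character(g1), as.character(g2))
    expect_equal(nchar(as.character(g1[[1]])), 1000L)
    expect_error(generateSyntheticGenome(0), "positive")
    g3 <- generateSyntheticGenome(20000, seed = 6)
    g4 <- generateSyntheticGenome(20000, seed = 7)
    sp <- rbind(bsCounts(computeBS(g3)), bsCounts(computeBS(g4)))
    expect_identical(exactIntegerRank(sp), 2L)  # linearly independent
})

test_that("signature genomes have well-separated, independent spectra", {
    g <- generateSyntheticGenomes(5, 30000, seed = 11)
    sp <- do.call(rbind, lapply(seq_along(g),
                                function(i) bsCounts(computeBS(g[i]))))
    expect_identical(exactIntegerRank(sp), 5L)
    expect_true(all(pairwiseAngles(sp) > 0.2))  # real-genome-like spread
    gu <- generateSyntheticGenomes(3, 5000, composition = "uniform",
                                   seed = 11)
    expect_equal(nchar(as.character(gu[[2]])), 5000L)
})

test_that("letter mutation preserves length and hits the expected rate", {
    set.seed(20)
    s <- randomSeq(100000L)
    expect_identical(mutateLetters(s, 0), s)
    expect_error(mutateLetters(s, 1), "\\[0, 1\\)")
    expect_error(mutateLetters(s, -0.1), "\\[0, 1\\)")
    mu <- mutateLetters(s, 0.001)
    expect_equal(nchar(mu), nchar(s))
    d <- sum(strsplit(s, "")[[1]] != strsplit(mu, "")[[1]])
    # Binomial(1e5, 1e-3): mean 100, sd ~10; 4-sigma band
    expect_gt(d, 60); expect_lt(d, 140)
    # replacements never reproduce the original letter: at rate 0.5 the
    # observed difference fraction stays ~0.5, not 3/8
    s2 <- randomSeq(20000L)
    d2 <- mean(strsplit(s2, "")[[1]] != strsplit(mutateLetters(s2, 0.5), "")[[1]])
    expect_gt(d2, 0.45)
})

test_that("fragment sets follow the coverage and scheme contracts", {
    set.seed(21)
    g <- generateSyntheticGenome(9000, id = "g1")
    d <- buildDictionary(4)
    fs <- makeFragmentSet(g, coverage = 0.75, nFragments = 20,
                          letterErrorRate = 0.001, dictionary = d)
    expect_equal(nrow(fs@spectra), 20L)
    flen <- round(0.75 * 9000)
    # substitutions keep windows clean, so totals are exact
    expect_true(all(rowSums(fs@spectra) == 2 * (flen - 4 + 1)))
    # coverage 1, no errors: every fragment is the genome itself
    fs1 <- makeFragmentSet(g, coverage = 1, nFragments = 3,
                           letterErrorRate = 0, dictionary = d)
    ref <- unname(bsCounts(computeBS(g, d)))
    for (i in 1:3) expect_equal(unname(fs1@spectra[i, ]), ref)
    expect_error(makeFragmentSet(g, coverage = 0.9, nFragments = 20,
                                 scheme = "partition_exclusion",
                                 dictionary = d),
                 "nFragments = 10")
    expect_error(makeFragmentSet(g, coverage = 0.75, nFragments = 10,
                                 scheme = "partition_exclusion",
                                 dictionary = d),
                 "coverage = 0.9")
    expect_error(makeFragmentSet("ACGTACGT", coverage = 0.25,
                                 dictionary = d),
                 "shorter than k")
})

test_that("partition exclusion builds the nine-part concatenations", {
    set.seed(22)
    s <- randomSeq(5000L)
    d <- buildDictionary(3)
    fs <- makeFragmentSet(s, coverage = 0.9, nFragments = 10,
                          scheme = "partition_exclusion",
                          letterErrorRate = 0, dictionary = d,
                          genomeId = "g")
    expect_equal(nrow(fs@spectra), 10L)
    partLen <- 5000 %/% 10
    starts <- (0:9) * partLen + 1
    parts <- substring(s, starts, starts + partLen - 1)
    for (i in c(1L, 5L, 10L)) {
        expected <- bsCounts(computeBS(paste(parts[-i], collapse = ""), d))
        expect_equal(unname(fs@spectra[i, ]), unname(expected))
    }
    # each fragment omits exactly one part
    expect_true(all(rowSums(fs@spectra) == 2 * (9 * partLen - 3 + 1)))
})

test_that("multiplicity draws follow the declared models", {
    set.seed(23)
    expect_identical(drawMultiplicities(normalModel(7, 0), 5),
                     rep(7L, 5))
    x <- replicate(400, drawMultiplicities(discreteModel(c(0, 1)), 3))
    expect_true(all(x %in% c(0L, 1L)))
    expect_gt(mean(x), 0.4); expect_lt(mean(x), 0.6)
    xp <- replicate(400, drawMultiplicities(
        discreteModel(c(2, 5), probs = c(0.9, 0.1)), 1))
    expect_lt(mean(xp == 5), 0.2)
    expect_error(drawMultiplicities(
        discreteModel(list(c(0, 1), c(0, 1))), 3), "1 or nGenomes")
    # mean |t - m| of rounded-normal draws matches the closed-form series
    y <- drawMultiplicities(normalModel(10, 3), 1e5)
    expect_lt(abs(mean(abs(y - 10)) - roundedNormalMeanAbsDeviation(3)),
              3 * sd(abs(y - 10)) / sqrt(1e5))
})

test_that("sample synthesis is linear in the multiplicities", {
    set.seed(24)
    d <- buildDictionary(4)
    g1 <- generateSyntheticGenome(4000, id = "a")
    g2 <- generateSyntheticGenome(4000, id = "b")
    fs <- lapply(list(g1, g2), makeFragmentSet, coverage = 1,
                 nFragments = 4, letterErrorRate = 0, dictionary = d)
    zero <- synthesizeSample(fs, c(0, 0))
    expect_true(all(bsCounts(zero) == 0))
    one <- synthesizeSample(fs, c(1, 0))
    expect_equal(bsCounts(one), bsCounts(computeBS(g1, d)),
                 ignore_attr = TRUE)
    two <- synthesizeSample(fs, c(2, 0))
    expect_equal(unname(bsCounts(two)), 2 * unname(bsCounts(one)))
    expect_error(synthesizeSample(fs, c(1, 1, 1)), "does not match")
    expect_error(synthesizeSample(fs, c(-1, 1)), "nonnegative")
})

test_that("generated sample sets are reproducible and rank-bounded", {
    g <- generateSyntheticGenomes(3, 4000, seed = 31)
    s1 <- generateSampleSet(g, normalModel(5, 2), nSamples = 8,
                            coverage = 1, letterErrorRate = 0, k = 4,
                            seed = 32)
    s2 <- generateSampleSet(g, normalModel(5, 2), nSamples = 8,
                            coverage = 1, letterErrorRate = 0, k = 4,
                            seed = 32)
    expect_identical(sampleCounts(s1), sampleCounts(s2))
    expect_identical(nSamples(s1), 8L)
    # error-free rows are combinations of 3 genome spectra
    expect_lte(incrementalRank(s1), 3L)
    expect_identical(incrementalRank(s1), 3L)
    cfg <- provenance(s1)$config
    expect_equal(cfg$nGenomes, 3)
    expect_equal(cfg$coverage, 1)
    expect_equal(provenance(s1)$seed, 32)
})
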