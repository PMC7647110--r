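test_that("dictionary enumerates all words in lexicographic order", {
    d1 <- buildDictionary(1)
    expect_identical(kmerWords(d1), c("A", "C", "G", "T"))
    d3 <- buildDictionary(3)
    expect_length(kmerWords(d3), 64L)
    expect_identical(wordIndex(d3, "AAA"), 1L)
    expect_identical(wordIndex(d3, "TTT"), 64L)
    expect_identical(kmerWords(d3), oracleWords(3))
    expect_equal(length(kmerWords(buildDictionary(6))), 4096L)
    expect_error(buildDictionary(0), "1\\.\\.12")
    expect_error(buildDictionary(13), "1\\.\\.12")
    expect_error(buildDictionary(2.5), "1\\.\\.12")
})

test_that("computeBS counts both strands and rejects degenerate input", {
    d1 <- buildDictionary(1)
    cnt <- bsCounts(computeBS("AA", d1))
    expect_equal(unname(cnt[c("A", "C", "G", "T")]), c(2, 0, 0, 2))
    d2 <- buildDictionary(2)
    cnt2 <- bsCounts(computeBS("ACGT", d2))
    expect_equal(sum(cnt2), 6)  # 2 * (4 - 2 + 1), palindromic sequence
    expect_equal(unname(cnt2[c("AC", "CG", "GT")]), c(2, 2, 2))
    expect_error(computeBS("", d2), "empty")
    expect_error(computeBS("A", d2), "shorter than k")
    expect_equal(bsCounts(computeBS("acgt", d2)), cnt2)  # case-insensitive
})

test_that("computeBS matches the naive two-strand counter", {
    set.seed(101)
    for (k in c(1L, 2L, 3L, 6L)) {
        d <- buildDictionary(k)
        for (L in c(max(k, 8L), 200L)) {
            s <- randomSeq(L, withN = TRUE)
            expect_equal(bsCounts(computeBS(s, d)), oracleBS(s, k),
                         info = paste("k =", k, "L =", L))
        }
    }
    s <- randomSeq(10000L)
    expect_equal(bsCounts(computeBS(s, buildDictionary(6))), oracleBS(s, 6))
})

test_that("spectra are reverse-complement symmetric and strand-invariant", {
    set.seed(102)
    d <- buildDictionary(3)
    rc <- kmerDim:::revcompWords(kmerWords(d))
    for (i in 1:5) {
        s <- randomSeq(300L, withN = TRUE)
        cnt <- bsCounts(computeBS(s, d))
        expect_equal(unname(cnt), unname(cnt[rc]))  # symmetry
        expect_equal(cnt, bsCounts(computeBS(oracleRevComp(s), d)))
    }
    # mass: clean sequence sums to 2 (L - k + 1)
    s <- randomSeq(500L)
    expect_equal(sum(bsCounts(computeBS(s, d))), 2 * (500 - 3 + 1))
})

test_that("pairwise angles behave like angles", {
    v <- matrix(0, 3, 16)
    v[1, 1] <- 1; v[2, 2] <- 1; v[3, 1] <- 1
    a <- pairwiseAngles(v)
    expect_equal(a, c(pi / 2, 0, pi / 2))  # (1,2), (1,3), (2,3)
    expect_error(pairwiseAngles(rbind(v, 0)), "all-zero")
    expect_error(pairwiseAngles(v[1, , drop = FALSE]), "at least two")
    # spectra of two long random genomes: independent but not orthogonal
    g <- generateSyntheticGenomes(2, 20000, seed = 7)
    sp <- rbind(bsCounts(computeBS(g[1])), bsCounts(computeBS(g[2])))
    ang <- pairwiseAngles(sp)
    expect_gt(ang, 0)
    expect_lt(ang, pi / 2)
    expect_identical(exactIntegerRank(sp), 2L)
})

test_that("readFasta parses, uppercases and trims ids", {
    tf <- tempfile(fileext = ".fa")
    writeLines(c(">g1 some description", "ACGTAC", "GTACGT",
                 ">g2", "acgtnn"), tf)
    seqs <- readFasta(tf)
    expect_length(seqs, 2L)
    expect_identical(names(seqs), c("g1", "g2"))
    expect_identical(as.character(seqs[[1]]), "ACGTACGTACGT")
    expect_identical(as.character(seqs[[2]]), "ACGTNN")
    writeLines(character(0), tf)
    expect_error(readFasta(tf), "no FASTA records")
    expect_error(readFasta(tempfile()), "not found")
})

test_that("spectra TSV round-trips and long format is well-formed", {
    d <- buildDictionary(2)
    ss <- SampleSet(matrix(c(1:16, 16:1), nrow = 2, byrow = TRUE), d,
                    sampleIds = c("s1", "s2"))
    tf <- tempfile(fileext = ".tsv")
    writeSpectraTSV(ss, tf)
    back <- readSampleSetTSV(tf)
    expect_equal(sampleCounts(back), sampleCounts(ss))
    expect_identical(sampleIds(back), c("s1", "s2"))
    writeSpectraTSV(ss, tf, format = "long")
    lf <- read.delim(tf)
    expect_identical(colnames(lf), c("source_id", "word", "count"))
    expect_equal(nrow(lf), 32L)
    expect_equal(sum(lf$count), sum(sampleCounts(ss)))
})
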