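test_that("closed-form bounds evaluate to their known values", {
    expect_equal(independenceProbabilityBound(2, 1), 0.5)
    expect_equal(independenceProbabilityBound(2, 4), 0.9375)
    expect_true(all(diff(vapply(2:12, independenceProbabilityBound,
                                numeric(1), p = 1)) > 0))
    expect_error(independenceProbabilityBound(1, 1), ">= 2")
    expect_error(independenceProbabilityBound(2, 0), ">= 1")

    expect_equal(measureBound(1), 0.5)
    expect_error(measureBound(0), "positive")
    # uniform measure reduces to the combinatorial bound at codimension 1
    for (s in 2:5) {
        unif <- matrix(1 / s, nrow = 3, ncol = s)
        expect_equal(lambdaFromProbs(unif), s - 1)
        expect_equal(measureBound(lambdaFromProbs(unif)),
                     independenceProbabilityBound(s, 1))
    }

    expect_equal(lambdaFromProbs(rbind(c(0.5, 0.5), c(0.9, 0.1))), 1 / 9)
    expect_error(lambdaFromProbs(rbind(c(0.1, 0.9))), "non-increasing")
    expect_error(lambdaFromProbs(rbind(c(0.5, 0.4))), "sum to 1")

    expect_equal(round(lambdaNormal(10), 3), 0.995)
    lam <- vapply(c(0.5, 1, 2, 5, 10, 100), lambdaNormal, numeric(1))
    expect_true(all(diff(lam) > 0))     # strictly increasing in sigma0
    expect_true(all(lam < 1))
    expect_error(lambdaNormal(0), "positive")

    expect_equal(expectedSampleCount(10, 0.5), 20)
    expect_equal(expectedSampleCount(7, 1), 7)
    expect_error(expectedSampleCount(7, 0), "\\(0, 1\\]")
    for (lam in c(0.2, 1, 3))           # (1+lambda) n / lambda consistency
        expect_equal((1 + lam) * 12 / lam,
                     expectedSampleCount(12, measureBound(lam)))

    expect_equal(terminationConfidence(4, 0.5), 0.9375)
    expect_equal(round(100 * terminationConfidence(4, 0.5)), 94)
    expect_equal(terminationConfidence(1, 1), 1)
    conf <- vapply(1:8, terminationConfidence, numeric(1))
    expect_true(all(diff(conf) > 0))
})

test_that("rounded-normal absolute deviation matches simulation", {
    expect_equal(roundedNormalMeanAbsDeviation(0), 0)
    expect_error(roundedNormalMeanAbsDeviation(-1), "nonnegative")
    vals <- vapply(c(0.5, 1, 2, 3, 5), roundedNormalMeanAbsDeviation,
                   numeric(1))
    expect_true(all(diff(vals) > 0))
    set.seed(40)
    x <- abs(round(rnorm(2e5, 0, 1)))
    expect_lt(abs(mean(x) - roundedNormalMeanAbsDeviation(1)),
              3 * sd(x) / sqrt(2e5))
})

test_that("negative-binomial sampling length agrees with n/p", {
    set.seed(41)
    for (np in list(c(1, 0.5), c(10, 0.5), c(5, 0.8))) {
        r <- negativeBinomialMeanCheck(np[1], np[2], trials = 2e4)
        expect_lt(abs(r$mean - r$expected), 3 * r$se)
    }
    r1 <- negativeBinomialMeanCheck(6, 1, trials = 100)
    expect_equal(r1$mean, 6)
})

test_that("exhaustive enumeration reproduces the worked hyperplane examples", {
    # span of e1..e4 in 5-space: half of {0,1}^5 lies outside
    e <- diag(5)[1:4, ]
    expect_equal(as.numeric(enumerateFractionOutside(c(0, 1), e, n = 5)),
                 0.5)
    # span of u_i = (sum of all e_j) - e_i: the hyperplane contains the
    # four u_i and the zero vector, so 27 of 32 vectors lie outside
    u <- t(vapply(1:4, function(i) {
        v <- rep(1, 5); v[i] <- 0; v
    }, numeric(5)))
    fr <- enumerateFractionOutside(c(0, 1), u, n = 5)
    expect_equal(as.numeric(fr), 27 / 32)
    expect_equal(unname(attr(fr, "counts")["inside"]), 5)
    expect_error(enumerateFractionOutside(c(0, 1), diag(20)[1:2, ], n = 20),
                 "n <= 16")
    expect_error(enumerateFractionOutside(rep(list(0:9), 7), diag(7)[1:2, ]),
                 "too large")
    expect_error(enumerateFractionOutside(c(0, 1), rbind(e, e[1, ])),
                 "independent")
})

test_that("codimension bounds hold exhaustively on small instances", {
    set.seed(42)
    spansTried <- 0L
    for (n in 2:6) for (s in 2:3) {
        vs <- 0:(s - 1)
        for (rep in seq_len(10)) {
            spanDim <- sample.int(n - 1, 1)
            codim <- n - spanDim
            span <- NULL
            repeat {
                cand <- matrix(sample(-2:2, spanDim * n, replace = TRUE),
                               spanDim, n)
                if (exactIntegerRank(cand) == spanDim) { span <- cand; break }
            }
            fr <- enumerateFractionOutside(vs, span, n = n)
            expect_gte(as.numeric(fr),
                       independenceProbabilityBound(s, codim) - 1e-12)
            spansTried <- spansTried + 1L
        }
    }
    expect_gte(spansTried, 100L)
})

test_that("the measure-weighted hyperplane bound holds on random instances", {
    set.seed(43)
    for (rep in 1:30) {
        n <- sample(2:5, 1)
        s <- sample(2:3, 1)
        vs <- 0:(s - 1)
        # random non-increasing probability rows
        probs <- lapply(seq_len(n), function(i) {
            pr <- sort(runif(s), decreasing = TRUE)
            pr / sum(pr)
        })
        span <- NULL
        repeat {
            cand <- matrix(sample(-2:2, (n - 1) * n, replace = TRUE),
                           n - 1, n)
            if (exactIntegerRank(cand) == n - 1) { span <- cand; break }
        }
        # probability-weighted fraction outside, by direct enumeration
        grid <- as.matrix(expand.grid(rep(list(vs), n)))
        w <- apply(grid, 1, function(v)
            prod(vapply(seq_len(n),
                        function(i) probs[[i]][match(v[i], vs)],
                        numeric(1))))
        outside <- vapply(seq_len(nrow(grid)), function(i)
            exactIntegerRank(rbind(span, grid[i, ])) > n - 1, logical(1))
        massOutside <- sum(w[outside]) / sum(w)
        expect_gte(massOutside,
                   measureBound(lambdaFromProbs(do.call(rbind, probs))) -
                       1e-12)
    }
})

test_that("exact integer rank agrees with a floating-point reference", {
    set.seed(44)
    for (i in 1:50) {
        nr <- sample(2:6, 1); nc <- sample(2:6, 1)
        m <- matrix(sample(-5:5, nr * nc, replace = TRUE), nr, nc)
        expect_identical(exactIntegerRank(m), oracleQrRank(m),
                         info = paste("case", i))
    }
    expect_identical(exactIntegerRank(matrix(0, 3, 3)), 0L)
    expect_error(exactIntegerRank(matrix(c(0.5, 1, 1, 1), 2)), "integer")
    # large badly-scaled matrix: det = 2^31 by cofactor expansion, so the
    # true rank is 3; a floating-point QR rank at default tolerance calls
    # it 1, which is exactly why the exact path exists
    big <- matrix(c(2^30, 1, 1, 2^30, 2, 2, 2^30, 3, 5), 3, 3)
    expect_identical(exactIntegerRank(big), 3L)
})
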