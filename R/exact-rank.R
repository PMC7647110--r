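# Exact rank of integer matrices.
#
# Primary route: fraction-free (Bareiss) Gaussian elimination, which keeps
# every intermediate entry an integer (a minor of the input), so arithmetic
# in doubles is exact as long as entries stay below 2^52. When the guard
# trips (large counts, wide matrices), fall back to elimination over two
# prime fields with p < 46341, where all products stay below 2^31 and are
# again exact in doubles. The rank over a prime field never exceeds the
# rational rank; taking the maximum over two primes makes an undercount
# require all r x r minors to be divisible by both primes.

.MODP_PRIMES <- c(46337, 46327)

.modInverse <- function(a, p) {
    # a^(p-2) mod p by square-and-multiply; operands stay < p^2 < 2^31.
    res <- 1
    base <- a %% p
    e <- p - 2
    while (e > 0) {
        if (e %% 2 == 1) res <- (res * base) %% p
        base <- (base * base) %% p
        e <- e %/% 2
    }
    res
}

.modPRank <- function(m, p) {
    a <- m %% p
    nr <- nrow(a); nc <- ncol(a)
    rank <- 0L
    row <- 1L
    for (col in seq_len(nc)) {
        if (row > nr) break
        piv <- which(a[row:nr, col] != 0)
        if (length(piv) == 0L) next
        piv <- piv[1L] + row - 1L
        if (piv != row) a[c(row, piv), ] <- a[c(piv, row), ]
        inv <- .modInverse(a[row, col], p)
        a[row, ] <- (a[row, ] * inv) %% p
        if (row < nr) {
            below <- (row + 1L):nr
            fac <- a[below, col]
            nz <- which(fac != 0)
            if (length(nz)) {
                rows <- below[nz]
                a[rows, ] <- (a[rows, , drop = FALSE] -
                    outer(fac[nz], a[row, ])) %% p
            }
        }
        rank <- rank + 1L
        row <- row + 1L
    }
    rank
}

.bareissRank <- function(m, limit = 2^26) {
    # limit bounds the ENTRIES, not the quotients: the update multiplies
    # two entries before the exact division, and that product must stay
    # below 2^53 for double arithmetic to remain exact.
    a <- m
    nr <- nrow(a); nc <- ncol(a)
    rank <- 0L
    row <- 1L
    prev <- 1
    for (col in seq_len(nc)) {
        if (row > nr) break
        piv <- which(a[row:nr, col] != 0)
        if (length(piv) == 0L) next
        piv <- piv[1L] + row - 1L
        if (piv != row) a[c(row, piv), ] <- a[c(piv, row), ]
        if (row < nr) {
            below <- (row + 1L):nr
            if (max(abs(a[row:nr, ])) > limit) return(NA_integer_)
            newv <- (a[below, , drop = FALSE] * a[row, col] -
                     outer(a[below, col], a[row, ])) / prev
            if (max(abs(newv)) > limit) return(NA_integer_)
            a[below, ] <- newv
        }
        prev <- a[row, col]
        rank <- rank + 1L
        row <- row + 1L
    }
    rank
}

#' Exact rank of an integer matrix over the rationals
#'
#' Fraction-free integer elimination with a modular-arithmetic fallback
#' (see the source for the exactness argument). Tolerance-free, unlike
#' floating-point rank estimates, which is what the combinatorial
#' statements about multiplicity vectors require.
#'
#' @param m numeric matrix with integer-valued entries.
#' @return integer rank.
#' @export
exactIntegerRank <- function(m) {
    m <- as.matrix(m)
    if (length(m) == 0L) return(0L)
    if (anyNA(m) || any(m != round(m)))
        stop("matrix must have integer-valued entries", call. = FALSE)
    if (max(abs(m)) < 2^17) {
        r <- .bareissRank(m)
        if (!is.na(r)) return(r)
    }
    max(vapply(.MODP_PRIMES, function(p) .modPRank(m, p), integer(1)))
}
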