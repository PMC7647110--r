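# Independent oracles and small fixture builders. Nothing here calls the
# package's counting or rank code paths: the naive counter works on plain
# character vectors, the reference rank uses base qr() on small matrices.

oracleRevComp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    ch <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1L]])
    out <- comp[ch]
    out[is.na(out)] <- ch[is.na(out)]
    paste(out, collapse = "")
}

# All k-words over ACGT in lexicographic order, built with base R only.
oracleWords <- function(k) {
    g <- do.call(expand.grid,
                 c(rep(list(c("A", "C", "G", "T")), k),
                   stringsAsFactors = FALSE))
    sort(do.call(paste0, g[, rev(seq_len(k)), drop = FALSE]))
}

# Counts of clean k-windows of one strand; windows with non-ACGT letters
# are dropped.
oracleCountStrand <- function(s, k) {
    L <- nchar(s)
    if (L < k) return(character(0))
    w <- substring(s, 1:(L - k + 1), k:L)
    w[!grepl("[^ACGT]", w)]
}

# The naive double-stranded counter: both strands scanned 5'-to-3'.
oracleBS <- function(s, k) {
    s <- toupper(s)
    words <- oracleWords(k)
    hits <- c(oracleCountStrand(s, k),
              oracleCountStrand(oracleRevComp(s), k))
    tab <- table(factor(hits, levels = words))
    stats::setNames(as.numeric(tab), words)
}

randomSeq <- function(L, withN = FALSE) {
    alph <- c("A", "C", "G", "T", if (withN) "N")
    prob <- if (withN) c(rep(0.24, 4), 0.04) else NULL
    paste(sample(alph, L, replace = TRUE, prob = prob), collapse = "")
}

# Floating-point reference rank for small integer matrices.
oracleQrRank <- function(m) qr(m)$rank

# A tiny error-free SampleSet over p short genomes: every row an integer
# combination of the genome spectra.
makeCleanSampleSet <- function(p, nSamples, genomeLength = 5000,
                               m = 10, sigma = 3, k = 6) {
    genomes <- generateSyntheticGenomes(p, genomeLength)
    generateSampleSet(genomes, normalModel(m, sigma), nSamples = nSamples,
                      coverage = 1, letterErrorRate = 0, k = k)
}
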