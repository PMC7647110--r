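# Coerce assorted sequence containers to a single uppercase character string.
.asSequence <- function(x) {
    if (is(x, "DNAString")) return(as.character(x))
    if (is(x, "DNAStringSet")) {
        if (length(x) != 1L)
            stop("expected a single sequence, got ", length(x), call. = FALSE)
        return(as.character(x[[1L]]))
    }
    if (is.character(x) && length(x) == 1L) return(toupper(x))
    stop("cannot interpret object of class '", class(x)[1L],
         "' as a single DNA sequence", call. = FALSE)
}

# Double-stranded k-mer count matrix for a DNAStringSet (rows = sequences).
# Windows containing any non-ACGT letter match no dictionary word and are
# thereby skipped on both strands.
.bsMatrix <- function(seqs, k) {
    fwd <- Biostrings::oligonucleotideFrequency(seqs, width = k)
    rev <- Biostrings::oligonucleotideFrequency(
        Biostrings::reverseComplement(seqs), width = k)
    m <- fwd + rev
    storage.mode(m) <- "double"
    m
}

#' Compute the barcode spectrum of a sequence
#'
#' Counts every dictionary word on both strands of the sequence, read
#' 5'-to-3': `counts[w]` is the number of occurrences of `w` in the forward
#' strand plus the number of occurrences of `revcomp(w)` in the forward
#' strand. Any window containing a non-ACGT letter (e.g. N) contributes
#' nothing on either strand. For a clean sequence of length L the counts
#' sum to \eqn{2 (L - k + 1)}.
#'
#' @param x a single sequence: character string, [Biostrings::DNAString],
#'   or a length-1 [Biostrings::DNAStringSet] (its name is used as the
#'   default `sourceId`).
#' @param dictionary a [KmerDictionary]; defaults to the 6-mer dictionary.
#' @param sourceId identifier stored with the spectrum.
#' @return a [BarcodeSpectrum].
#' @examples
#' d1 <- buildDictionary(1)
#' bsCounts(computeBS("AA", d1))  # A:2 T:2 C:0 G:0
#' @export
computeBS <- function(x, dictionary = buildDictionary(6L),
                      sourceId = NULL) {
    stopifnot(is(dictionary, "KmerDictionary"))
    if (is.null(sourceId))
        sourceId <- if (is(x, "DNAStringSet") && !is.null(names(x)))
            names(x)[1L] else "sequence"
    s <- .asSequence(x)
    if (nchar(s) == 0L)
        stop("empty sequence", call. = FALSE)
    if (nchar(s) < dictionary@k)
        stop("sequence length (", nchar(s), ") is shorter than k (",
             dictionary@k, ")", call. = FALSE)
    counts <- .bsMatrix(Biostrings::DNAStringSet(s), dictionary@k)[1L, ]
    new("BarcodeSpectrum", counts = unname(counts), dictionary = dictionary,
        sourceId = as.character(sourceId))
}

#' Pairwise angles between barcode spectra
#'
#' The angle between two spectra is `acos` of their cosine similarity; for
#' nonnegative vectors it lies in \eqn{[0, \pi/2]}. Spectra of long random
#' (and of real bacterial) genomes are far from collinear, which is the
#' premise that makes the sample-spectra matrix rank equal to the genome
#' count.
#'
#' @param x a list of [BarcodeSpectrum] objects sharing one dictionary, a
#'   [SampleSet], or a numeric matrix with spectra in rows.
#' @return numeric vector of angles in radians, one per unordered pair, in
#'   row order of the upper triangle.
#' @export
pairwiseAngles <- function(x) {
    m <- if (is(x, "SampleSet")) {
        x@counts
    } else if (is.list(x)) {
        if (length(x) < 2L)
            stop("need at least two spectra", call. = FALSE)
        k0 <- vapply(x, function(b) b@dictionary@k, integer(1))
        if (length(unique(k0)) != 1L)
            stop("spectra use different dictionaries", call. = FALSE)
        do.call(rbind, lapply(x, function(b) b@counts))
    } else if (is.matrix(x)) {
        x
    } else stop("unsupported input for pairwiseAngles", call. = FALSE)
    if (nrow(m) < 2L)
        stop("need at least two spectra", call. = FALSE)
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0))
        stop("angle undefined for an all-zero spectrum", call. = FALSE)
    g <- tcrossprod(m / nrm)
    acos(pmin(1, pmax(-1, g[upper.tri(g)])))
}

#' @describeIn bsCounts counts of a single spectrum
#' @export
setMethod("bsCounts", "BarcodeSpectrum", function(x) {
    stats::setNames(x@counts, x@dictionary@words)
})

#' @describeIn sourceId source of a spectrum
#' @export
setMethod("sourceId", "BarcodeSpectrum", function(x) x@sourceId)

#' @describeIn kmerLength word length of a spectrum's dictionary
#' @export
setMethod("kmerLength", "BarcodeSpectrum", function(x) x@dictionary@k)

#' @describeIn dictionary dictionary of a spectrum
#' @export
setMethod("dictionary", "BarcodeSpectrum", function(x) x@dictionary)

setMethod("show", "BarcodeSpectrum", function(object) {
    cat("BarcodeSpectrum of '", object@sourceId, "': k = ",
        object@dictionary@k, ", total count ", sum(object@counts),
        ", ", sum(object@counts > 0), "/", length(object@counts),
        " words present\n", sep = "")
})

## ---- SampleSet construction and accessors ----

#' Construct a SampleSet from a count matrix
#'
#' @param counts numeric matrix, samples in rows, \eqn{4^k} word columns.
#' @param dictionary a [KmerDictionary] matching the column count.
#' @param sampleIds row identifiers; defaults to existing row names or
#'   `sample_1 ... sample_N`.
#' @param provenance list recording how the matrix was produced.
#' @return a [SampleSet].
#' @export
SampleSet <- function(counts, dictionary, sampleIds = NULL,
                      provenance = list()) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (is.null(sampleIds))
        sampleIds <- if (!is.null(rownames(counts))) rownames(counts)
                     else paste0("sample_", seq_len(nrow(counts)))
    rownames(counts) <- NULL
    colnames(counts) <- NULL
    new("SampleSet", counts = counts, sampleIds = as.character(sampleIds),
        dictionary = dictionary, provenance = provenance)
}

#' @describeIn sampleCounts samples-by-words matrix of a SampleSet
#' @export
setMethod("sampleCounts", "SampleSet", function(x) {
    m <- x@counts
    dimnames(m) <- list(x@sampleIds, x@dictionary@words)
    m
})

#' @describeIn sampleIds ids of a SampleSet
#' @export
setMethod("sampleIds", "SampleSet", function(x) x@sampleIds)

#' @describeIn nSamples rows of a SampleSet
#' @export
setMethod("nSamples", "SampleSet", function(x) nrow(x@counts))

#' @describeIn kmerLength word length of a SampleSet's dictionary
#' @export
setMethod("kmerLength", "SampleSet", function(x) x@dictionary@k)

#' @describeIn dictionary dictionary of a SampleSet
#' @export
setMethod("dictionary", "SampleSet", function(x) x@dictionary)

#' @describeIn provenance provenance of a SampleSet
#' @export
setMethod("provenance", "SampleSet", function(x) x@provenance)

#' Subset samples
#'
#' `x[i]` keeps the selected sample rows (all words are retained).
#' @param x a [SampleSet].
#' @param i row index vector.
#' @param j unused.
#' @param ... unused.
#' @param drop unused.
#' @export
setMethod("[", "SampleSet", function(x, i, j, ..., drop = FALSE) {
    new("SampleSet", counts = x@counts[i, , drop = FALSE],
        sampleIds = x@sampleIds[i], dictionary = x@dictionary,
        provenance = x@provenance)
})

#' Stack two sample sets sharing a dictionary
#'
#' Used to append virtual samples to real ones; duplicate ids on the right
#' are suffixed.
#' @param x,y [SampleSet] objects over identical dictionaries.
#' @return a [SampleSet] with the rows of `x` followed by the rows of `y`.
#' @export
combineSamples <- function(x, y) {
    stopifnot(is(x, "SampleSet"), is(y, "SampleSet"))
    if (x@dictionary@k != y@dictionary@k ||
        !identical(x@dictionary@words, y@dictionary@words))
        stop("sample sets use different dictionaries", call. = FALSE)
    ids <- c(x@sampleIds, y@sampleIds)
    dup <- duplicated(ids)
    if (any(dup)) ids[dup] <- paste0(ids[dup], "_2")
    new("SampleSet", counts = rbind(x@counts, y@counts), sampleIds = ids,
        dictionary = x@dictionary,
        provenance = list(combined = list(x@provenance, y@provenance)))
}

setMethod("show", "SampleSet", function(object) {
    cat("SampleSet:", nrow(object@counts), "samples x",
        ncol(object@counts), "words (k =", object@dictionary@k, ")\n")
    if (length(object@provenance))
        cat("  provenance:", paste(names(object@provenance), collapse = ", "),
            "\n")
})
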