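DNA_BASES <- c("A", "C", "G", "T")

#' Build the dictionary of all DNA words of length k
#'
#' Enumerates all \eqn{4^k} words over \{A,C,G,T\} in lexicographic order
#' (A < C < G < T), the order used throughout the package for spectrum
#' vectors and TSV output. The dictionary is closed under reverse
#' complement, which is what makes the double-stranded symmetry of barcode
#' spectra expressible coordinate-wise.
#'
#' @param k word length; the default 6 gives the 4096-dimensional spectrum
#'   space used for bacterial genome comparison.
#' @return a [KmerDictionary].
#' @examples
#' d <- buildDictionary(3)
#' kmerWords(d)[1]   # "AAA"
#' kmerWords(d)[64]  # "TTT"
#' @export
buildDictionary <- function(k = 6L) {
    if (length(k) != 1L || is.na(k) || k != round(k) || k < 1L || k > 12L)
        stop("k must be a single integer in 1..12", call. = FALSE)
    k <- as.integer(k)
    words <- Biostrings::mkAllStrings(DNA_BASES, k)
    new("KmerDictionary", k = k, words = words)
}

#' Reverse complement of a set of words
#'
#' @param words character vector of DNA words.
#' @return character vector of the same length.
#' @keywords internal
revcompWords <- function(words) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
}

#' Positions of words in a dictionary
#'
#' @param dictionary a [KmerDictionary].
#' @param words character vector of words to look up.
#' @return integer positions (1-based) into the dictionary order.
#' @export
wordIndex <- function(dictionary, words) {
    stopifnot(is(dictionary, "KmerDictionary"))
    idx <- match(words, dictionary@words)
    if (anyNA(idx))
        stop("word(s) not in dictionary: ",
             paste(head(words[is.na(idx)], 3L), collapse = ", "),
             call. = FALSE)
    idx
}

#' @describeIn kmerLength word length of a dictionary
#' @export
setMethod("kmerLength", "KmerDictionary", function(x) x@k)

#' @describeIn kmerWords words of a dictionary
#' @export
setMethod("kmerWords", "KmerDictionary", function(x) x@words)

setMethod("show", "KmerDictionary", function(object) {
    cat("KmerDictionary: k =", object@k, "|", length(object@words),
        "words (", object@words[1], "...",
        object@words[length(object@words)], ")\n")
})
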