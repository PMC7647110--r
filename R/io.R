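#' Read genome sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]: sequence names are
#' trimmed to the first whitespace-delimited token of the header and
#' lowercase letters are uppercased (IUPAC ambiguity letters are
#' tolerated; windows containing them are skipped during spectrum
#' computation). Plain and gzip-compressed FASTA are accepted.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet], one element per entry.
#' @export
readFasta <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
        error = function(e)
            stop("failed to parse FASTA file '", path, "': ",
                 conditionMessage(e), call. = FALSE))
    if (length(seqs) == 0L)
        stop("no FASTA records in '", path, "'", call. = FALSE)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs
}

#' Write spectra to a TSV file
#'
#' Wide format: a `source_id` column followed by one column per dictionary
#' word (header row of words, in dictionary order). Long format (intended
#' for small k): columns `source_id`, `word`, `count`.
#'
#' @param x a [SampleSet], a [BarcodeSpectrum], or a list of
#'   [BarcodeSpectrum] objects sharing one dictionary.
#' @param path output file path.
#' @param format `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
writeSpectraTSV <- function(x, path, format = c("wide", "long")) {
    format <- match.arg(format)
    if (is(x, "BarcodeSpectrum")) x <- list(x)
    if (is.list(x)) {
        dict <- x[[1L]]@dictionary
        m <- do.call(rbind, lapply(x, function(b) b@counts))
        ids <- vapply(x, function(b) b@sourceId, character(1))
    } else if (is(x, "SampleSet")) {
        dict <- x@dictionary
        m <- x@counts
        ids <- x@sampleIds
    } else stop("unsupported input for writeSpectraTSV", call. = FALSE)
    if (format == "wide") {
        df <- data.frame(source_id = ids, m, check.names = FALSE)
        colnames(df) <- c("source_id", dict@words)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        df <- data.frame(
            source_id = rep(ids, each = ncol(m)),
            word = rep(dict@words, times = nrow(m)),
            count = as.vector(t(m)))
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read a samples-by-words spectra matrix from TSV
#'
#' Reads the wide format written by [writeSpectraTSV()]: a `source_id`
#' column plus \eqn{4^k} word columns. The word length is inferred from
#' the column count and the header is checked against the lexicographic
#' dictionary order.
#'
#' @param path path to the TSV file.
#' @return a [SampleSet] with empty provenance.
#' @export
readSampleSetTSV <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L || colnames(df)[1L] != "source_id")
        stop("expected a 'source_id' column followed by word columns",
             call. = FALSE)
    nw <- ncol(df) - 1L
    k <- as.integer(round(log(nw, 4)))
    if (4^k != nw)
        stop("number of word columns (", nw, ") is not a power of 4",
             call. = FALSE)
    dict <- buildDictionary(k)
    if (!identical(colnames(df)[-1L], dict@words))
        stop("word columns are not in lexicographic dictionary order",
             call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (anyNA(m) || !is.numeric(m))
        stop("non-numeric or missing counts in '", path, "'", call. = FALSE)
    SampleSet(m, dict, sampleIds = as.character(df[[1L]]))
}
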