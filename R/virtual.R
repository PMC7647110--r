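#' Build a library of known genome spectra
#'
#' @param genomes a named [Biostrings::DNAStringSet] of genome sequences,
#'   or a numeric matrix of full-genome spectra with genome ids as row
#'   names.
#' @param dictionary a [KmerDictionary] (used directly when `genomes` is a
#'   matrix; otherwise spectra are computed at its word length).
#' @return a [SpectraLibrary].
#' @export
spectraLibrary <- function(genomes, dictionary = buildDictionary(6L)) {
    if (is.matrix(genomes)) {
        return(new("SpectraLibrary", spectra = genomes,
                   dictionary = dictionary))
    }
    if (!is(genomes, "DNAStringSet"))
        stop("genomes must be a DNAStringSet or a spectra matrix",
             call. = FALSE)
    if (is.null(names(genomes)) || anyDuplicated(names(genomes)))
        stop("genomes must carry unique names", call. = FALSE)
    m <- .bsMatrix(genomes, dictionary@k)
    rownames(m) <- names(genomes)
    new("SpectraLibrary", spectra = m, dictionary = dictionary)
}

#' Genome identifiers held by a library
#' @param library a [SpectraLibrary].
#' @return character vector of genome ids.
#' @export
libraryIds <- function(library) {
    stopifnot(is(library, "SpectraLibrary"))
    rownames(library@spectra)
}

#' @describeIn kmerLength word length of a library's dictionary
#' @export
setMethod("kmerLength", "SpectraLibrary", function(x) x@dictionary@k)

#' @describeIn dictionary dictionary of a library
#' @export
setMethod("dictionary", "SpectraLibrary", function(x) x@dictionary)

setMethod("show", "SpectraLibrary", function(object) {
    cat("SpectraLibrary:", nrow(object@spectra), "genomes, k =",
        object@dictionary@k, "\n")
})

#' Describe a virtual-sample design
#'
#' @param design integer 1-4 or one of `"single_clean"`,
#'   `"mixture_clean"`, `"single_error"`, `"mixture_error"` (designs 1-4
#'   in that order).
#' @param nVirtual number of virtual samples; NA picks the design default
#'   (one per selected genome for single designs, twice that for
#'   mixtures).
#' @param mixtureRange inclusive integer range for mixture coefficients
#'   (default 1..3, mirroring small copy numbers).
#' @param includeProb probability that a selected genome enters a mixture
#'   row (default 0.5; empty mixtures are redrawn).
#' @param coverage fragment coverage f for the error designs.
#' @param errorRate per-letter substitution rate for the error designs.
#' @return a [VirtualDesign].
#' @export
virtualDesign <- function(design, nVirtual = NA, mixtureRange = c(1L, 3L),
                          includeProb = 0.5, coverage = 0.75,
                          errorRate = 0.001) {
    names4 <- c("single_clean", "mixture_clean", "single_error",
                "mixture_error")
    if (is.numeric(design)) {
        if (length(design) != 1L || !design %in% 1:4)
            stop("numeric design must be 1, 2, 3 or 4", call. = FALSE)
        design <- names4[design]
    }
    design <- match.arg(design, names4)
    new("VirtualDesign", design = design, nVirtual = as.integer(nVirtual),
        mixtureRange = as.integer(mixtureRange),
        includeProb = includeProb, coverage = coverage,
        errorRate = errorRate)
}

# Random positive-integer mixture row over the selected spectra.
.mixtureRow <- function(spectra, design) {
    n <- nrow(spectra)
    repeat {
        incl <- runif(n) < design@includeProb
        if (any(incl)) break
    }
    lo <- design@mixtureRange[1L]; hi <- design@mixtureRange[2L]
    coef <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
    as.numeric(coef[incl] %*% spectra[incl, , drop = FALSE])
}

# One error-bearing fragment spectrum per requested genome id (batched).
.errorSpectra <- function(genomes, ids, design, dictionary) {
    seqs <- vapply(ids, function(id) {
        s <- .asSequence(genomes[id])
        flen <- round(design@coverage * nchar(s))
        if (flen < dictionary@k)
            stop("fragment shorter than k for genome '", id, "'",
                 call. = FALSE)
        mutateLetters(.randomWindow(s, flen), design@errorRate)
    }, character(1), USE.NAMES = FALSE)
    .bsMatrix(Biostrings::DNAStringSet(seqs), dictionary@k)
}

#' Fabricate virtual samples from a library of known genomes
#'
#' Virtual samples are spectra built from library genomes and appended to
#' the real samples so that the estimated total dimension, minus the
#' number of genomes added, counts the genomes absent from the library.
#' Design 1 places one clean library spectrum per virtual sample (each
#' selected genome appears at least once); design 2 makes each virtual
#' sample a random positive-integer mixture of the selected spectra;
#' designs 3 and 4 repeat 1 and 2 with each spectrum replaced by an
#' error-bearing fragment spectrum of the genome, which requires the
#' genome sequences themselves.
#'
#' @param library a [SpectraLibrary].
#' @param selectedIds genome ids to use, all present in the library.
#' @param design a [VirtualDesign] (or an integer 1-4 / design name, which
#'   is passed to [virtualDesign()] with defaults).
#' @param genomes named [Biostrings::DNAStringSet] with the selected
#'   genomes' sequences; required for the error designs.
#' @param seed optional integer seed.
#' @return a [SampleSet] of virtual rows; provenance records the design
#'   and ids.
#' @export
buildVirtualSamples <- function(library, selectedIds, design,
                                genomes = NULL, seed = NULL) {
    stopifnot(is(library, "SpectraLibrary"))
    if (!is(design, "VirtualDesign")) design <- virtualDesign(design)
    validObject(design)
    if (length(selectedIds) == 0L)
        stop("empty genome selection", call. = FALSE)
    missing <- setdiff(selectedIds, libraryIds(library))
    if (length(missing))
        stop("ids not in library: ", paste(head(missing, 3L), collapse = ", "),
             call. = FALSE)
    if (anyDuplicated(selectedIds))
        stop("selectedIds must be unique", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    nSel <- length(selectedIds)
    single <- design@design %in% c("single_clean", "single_error")
    nV <- design@nVirtual
    if (is.na(nV)) nV <- if (single) nSel else 2L * nSel
    if (single && nV < nSel)
        stop("single designs need nVirtual >= number of selected genomes",
             call. = FALSE)
    sel <- library@spectra[selectedIds, , drop = FALSE]
    dict <- library@dictionary
    if (grepl("error", design@design)) {
        if (is.null(genomes))
            stop("error designs need the genome sequences (genomes =)",
                 call. = FALSE)
        if (!all(selectedIds %in% names(genomes)))
            stop("genomes must contain every selected id", call. = FALSE)
    }
    m <- switch(design@design,
        single_clean = sel[rep_len(seq_len(nSel), nV), , drop = FALSE],
        mixture_clean = t(vapply(seq_len(nV), function(i)
            .mixtureRow(sel, design), numeric(ncol(sel)))),
        single_error = .errorSpectra(
            genomes, selectedIds[rep_len(seq_len(nSel), nV)], design, dict),
        mixture_error = t(vapply(seq_len(nV), function(i) {
            repeat {
                incl <- runif(nSel) < design@includeProb
                if (any(incl)) break
            }
            lo <- design@mixtureRange[1L]; hi <- design@mixtureRange[2L]
            coef <- lo + sample.int(hi - lo + 1L, sum(incl),
                                    replace = TRUE) - 1L
            err <- .errorSpectra(genomes, selectedIds[incl], design, dict)
            as.numeric(coef %*% err)
        }, numeric(ncol(sel)))))
    SampleSet(m, dict, sampleIds = paste0("virtual_", seq_len(nV)),
        provenance = list(
            config = list(design = design@design, selectedIds = selectedIds,
                          nVirtual = nV, coverage = design@coverage,
                          errorRate = design@errorRate),
            seed = seed))
}

#' Count the genomes of a metagenome that are absent from a library
#'
#' Stacks the real samples with the virtual samples, estimates the total
#' number of distinct genomes Z in the combined set, and returns
#' `Z - nLibraryAdded`, where `nLibraryAdded` is the number of distinct
#' library genomes used in the virtual samples. If the metagenome holds p
#' genomes of which p1 are among the added library genomes, the combined
#' set spans p + (nLibraryAdded - p1) dimensions and the result is
#' p - p1, the number of unknown genomes. Negative results are clamped to
#' zero and flagged.
#'
#' @param real [SampleSet] of real samples.
#' @param virtual [SampleSet] of virtual samples (same dictionary), or
#'   NULL to reduce to a plain genome-count estimate.
#' @param nLibraryAdded number of distinct library genomes represented in
#'   the virtual samples.
#' @param ... passed to [estimateGenomeCount()].
#' @return list with `nUnknown` (integer, clamped at 0), `Z` (estimated
#'   total dimension), `clamped` (logical) and `estimate` (the underlying
#'   [DimensionEstimate]).
#' @export
countUnknownGenomes <- function(real, virtual = NULL, nLibraryAdded, ...) {
    stopifnot(is(real, "SampleSet"))
    if (!is.numeric(nLibraryAdded) || nLibraryAdded < 0 ||
        nLibraryAdded != round(nLibraryAdded))
        stop("nLibraryAdded must be a nonnegative integer", call. = FALSE)
    combined <- if (is.null(virtual)) real else combineSamples(real, virtual)
    est <- estimateGenomeCount(combined, ...)
    z <- est@genomeCount
    raw <- z - as.integer(nLibraryAdded)
    clamped <- raw < 0L
    if (clamped)
        warning("estimated dimension below the number of added genomes; ",
                "unknown-genome count clamped to 0")
    list(nUnknown = max(0L, raw), Z = z, clamped = clamped, estimate = est)
}
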