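#' @import methods
#' @importFrom stats pnorm rnorm runif rnbinom sd quantile
#' @importFrom utils head tail read.delim write.table
NULL

#' KmerDictionary: the word support of a barcode spectrum
#'
#' Holds the ordered set of all \eqn{4^k} DNA words of length `k` over
#' \{A,C,G,T\}. Words are kept in lexicographic order (A < C < G < T), the
#' same order used by [Biostrings::oligonucleotideFrequency()], so that
#' spectrum vectors and TSV exports are bit-reproducible.
#'
#' @slot k integer word length.
#' @slot words character vector of all \eqn{4^k} words, lexicographic.
#' @seealso [buildDictionary()]
#' @export
setClass("KmerDictionary",
    representation(k = "integer", words = "character"))

setValidity("KmerDictionary", function(object) {
    msg <- NULL
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
        msg <- c(msg, "k must be a single positive integer")
    else if (length(object@words) != 4^object@k)
        msg <- c(msg, sprintf("expected %d words, got %d",
                              4^object@k, length(object@words)))
    if (anyDuplicated(object@words))
        msg <- c(msg, "words must be unique")
    if (is.null(msg)) TRUE else msg
})

#' BarcodeSpectrum: double-stranded k-mer counts of one sequence
#'
#' A length-\eqn{4^k} nonnegative count vector over a [KmerDictionary].
#' Entry `w` is the number of occurrences of word `w` counted on both
#' strands read 5'-to-3', so the vector is symmetric under reverse
#' complement: `counts[w] == counts[revcomp(w)]`.
#'
#' @slot counts numeric vector of length \eqn{4^k}, nonnegative.
#' @slot dictionary the [KmerDictionary] the counts are indexed by.
#' @slot sourceId identifier of the sequence the spectrum was computed from.
#' @seealso [computeBS()]
#' @export
setClass("BarcodeSpectrum",
    representation(counts = "numeric", dictionary = "KmerDictionary",
                   sourceId = "character"))

setValidity("BarcodeSpectrum", function(object) {
    msg <- NULL
    if (length(object@counts) != 4^object@dictionary@k)
        msg <- c(msg, "counts length must equal 4^k")
    if (anyNA(object@counts) || any(object@counts < 0))
        msg <- c(msg, "counts must be nonnegative and non-missing")
    if (length(object@sourceId) != 1L)
        msg <- c(msg, "sourceId must be a single string")
    if (is.null(msg)) TRUE else msg
})

#' MultiplicityModel: per-sample genome copy-number generator
#'
#' Describes how the copy number of each genome fluctuates across samples
#' of the same medium. Two kinds are supported: `"normal"` draws each copy
#' number as an integer-rounded Normal(m, sigma) clipped below at zero;
#' `"discrete"` draws each genome's copy number uniformly (or with supplied
#' probabilities) from a finite set of nonnegative integers.
#'
#' @slot kind `"normal"` or `"discrete"`.
#' @slot m mean copy number (normal kind).
#' @slot sigma standard deviation of the copy number (normal kind).
#' @slot valueSets list of per-genome integer value sets (discrete kind);
#'   a single set is recycled over genomes.
#' @slot probs list of per-genome probability vectors matching `valueSets`,
#'   or an empty list for uniform draws.
#' @seealso [normalModel()], [discreteModel()], [drawMultiplicities()]
#' @export
setClass("MultiplicityModel",
    representation(kind = "character", m = "numeric", sigma = "numeric",
                   valueSets = "list", probs = "list"))

setValidity("MultiplicityModel", function(object) {
    msg <- NULL
    if (!object@kind %in% c("normal", "discrete"))
        msg <- c(msg, "kind must be 'normal' or 'discrete'")
    if (object@kind == "normal") {
        if (length(object@m) != 1L || object@m <= 0)
            msg <- c(msg, "m must be a single positive number")
        if (length(object@sigma) != 1L || object@sigma < 0)
            msg <- c(msg, "sigma must be a single nonnegative number")
    } else if (object@kind == "discrete") {
        if (length(object@valueSets) < 1L)
            msg <- c(msg, "discrete kind needs at least one value set")
        for (vs in object@valueSets) {
            if (length(vs) < 1L || anyNA(vs) || any(vs < 0) ||
                any(vs != round(vs))) {
                msg <- c(msg,
                    "value sets must be nonempty nonnegative integers")
                break
            }
        }
        if (length(object@probs)) {
            if (length(object@probs) != length(object@valueSets))
                msg <- c(msg, "probs must match valueSets in length")
            else for (i in seq_along(object@probs)) {
                pr <- object@probs[[i]]
                if (length(pr) != length(object@valueSets[[i]]) ||
                    any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
                    msg <- c(msg, "each probs row must be nonnegative and sum to 1")
                    break
                }
            }
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' FragmentSet: error-bearing fragment spectra of one genome
#'
#' The set G(g, f) of barcode spectra of fragments covering fraction `f`
#' of genome `g`, each fragment carrying random letter-substitution
#' errors. Used by the sample simulator to emulate the loss of part of a
#' genome and sequencing errors: each genome copy in a sample contributes
#' one spectrum drawn uniformly from this set.
#'
#' @slot genomeId identifier of the source genome.
#' @slot coverage fraction f of the genome covered by each fragment.
#' @slot spectra matrix, one row per fragment spectrum, \eqn{4^k} columns.
#' @slot scheme `"random_window"` (contiguous window at a uniform random
#'   start, circular genome) or `"partition_exclusion"` (ten fragments,
#'   each omitting one of ten equal parts; f = 0.9).
#' @slot dictionary shared [KmerDictionary].
#' @seealso [makeFragmentSet()]
#' @export
setClass("FragmentSet",
    representation(genomeId = "character", coverage = "numeric",
                   spectra = "matrix", scheme = "character",
                   dictionary = "KmerDictionary"))

setValidity("FragmentSet", function(object) {
    msg <- NULL
    if (ncol(object@spectra) != 4^object@dictionary@k)
        msg <- c(msg, "spectra must have 4^k columns")
    if (any(object@spectra < 0))
        msg <- c(msg, "fragment spectra must be nonnegative")
    if (!object@scheme %in% c("random_window", "partition_exclusion"))
        msg <- c(msg, "unknown scheme")
    if (length(object@coverage) != 1L || object@coverage <= 0 ||
        object@coverage > 1)
        msg <- c(msg, "coverage must be in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' SampleSet: per-sample barcode spectra of a metagenome
#'
#' The central data object: an N-samples-by-\eqn{4^k} nonnegative matrix,
#' one row per medium sample, whose linear dimension equals (or, with data
#' errors, is close to) the number of distinct genomes in the medium.
#'
#' @slot counts numeric matrix, samples in rows, words in columns.
#' @slot sampleIds character vector of row identifiers.
#' @slot dictionary shared [KmerDictionary].
#' @slot provenance list recording the generating configuration and seed
#'   (empty for real data read from file).
#' @seealso [generateSampleSet()], [estimateGenomeCount()]
#' @export
setClass("SampleSet",
    representation(counts = "matrix", sampleIds = "character",
                   dictionary = "KmerDictionary", provenance = "list"))

setValidity("SampleSet", function(object) {
    msg <- NULL
    if (nrow(object@counts) != length(object@sampleIds))
        msg <- c(msg, "sampleIds must match the number of rows")
    if (ncol(object@counts) != 4^object@dictionary@k)
        msg <- c(msg, "counts must have 4^k columns")
    if (anyNA(object@counts) || any(object@counts < 0))
        msg <- c(msg, "counts must be nonnegative and non-missing")
    if (anyDuplicated(object@sampleIds))
        msg <- c(msg, "sampleIds must be unique")
    if (is.null(msg)) TRUE else msg
})

#' MarkerCurves: PCA residual curve and its normalized derivatives
#'
#' For a centered sample matrix, `f[n]` is the sum over samples of the
#' Euclidean distance of each row to the span of the first `n` principal
#' components. The normalized first derivative is
#' `d1[n] = (f[n] - f[n+1]) / f[n]` and the normalized second derivative is
#' `d2[n] = (d1[n] - d1[n+1]) / d1[n]`. A sharp peak of `d2` marks the
#' intrinsic linear dimension of the (noisy) sample set.
#'
#' @slot f numeric residual curve, n = 1..nMax.
#' @slot d1 numeric, length nMax - 1.
#' @slot d2 numeric, length nMax - 2.
#' @slot nMax integer, number of principal components examined.
#' @seealso [pcaResidualCurve()], [detectMarkerPattern()]
#' @export
setClass("MarkerCurves",
    representation(f = "numeric", d1 = "numeric", d2 = "numeric",
                   nMax = "integer"))

setValidity("MarkerCurves", function(object) {
    msg <- NULL
    if (length(object@f) != object@nMax)
        msg <- c(msg, "f must have length nMax")
    if (length(object@d1) != max(0L, object@nMax - 1L))
        msg <- c(msg, "d1 must have length nMax - 1")
    if (length(object@d2) != max(0L, object@nMax - 2L))
        msg <- c(msg, "d2 must have length nMax - 2")
    if (any(object@f < -1e-9))
        msg <- c(msg, "f must be nonnegative")
    if (any(diff(object@f) > 1e-6 * max(object@f, 1)))
        msg <- c(msg, "f must be non-increasing")
    if (is.null(msg)) TRUE else msg
})

#' DimensionEstimate: estimated number of distinct genomes
#'
#' Result container for the genome-count estimators. `method` records which
#' path produced the estimate: `"exact_rank"` (incremental rank of
#' error-free data) or `"pca_marker"` (marker-pattern detection on noisy
#' data, where `genomeCount = peakIndex + 1` because centering the data
#' consumes the mean direction).
#'
#' @slot genomeCount integer estimate of the number of distinct genomes.
#' @slot peakIndex integer position of the detected second-derivative peak
#'   (NA for the exact path).
#' @slot method `"exact_rank"` or `"pca_marker"`.
#' @slot curves the [MarkerCurves] examined (PCA path), or NULL.
#' @slot confidenceNote human-readable note: termination-rule confidence
#'   for the exact path, the +/-1 reporting band for the PCA path.
#' @slot ambiguous TRUE when tied peaks (or an exact-zero residual
#'   shortcut) make the estimate uncertain by one.
#' @slot terminated FALSE when a sequential stream was exhausted before the
#'   termination rule fired.
#' @slot nSamplesUsed number of samples consumed.
#' @export
setClass("DimensionEstimate",
    representation(genomeCount = "integer", peakIndex = "integer",
                   method = "character", curves = "ANY",
                   confidenceNote = "character", ambiguous = "logical",
                   terminated = "logical", nSamplesUsed = "integer"))

#' BasisState: state of the sequential basis-building procedure
#'
#' @slot basisRows matrix of the currently accepted linearly independent
#'   sample spectra (one per row).
#' @slot consecutiveDependent number of consecutive samples found linearly
#'   dependent on the current basis; reset to zero whenever a basis row is
#'   added.
#' @slot stopM termination threshold: stop after this many consecutive
#'   dependent samples.
#' @slot tolerance relative residual-norm threshold used for the
#'   dependence test.
#' @seealso [sequentialBasis()]
#' @export
setClass("BasisState",
    representation(basisRows = "matrix", consecutiveDependent = "integer",
                   stopM = "integer", tolerance = "numeric"))

#' SpectraLibrary: known genomes represented by their barcode spectra
#'
#' @slot spectra matrix of full-genome barcode spectra, one genome per row;
#'   row names are the genome identifiers.
#' @slot dictionary shared [KmerDictionary].
#' @seealso [spectraLibrary()], [buildVirtualSamples()]
#' @export
setClass("SpectraLibrary",
    representation(spectra = "matrix", dictionary = "KmerDictionary"))

setValidity("SpectraLibrary", function(object) {
    msg <- NULL
    if (is.null(rownames(object@spectra)))
        msg <- c(msg, "spectra must have genome ids as row names")
    else if (anyDuplicated(rownames(object@spectra)))
        msg <- c(msg, "genome ids must be unique")
    if (ncol(object@spectra) != 4^object@dictionary@k)
        msg <- c(msg, "spectra must have 4^k columns")
    if (any(object@spectra < 0))
        msg <- c(msg, "spectra must be nonnegative")
    if (is.null(msg)) TRUE else msg
})

#' VirtualDesign: how virtual samples are fabricated from a library
#'
#' The four designs: `"single_clean"` (one clean library spectrum per
#' virtual sample), `"mixture_clean"` (a random positive-integer mixture of
#' the selected spectra), `"single_error"` (one error-bearing fragment
#' spectrum per virtual sample) and `"mixture_error"` (a mixture with
#' per-genome errors). Integer codes 1-4 map onto these in that order.
#'
#' @slot design one of the four design names.
#' @slot nVirtual number of virtual samples (NA = design default: one per
#'   selected genome for single designs, twice that for mixtures).
#' @slot mixtureRange integer range the mixture coefficients are drawn
#'   from, uniformly.
#' @slot includeProb probability a selected genome enters a mixture row.
#' @slot coverage fragment coverage f for the error designs.
#' @slot errorRate per-letter substitution rate for the error designs.
#' @seealso [virtualDesign()], [buildVirtualSamples()]
#' @export
setClass("VirtualDesign",
    representation(design = "character", nVirtual = "integer",
                   mixtureRange = "integer", includeProb = "numeric",
                   coverage = "numeric", errorRate = "numeric"))

setValidity("VirtualDesign", function(object) {
    msg <- NULL
    if (!object@design %in% c("single_clean", "mixture_clean",
                              "single_error", "mixture_error"))
        msg <- c(msg, "unknown design")
    if (length(object@mixtureRange) != 2L ||
        object@mixtureRange[1] < 1L ||
        object@mixtureRange[2] < object@mixtureRange[1])
        msg <- c(msg, "mixtureRange must be an increasing pair of positive integers")
    if (object@includeProb <= 0 || object@includeProb > 1)
        msg <- c(msg, "includeProb must be in (0, 1]")
    if (grepl("error", object@design)) {
        if (object@coverage <= 0 || object@coverage > 1)
            msg <- c(msg, "coverage must be in (0, 1]")
        if (object@errorRate < 0 || object@errorRate >= 1)
            msg <- c(msg, "errorRate must be in [0, 1)")
    }
    if (is.null(msg)) TRUE else msg
})
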