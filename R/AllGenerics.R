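#' Word length of a dictionary-bearing object
#' @param x a [KmerDictionary], [BarcodeSpectrum], [SampleSet],
#'   [FragmentSet] or [SpectraLibrary].
#' @return integer word length k.
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))

#' Ordered words of the dictionary underlying an object
#' @inheritParams kmerLength
#' @return character vector of the \eqn{4^k} words in storage order.
#' @export
setGeneric("kmerWords", function(x) standardGeneric("kmerWords"))

#' Dictionary of a spectra-bearing object
#' @inheritParams kmerLength
#' @return the [KmerDictionary].
#' @export
setGeneric("dictionary", function(x) standardGeneric("dictionary"))

#' Count vector / count matrix access
#'
#' `bsCounts` returns the count vector of a [BarcodeSpectrum];
#' `sampleCounts` returns the samples-by-words count matrix of a
#' [SampleSet] (with sample ids as row names and words as column names).
#' @inheritParams kmerLength
#' @return numeric vector or matrix of counts.
#' @export
setGeneric("bsCounts", function(x) standardGeneric("bsCounts"))

#' @rdname bsCounts
#' @export
setGeneric("sampleCounts", function(x) standardGeneric("sampleCounts"))

#' Sample identifiers of a SampleSet
#' @param x a [SampleSet].
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Identifier of the sequence a spectrum was computed from
#' @param x a [BarcodeSpectrum].
#' @return single string.
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' Number of samples held by an object
#' @param x a [SampleSet].
#' @return integer.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Generation provenance of a simulated object
#' @param x a [SampleSet].
#' @return list with elements `config` and `seed` (empty for real data).
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Estimated genome count and related accessors
#' @param x a [DimensionEstimate].
#' @return `genomeCount`: integer estimate; `peakIndex`: integer position
#'   of the second-derivative peak (NA on the exact path);
#'   `estimateMethod`: `"exact_rank"` or `"pca_marker"`; `markerCurves`:
#'   the [MarkerCurves] inspected, or NULL.
#' @export
setGeneric("genomeCount", function(x) standardGeneric("genomeCount"))

#' @rdname genomeCount
#' @export
setGeneric("peakIndex", function(x) standardGeneric("peakIndex"))

#' @rdname genomeCount
#' @export
setGeneric("estimateMethod", function(x) standardGeneric("estimateMethod"))

#' @rdname genomeCount
#' @export
setGeneric("markerCurves", function(x) standardGeneric("markerCurves"))
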