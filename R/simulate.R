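#' Generate a random synthetic genome
#'
#' Letters are i.i.d. uniform over \{A,C,G,T\}. Long random sequences have
#' 6-mer barcode spectra that are pairwise far from collinear, which makes
#' them usable stand-ins for real bacterial genomes in simulation studies
#' of the genome-count estimators. Lengths of tens of kilobases are
#' recommended; the package default elsewhere is 50 kb.
#'
#' @param length sequence length (positive integer).
#' @param id name given to the sequence.
#' @param seed optional integer seed for reproducibility.
#' @return a length-1 named [Biostrings::DNAStringSet].
#' @export
generateSyntheticGenome <- function(length, id = "synthetic_genome",
                                    seed = NULL) {
    if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
        length < 1)
        stop("length must be a positive integer", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    s <- paste(sample(DNA_BASES, as.integer(length), replace = TRUE),
               collapse = "")
    out <- Biostrings::DNAStringSet(s)
    names(out) <- id
    out
}

.CODONS <- sort(do.call(paste0,
    expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                stringsAsFactors = FALSE)[, 3:1]))

#' Generate a synthetic genome library with distinct compositional signatures
#'
#' Emulates a library of unrelated bacterial genomes. Each genome is a
#' sequence of i.i.d. codons drawn from a genome-specific random usage
#' distribution (lognormal weights over the 64 triplets, `usageSdlog`
#' controlling the skew). Codon-usage bias is the classic driver of
#' between-genome k-mer signatures; with the default strength the pairwise
#' angles between 6-mer barcode spectra of 50 kb genomes fall mostly in
#' 0.6-1.4 rad, the scale observed between unrelated real genomes, and the
#' spectra are far from collinear — the premise of the genome-count
#' estimators. `composition = "uniform"` instead draws every letter
#' i.i.d. uniform (all genomes then share one flat expected spectrum,
#' which is atypical of real libraries).
#'
#' @param n number of genomes.
#' @param length length of each genome.
#' @param prefix id prefix; genomes are named `prefix_1 ... prefix_n`.
#' @param composition `"signature"` (default; per-genome codon-usage bias)
#'   or `"uniform"`.
#' @param usageSdlog standard deviation of the log codon weights under
#'   `"signature"`.
#' @param seed optional integer seed.
#' @return a named [Biostrings::DNAStringSet] of length `n`.
#' @export
generateSyntheticGenomes <- function(n, length = 50000L, prefix = "genome",
                                     composition = c("signature", "uniform"),
                                     usageSdlog = 1, seed = NULL) {
    stopifnot(n >= 1, length >= 3)
    composition <- match.arg(composition)
    if (!is.null(seed)) set.seed(seed)
    length <- as.integer(length)
    seqs <- vapply(seq_len(n), function(i) {
        if (composition == "uniform") {
            paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
        } else {
            w <- exp(usageSdlog * rnorm(64L))
            s <- paste(sample(.CODONS, ceiling(length / 3), replace = TRUE,
                              prob = w / sum(w)), collapse = "")
            substr(s, 1L, length)
        }
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0(prefix, "_", seq_len(n))
    out
}

#' Introduce random letter-substitution errors
#'
#' Each position is independently replaced, with probability `rate`, by a
#' letter drawn uniformly from the three other bases — the substitution
#' model for sequencing errors (the reference setting is 1 letter in
#' 1000). Sequence length is preserved; no indels are introduced.
#'
#' @param sequence character string or [Biostrings::DNAString].
#' @param rate per-letter substitution probability in `[0, 1)`.
#' @return mutated sequence as a character string.
#' @export
mutateLetters <- function(sequence, rate) {
    if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
        rate < 0 || rate >= 1)
        stop("rate must be a single number in [0, 1)", call. = FALSE)
    s <- .asSequence(sequence)
    if (rate == 0) return(s)
    r <- charToRaw(s)
    idx <- which(runif(length(r)) < rate)
    if (length(idx) == 0L) return(s)
    bases <- charToRaw("ACGT")
    r[idx] <- vapply(r[idx], function(b) {
        alt <- bases[bases != b]
        alt[sample.int(length(alt), 1L)]
    }, raw(1), USE.NAMES = FALSE)
    rawToChar(r)
}

# One contiguous window of length flen at a uniform random start, genome
# treated as circular. flen >= L returns the genome unrotated so that
# coverage 1 reproduces the full-genome spectrum exactly.
.randomWindow <- function(s, flen) {
    L <- nchar(s)
    if (flen >= L) return(s)
    start <- sample.int(L, 1L)
    if (start + flen - 1L <= L) {
        substr(s, start, start + flen - 1L)
    } else {
        paste0(substr(s, start, L), substr(s, 1L, flen - (L - start) - 1L))
    }
}

#' Build the error-bearing fragment spectra G(g, f) of a genome
#'
#' Emulates data loss and sequencing error for one genome. Under
#' `"random_window"`, each of `nFragments` fragments is one contiguous
#' window of length `round(coverage * L)` starting at a uniform random
#' position (the genome is treated as circular); the reference settings
#' are twenty fragments at coverage 0.75 or 0.80. Under
#' `"partition_exclusion"` the genome is cut into 10 equal non-overlapping
#' parts and fragment i is the concatenation of the 9 parts excluding part
#' i (coverage 0.9, exactly 10 fragments, pairwise difference of 2 parts).
#' Every fragment is letter-mutated at `letterErrorRate` before its
#' spectrum is computed.
#'
#' @param genome a single sequence (character, [Biostrings::DNAString], or
#'   length-1 named [Biostrings::DNAStringSet]).
#' @param coverage fraction f of the genome per fragment, in (0, 1].
#' @param nFragments number of fragments (default 20).
#' @param scheme `"random_window"` or `"partition_exclusion"`.
#' @param letterErrorRate per-letter substitution probability (default
#'   0.001).
#' @param dictionary a [KmerDictionary].
#' @param genomeId identifier; defaults to the sequence name.
#' @return a [FragmentSet].
#' @export
makeFragmentSet <- function(genome, coverage = 0.75, nFragments = 20L,
                            scheme = c("random_window", "partition_exclusion"),
                            letterErrorRate = 0.001,
                            dictionary = buildDictionary(6L),
                            genomeId = NULL) {
    scheme <- match.arg(scheme)
    if (is.null(genomeId))
        genomeId <- if (is(genome, "DNAStringSet") && !is.null(names(genome)))
            names(genome)[1L] else "genome"
    s <- .asSequence(genome)
    L <- nchar(s)
    k <- dictionary@k
    if (!is.numeric(coverage) || coverage <= 0 || coverage > 1)
        stop("coverage must be in (0, 1]", call. = FALSE)
    if (scheme == "partition_exclusion") {
        if (abs(coverage - 0.9) > 1e-9 || nFragments != 10L)
            stop("partition_exclusion requires coverage = 0.9 and ",
                 "nFragments = 10", call. = FALSE)
        partLen <- L %/% 10L
        if (partLen * 9L < k)
            stop("genome too short for partition_exclusion", call. = FALSE)
        starts <- (0:9) * partLen + 1L
        parts <- substring(s, starts, starts + partLen - 1L)
        frags <- vapply(1:10, function(i)
            paste(parts[-i], collapse = ""), character(1))
    } else {
        flen <- round(coverage * L)
        if (flen < k)
            stop("fragment length (", flen, ") is shorter than k (", k, ")",
                 call. = FALSE)
        frags <- vapply(seq_len(nFragments), function(i)
            .randomWindow(s, flen), character(1))
    }
    if (letterErrorRate > 0)
        frags <- vapply(frags, mutateLetters, character(1),
                        rate = letterErrorRate, USE.NAMES = FALSE)
    spectra <- .bsMatrix(Biostrings::DNAStringSet(frags), k)
    new("FragmentSet", genomeId = as.character(genomeId),
        coverage = coverage, spectra = spectra, scheme = scheme,
        dictionary = dictionary)
}

#' @describeIn kmerLength word length of a fragment set's dictionary
#' @export
setMethod("kmerLength", "FragmentSet", function(x) x@dictionary@k)

#' @describeIn dictionary dictionary of a fragment set
#' @export
setMethod("dictionary", "FragmentSet", function(x) x@dictionary)

setMethod("show", "FragmentSet", function(object) {
    cat("FragmentSet G('", object@genomeId, "', ",
        round(100 * object@coverage), "%): ", nrow(object@spectra),
        " fragment spectra, scheme = ", object@scheme, "\n", sep = "")
})

#' Multiplicity model constructors
#'
#' `normalModel(m, sigma)` describes integer-rounded Normal(m, sigma) copy
#' numbers clipped below at zero. `discreteModel(valueSets, probs)`
#' describes independent draws from finite per-genome sets of nonnegative
#' integers, uniform unless `probs` is given.
#'
#' @param m mean copy number, positive.
#' @param sigma copy-number standard deviation, nonnegative.
#' @return a [MultiplicityModel].
#' @examples
#' normalModel(10, 3)
#' discreteModel(c(0, 1))          # each genome present or absent, p = 1/2
#' @export
normalModel <- function(m, sigma) {
    new("MultiplicityModel", kind = "normal", m = as.numeric(m),
        sigma = as.numeric(sigma), valueSets = list(), probs = list())
}

#' @rdname normalModel
#' @param valueSets a numeric vector (one set recycled over genomes) or a
#'   list of per-genome value sets.
#' @param probs optional probabilities: a vector matching a single value
#'   set, or a list matching `valueSets`.
#' @export
discreteModel <- function(valueSets, probs = NULL) {
    if (!is.list(valueSets)) valueSets <- list(as.numeric(valueSets))
    if (!is.null(probs) && !is.list(probs)) probs <- list(as.numeric(probs))
    new("MultiplicityModel", kind = "discrete", m = numeric(0),
        sigma = numeric(0), valueSets = valueSets,
        probs = if (is.null(probs)) list() else probs)
}

#' Draw a vector of genome multiplicities (VGM)
#'
#' One independent copy-number draw per genome, per sample. Entries are
#' mutually independent — the random fluctuation across samples that the
#' whole estimation approach relies on.
#'
#' @param model a [MultiplicityModel].
#' @param nGenomes number of genomes n.
#' @return integer vector of length `nGenomes`, nonnegative.
#' @export
drawMultiplicities <- function(model, nGenomes) {
    stopifnot(is(model, "MultiplicityModel"), nGenomes >= 1)
    validObject(model)
    n <- as.integer(nGenomes)
    if (model@kind == "normal") {
        as.integer(pmax(0, round(rnorm(n, model@m, model@sigma))))
    } else {
        sets <- model@valueSets
        prb <- model@probs
        if (length(sets) == 1L) sets <- rep(sets, n)
        if (length(sets) != n)
            stop("valueSets length must be 1 or nGenomes", call. = FALSE)
        if (length(prb) == 1L) prb <- rep(prb, n)
        vapply(seq_len(n), function(i) {
            vs <- sets[[i]]
            p <- if (length(prb)) prb[[i]] else NULL
            as.integer(vs[sample.int(length(vs), 1L, prob = p)])
        }, integer(1))
    }
}

# Internal fast path: one sample row from per-genome fragment spectra.
.synthRow <- function(spectraList, vgm) {
    out <- numeric(ncol(spectraList[[1L]]))
    for (g in seq_along(spectraList)) {
        t <- vgm[g]
        if (t > 0L) {
            sp <- spectraList[[g]]
            rows <- sample.int(nrow(sp), t, replace = TRUE)
            out <- out + colSums(sp[rows, , drop = FALSE])
        }
    }
    out
}

#' Synthesize one sample spectrum from fragment sets and a VGM
#'
#' If the sample contains t copies of genome g, then t fragment spectra
#' are drawn from G(g, f) uniformly, with replacement, independently of
#' each other, and all drawn spectra are summed. A zero multiplicity
#' contributes nothing.
#'
#' @param fragmentSets list of [FragmentSet], one per genome.
#' @param vgm integer vector of genome multiplicities, same length.
#' @param sourceId identifier for the resulting spectrum.
#' @return a [BarcodeSpectrum] for the sample.
#' @export
synthesizeSample <- function(fragmentSets, vgm, sourceId = "sample") {
    if (!is.list(fragmentSets) ||
        !all(vapply(fragmentSets, is, logical(1), "FragmentSet")))
        stop("fragmentSets must be a list of FragmentSet objects",
             call. = FALSE)
    if (length(vgm) != length(fragmentSets))
        stop("vgm length (", length(vgm),
             ") does not match the number of fragment sets (",
             length(fragmentSets), ")", call. = FALSE)
    if (anyNA(vgm) || any(vgm < 0) || any(vgm != round(vgm)))
        stop("vgm must be nonnegative integers", call. = FALSE)
    dict <- fragmentSets[[1L]]@dictionary
    counts <- .synthRow(lapply(fragmentSets, function(f) f@spectra),
                        as.integer(vgm))
    new("BarcodeSpectrum", counts = counts, dictionary = dict,
        sourceId = sourceId)
}

#' Simulate a full set of metagenome samples
#'
#' The end-to-end simulator: builds the fragment-spectra set G(g, f) for
#' every genome once, then draws `nSamples` independent samples, each with
#' its own vector of genome multiplicities. The reference study
#' conditions are 50 kb genomes, Normal(10, 3) multiplicities, coverage
#' 0.75 with 20 fragments per genome, and a 0.001 letter-error rate.
#'
#' @param genomes a named [Biostrings::DNAStringSet] of genome sequences
#'   (e.g. from [readFasta()] or [generateSyntheticGenomes()]).
#' @param model a [MultiplicityModel].
#' @param nSamples number of samples N to draw.
#' @param coverage fragment coverage f in (0, 1].
#' @param nFragments fragments per genome.
#' @param scheme fragment scheme, see [makeFragmentSet()].
#' @param letterErrorRate per-letter substitution probability.
#' @param k word length (default 6).
#' @param seed optional integer seed; recorded in the provenance.
#' @return a [SampleSet] whose provenance records the full configuration.
#' @export
generateSampleSet <- function(genomes, model, nSamples, coverage = 0.75,
                              nFragments = 20L, scheme = "random_window",
                              letterErrorRate = 0.001, k = 6L,
                              seed = NULL) {
    stopifnot(is(model, "MultiplicityModel"), nSamples >= 1)
    if (!is.null(seed)) set.seed(seed)
    if (is.null(names(genomes)))
        names(genomes) <- paste0("genome_", seq_along(genomes))
    dict <- buildDictionary(k)
    fragmentSets <- lapply(seq_along(genomes), function(i)
        makeFragmentSet(genomes[i], coverage = coverage,
                        nFragments = nFragments, scheme = scheme,
                        letterErrorRate = letterErrorRate,
                        dictionary = dict, genomeId = names(genomes)[i]))
    spectraList <- lapply(fragmentSets, function(f) f@spectra)
    nG <- length(genomes)
    m <- matrix(0, nrow = nSamples, ncol = 4^k)
    for (i in seq_len(nSamples))
        m[i, ] <- .synthRow(spectraList, drawMultiplicities(model, nG))
    SampleSet(m, dict,
        sampleIds = paste0("sample_", seq_len(nSamples)),
        provenance = list(
            config = list(
                nGenomes = nG, genomeIds = names(genomes),
                model = model, coverage = coverage,
                nFragments = nFragments, scheme = scheme,
                letterErrorRate = letterErrorRate, k = k,
                nSamples = nSamples),
            seed = seed))
}
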