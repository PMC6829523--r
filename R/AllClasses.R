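#' Simulation configuration for the synthetic ISR fixture
#'
#' `SimConfig` bundles every parameter of the synthetic-data generator: the
#' study layout (three treatment conditions, three replicate libraries each),
#' genome and locus sizing, sequencing depth, the identity and strength of the
#' treatment-specific miRNA repression, the read-length distribution and the
#' degradome signal model.  A fixed `seed` makes every downstream file
#' byte-identical between runs.
#'
#' The default read-length distribution places 88% of its mass on 20--24 nt
#' with a 24-nt mode, matching the hallmark length profile of plant small RNA
#' libraries; the generator enforces that any user-supplied distribution keeps
#' more than 75% of its mass in 20--24 nt, since that property is a documented
#' contract of the fixtures.
#'
#' @slot seed integer RNG seed.
#' @slot genomeLength chromosome length in bp (single synthetic chromosome).
#' @slot nKnownMirnas,nNovelMirnas number of known / novel miRNA loci.
#' @slot nTranscripts number of transcriptome entries.
#' @slot nLibrariesPerCondition replicate libraries per condition.
#' @slot conditions condition labels; the first label is the ISR-inducing
#'   treatment in which `repressedSet` is repressed.
#' @slot depthPerLibrary reads per library.
#' @slot repressedSet names of known miRNAs repressed only in the first
#'   condition.
#' @slot repressionFactor fold reduction of the repressed means.
#' @slot lengthDist named numeric, read length -> probability.
#' @slot dispersion negative-binomial dispersion of per-miRNA counts
#'   (0 gives Poisson counts).
#' @slot adapter3 3' adapter sequence appended to every simulated read.
#' @slot backgroundFraction fraction of depth drawn as random genomic
#'   fragments (true negatives for cleaning and matching).
#' @slot readLength raw read length written to FASTQ.
#' @slot degradomeSignal expected degradome tag count at a true cleavage site.
#' @slot degradomeNoiseRate expected background tags per transcript position.
#'
#' @seealso [simConfig()], [makeGenome()], [writeFixture()]
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    genomeLength = "numeric",
    nKnownMirnas = "integer",
    nNovelMirnas = "integer",
    nTranscripts = "integer",
    nLibrariesPerCondition = "integer",
    conditions = "character",
    depthPerLibrary = "numeric",
    repressedSet = "character",
    repressionFactor = "numeric",
    lengthDist = "numeric",
    dispersion = "numeric",
    adapter3 = "character",
    backgroundFraction = "numeric",
    readLength = "integer",
    degradomeSignal = "numeric",
    degradomeNoiseRate = "numeric"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed must be a single integer")
    if (object@genomeLength < 5e4)
        msg <- c(msg, "genomeLength must be at least 50 kb")
    if (abs(sum(object@lengthDist) - 1) > 1e-6)
        msg <- c(msg, "lengthDist probabilities must sum to 1")
    lens <- suppressWarnings(as.integer(names(object@lengthDist)))
    if (anyNA(lens))
        msg <- c(msg, "lengthDist must be named by integer read lengths")
    else if (sum(object@lengthDist[lens >= 20 & lens <= 24]) <= 0.75)
        msg <- c(msg, "lengthDist must put > 0.75 mass on 20-24 nt")
    if (object@repressionFactor < 1)
        msg <- c(msg, "repressionFactor must be >= 1")
    if (length(object@conditions) < 2 || anyDuplicated(object@conditions))
        msg <- c(msg, "conditions must be >= 2 distinct labels")
    if (object@depthPerLibrary <= 0)
        msg <- c(msg, "depthPerLibrary must be positive")
    if (object@backgroundFraction < 0 || object@backgroundFraction >= 1)
        msg <- c(msg, "backgroundFraction must be in [0, 1)")
    if (nchar(object@adapter3) < 6)
        msg <- c(msg, "adapter3 must be at least 6 nt")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' The defaults define the reference fixture used throughout the package:
#' three conditions (`FZB42`, `mutant`, `control`) with three libraries each,
#' 50 known and 8 novel miRNA loci, 1e5 reads per library of which 10% are
#' random genomic background, four known miRNAs repressed 4-fold in the
#' `FZB42` condition only, and a degradome with a strong tag pile-up
#' (expected 50 tags) at each true cleavage site over sparse positional
#' noise.
#'
#' @param seed integer seed.
#' @param genomeLength,nKnownMirnas,nNovelMirnas,nTranscripts see slots.
#' @param nLibrariesPerCondition,conditions,depthPerLibrary see slots.
#' @param repressedSet,repressionFactor,lengthDist,dispersion see slots.
#' @param adapter3,backgroundFraction,readLength see slots.
#' @param degradomeSignal,degradomeNoiseRate see slots.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      genomeLength = 3e5,
                      nKnownMirnas = 50L,
                      nNovelMirnas = 8L,
                      nTranscripts = 60L,
                      nLibrariesPerCondition = 3L,
                      conditions = c("FZB42", "mutant", "control"),
                      depthPerLibrary = 1e5,
                      repressedSet = c("zma-miR169a-5p", "zma-miR169c-5p",
                                       "zma-miR169i-5p", "zma-miR395b-5p"),
                      repressionFactor = 4,
                      lengthDist = c(`18` = 0.01, `19` = 0.02, `20` = 0.08,
                                     `21` = 0.20, `22` = 0.16, `23` = 0.10,
                                     `24` = 0.34, `25` = 0.05, `26` = 0.02,
                                     `27` = 0.02),
                      dispersion = 0.1,
                      adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                      backgroundFraction = 0.1,
                      readLength = 36L,
                      degradomeSignal = 50,
                      degradomeNoiseRate = 0.01) {
    new("SimConfig",
        seed = as.integer(seed), genomeLength = genomeLength,
        nKnownMirnas = as.integer(nKnownMirnas),
        nNovelMirnas = as.integer(nNovelMirnas),
        nTranscripts = as.integer(nTranscripts),
        nLibrariesPerCondition = as.integer(nLibrariesPerCondition),
        conditions = conditions, depthPerLibrary = depthPerLibrary,
        repressedSet = repressedSet, repressionFactor = repressionFactor,
        lengthDist = lengthDist, dispersion = dispersion, adapter3 = adapter3,
        backgroundFraction = backgroundFraction,
        readLength = as.integer(readLength),
        degradomeSignal = degradomeSignal,
        degradomeNoiseRate = degradomeNoiseRate)
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig (seed ", object@seed, ")\n", sep = "")
    cat("  genome: ", object@genomeLength, " bp; ",
        object@nKnownMirnas, " known + ", object@nNovelMirnas,
        " novel miRNA loci; ", object@nTranscripts, " transcripts\n", sep = "")
    cat("  libraries: ", paste(object@conditions, collapse = ", "), " x ",
        object@nLibrariesPerCondition, " replicates, ",
        format(object@depthPerLibrary, scientific = FALSE),
        " reads each\n", sep = "")
    cat("  repressed in ", object@conditions[1], ": ",
        paste(object@repressedSet, collapse = ", "),
        " (", object@repressionFactor, "-fold)\n", sep = "")
})

#' Planted ground truth of a synthetic fixture
#'
#' Records what the generator planted so tests can compare pipeline output
#' against it: the repressed miRNA names, the true (miRNA, transcript,
#' cleavage position) targets, the promoter cis-elements written into the
#' genome, and the genomic intervals of the novel miRNA loci.
#'
#' @slot repressedMirnas character vector of repressed known miRNA names.
#' @slot trueTargets data.frame with columns `mirna`, `transcript`,
#'   `cleavagePos` (1-based transcript coordinate of the degradome 5' end).
#' @slot plantedMotifs data.frame with columns `pri`, `motif`, `strand`,
#'   `offset` (1-based offset within the oriented promoter sequence).
#' @slot novelLoci [GenomicRanges::GRanges] of novel precursor loci.
#' @export
setClass("SyntheticTruth", representation(
    repressedMirnas = "character",
    trueTargets = "data.frame",
    plantedMotifs = "data.frame",
    novelLoci = "GRanges"
))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (!all(c("mirna", "transcript", "cleavagePos") %in%
             names(object@trueTargets)))
        msg <- c(msg, "trueTargets needs mirna/transcript/cleavagePos columns")
    if (!all(c("pri", "motif", "strand", "offset") %in%
             names(object@plantedMotifs)))
        msg <- c(msg, "plantedMotifs needs pri/motif/strand/offset columns")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@repressedMirnas),
        "repressed miRNAs,", nrow(object@trueTargets), "true targets,",
        nrow(object@plantedMotifs), "planted motifs,",
        length(object@novelLoci), "novel loci\n")
})

#' A complete in-memory synthetic fixture
#'
#' Produced by [makeGenome()]; holds the genome, annotation, miRNA locus
#' table, reference mature sequences, transcriptome, GO annotation and the
#' planted [SyntheticTruth-class].
#'
#' @slot config the generating [SimConfig-class].
#' @slot genome single-chromosome [Biostrings::DNAStringSet].
#' @slot annotation [GenomicRanges::GRanges] with gene,
#'   miRNA_primary_transcript and miRNA features.
#' @slot mirnas per-locus [S4Vectors::DataFrame] (name, family, arm, mature,
#'   star, precursor locus, baseline abundance, ...).
#' @slot matureKnown named [Biostrings::DNAStringSet] of known matures
#'   (the miRBase-style reference).
#' @slot transcripts named [Biostrings::DNAStringSet] transcriptome.
#' @slot goAnnotation data.frame gene/term/name/namespace.
#' @slot truth the planted [SyntheticTruth-class].
#' @export
setClass("SyntheticFixture", representation(
    config = "SimConfig",
    genome = "DNAStringSet",
    annotation = "GRanges",
    mirnas = "DFrame",
    matureKnown = "DNAStringSet",
    transcripts = "DNAStringSet",
    goAnnotation = "data.frame",
    truth = "SyntheticTruth"
))

setMethod("show", "SyntheticFixture", function(object) {
    cat("SyntheticFixture: genome", sum(Biostrings::width(object@genome)),
        "bp;",
        nrow(object@mirnas), "miRNA loci (",
        sum(object@mirnas$known), "known /", sum(!object@mirnas$known),
        "novel );", length(object@transcripts), "transcripts\n")
    show(object@truth)
})

#' @rdname SyntheticFixture-class
#' @param x a `SyntheticFixture`.
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname SyntheticFixture-class
#' @export
setMethod("truth", "SyntheticFixture", function(x) x@truth)

#' @rdname SyntheticFixture-class
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname SyntheticFixture-class
#' @export
setMethod("genomeSequence", "SyntheticFixture", function(x) x@genome)

#' @rdname SyntheticFixture-class
#' @export
setGeneric("annotationRanges", function(x) standardGeneric("annotationRanges"))
#' @rdname SyntheticFixture-class
#' @export
setMethod("annotationRanges", "SyntheticFixture", function(x) x@annotation)

#' @rdname SyntheticFixture-class
#' @export
setGeneric("mirnaTable", function(x) standardGeneric("mirnaTable"))
#' @rdname SyntheticFixture-class
#' @export
setMethod("mirnaTable", "SyntheticFixture", function(x) x@mirnas)

#' @rdname SyntheticFixture-class
#' @export
setGeneric("matureSequences", function(x) standardGeneric("matureSequences"))
#' @rdname SyntheticFixture-class
#' @export
setMethod("matureSequences", "SyntheticFixture", function(x) x@matureKnown)

#' @rdname SyntheticFixture-class
#' @export
setGeneric("transcriptSequences",
           function(x) standardGeneric("transcriptSequences"))
#' @rdname SyntheticFixture-class
#' @export
setMethod("transcriptSequences", "SyntheticFixture",
          function(x) x@transcripts)

#' @rdname SyntheticFixture-class
#' @export
setGeneric("goTable", function(x) standardGeneric("goTable"))
#' @rdname SyntheticFixture-class
#' @export
setMethod("goTable", "SyntheticFixture", function(x) x@goAnnotation)

#' @rdname SyntheticFixture-class
#' @export
setGeneric("simConfigOf", function(x) standardGeneric("simConfigOf"))
#' @rdname SyntheticFixture-class
#' @export
setMethod("simConfigOf", "SyntheticFixture", function(x) x@config)
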