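# Promoter extraction by orientation/distance rules and cis-element
# scanning.

#' Extract a pri-miRNA promoter region
#'
#' Implements the three-branch rule for pri-miRNA promoters, with the
#' intergenic gap between the pri-miRNA 5' end and the nearest boundary of
#' the upstream gene as the distance:
#'
#' * `same_dir_near` - same transcription direction, gap < `sameNearMax`
#'   (2.4 kb): the region from `downstreamShift` (400 bp) past the upstream
#'   gene's 3' end to the pri-miRNA 5' end (length = gap - 400).
#' * `opposite_far` - opposite direction, gap > `oppositeFarMin` (4 kb):
#'   from the pri-miRNA 5' end back to the midpoint of the gap.
#' * `default_2kb` - every other geometry (including an absent upstream
#'   gene, and opposite-direction gaps of 2.4--4 kb, which the rule set
#'   leaves to the fallback): `defaultLength` (2 kb) upstream of the
#'   pri-miRNA 5' end, clipped at the chromosome edge (`clipped` flag).
#'
#' Degenerate geometries (overlapping loci, or a near-gene gap of at most
#' 400 bp that would make the first branch empty) fall back to the default
#' branch with a warning.
#'
#' @param pri length-1 `GRanges` of the pri-miRNA locus (strand required).
#' @param upstreamGene length-1 `GRanges` of the upstream gene, or `NULL`.
#' @param chromLength chromosome length for edge clipping.
#' @param sameNearMax,downstreamShift,oppositeFarMin,defaultLength rule
#'   thresholds in bp.
#' @return length-1 `GRanges` (strand = pri strand) with metadata columns
#'   `branch`, `clipped`, `gap`, `orientation`.
#' @examples
#' library(GenomicRanges)
#' pri <- GRanges("chr1", IRanges(10000, 10150), strand = "+")
#' gene <- GRanges("chr1", IRanges(8000, 8999), strand = "+")
#' extractPromoter(pri, gene, chromLength = 50000)  # gap 1000 -> 600 bp
#' @export
extractPromoter <- function(pri, upstreamGene = NULL, chromLength,
                            sameNearMax = 2400L, downstreamShift = 400L,
                            oppositeFarMin = 4000L, defaultLength = 2000L) {
    stopifnot(is(pri, "GRanges"), length(pri) == 1L)
    priStrand <- as.character(strand(pri))
    if (!priStrand %in% c("+", "-"))
        stop("pri-miRNA strand must be + or -")
    pri5 <- if (priStrand == "+") start(pri) else end(pri)
    chrom <- as.character(seqnames(pri))

    fallback <- function(clippedWarn = NULL) {
        if (!is.null(clippedWarn)) warning(clippedWarn, call. = FALSE)
        if (priStrand == "+") {
            s <- pri5 - defaultLength
            clip <- s < 1L
            gr <- GRanges(chrom, IRanges(max(1L, s), pri5 - 1L),
                          strand = priStrand)
        } else {
            e <- pri5 + defaultLength
            clip <- e > chromLength
            gr <- GRanges(chrom, IRanges(pri5 + 1L, min(chromLength, e)),
                          strand = priStrand)
        }
        mcols(gr) <- DataFrame(branch = "default_2kb", clipped = clip,
                               gap = NA_integer_,
                               orientation = NA_character_)
        gr
    }

    if (is.null(upstreamGene)) return(fallback())
    stopifnot(is(upstreamGene, "GRanges"), length(upstreamGene) == 1L)
    if (as.character(seqnames(upstreamGene)) != chrom)
        stop("pri-miRNA and upstream gene must be on the same chromosome")
    geneStrand <- as.character(strand(upstreamGene))
    orientation <- if (geneStrand == priStrand) "same" else "opposite"

    gap <- if (priStrand == "+") start(pri) - end(upstreamGene) - 1L
           else start(upstreamGene) - end(pri) - 1L
    if (gap < 0L)
        return(fallback("pri-miRNA and upstream gene overlap; using the default 2 kb branch"))

    decorate <- function(gr, branch, clipped = FALSE) {
        mcols(gr) <- DataFrame(branch = branch, clipped = clipped,
                               gap = gap, orientation = orientation)
        gr
    }

    if (orientation == "same" && gap < sameNearMax) {
        if (gap <= downstreamShift)
            return(fallback(paste0(
                "gap (", gap, " bp) within the ", downstreamShift,
                " bp downstream shift; using the default 2 kb branch")))
        gr <- if (priStrand == "+")
            GRanges(chrom, IRanges(end(upstreamGene) + downstreamShift + 1L,
                                   pri5 - 1L), strand = priStrand)
        else
            GRanges(chrom, IRanges(pri5 + 1L,
                                   start(upstreamGene) - downstreamShift - 1L),
                    strand = priStrand)
        return(decorate(gr, "same_dir_near"))
    }
    if (orientation == "opposite" && gap > oppositeFarMin) {
        half <- gap %/% 2L
        gr <- if (priStrand == "+")
            GRanges(chrom, IRanges(pri5 - half, pri5 - 1L),
                    strand = priStrand)
        else
            GRanges(chrom, IRanges(pri5 + 1L, pri5 + half),
                    strand = priStrand)
        return(decorate(gr, "opposite_far"))
    }
    gr <- fallback()
    mcols(gr)$gap <- gap
    mcols(gr)$orientation <- orientation
    gr
}

#' Default defense-related cis-element library
#'
#' Reads the editable motif table shipped with the package: consensus
#' strings for the TCA element (salicylic acid responsiveness), the CGTCA
#' motif (methyl jasmonate responsiveness) and TC-rich repeats
#' (defense/stress responsiveness).  These defaults are configuration:
#' replace or extend the table for other element catalogues.
#'
#' @param path TSV with columns `name`, `sequence`, `category`.
#' @return data.frame motif library.
#' @export
defaultMotifLibrary <- function(path = system.file("extdata",
                                                   "motifs_plantcare.tsv",
                                                   package = "mirISR")) {
    read.delim(path, stringsAsFactors = FALSE)
}

#' Scan promoter sequences for cis-element motifs on both strands
#'
#' Motifs are literal nucleotide strings with IUPAC degeneracy; all exact
#' (IUPAC-aware) occurrences are reported, including overlapping ones.
#' Minus-strand hits are found by matching the reverse complement of the
#' motif and reported at forward-strand (promoter sense) offsets.
#'
#' @param promoters named `DNAStringSet` (or named character vector) of
#'   promoter sequences, oriented 5'->3' on the pri-miRNA sense strand.
#' @param motifs motif library data.frame (`name`, `sequence`); see
#'   [defaultMotifLibrary()].
#' @return data.frame with columns `promoter`, `motif`, `strand`, `offset`
#'   (1-based start within the promoter), `matched` (promoter-sense
#'   sequence at the hit).
#' @examples
#' scanMotifs(c(p1 = "AAAACGTCAAAA"),
#'            data.frame(name = "CGTCA-motif", sequence = "CGTCA"))
#' @export
scanMotifs <- function(promoters, motifs) {
    if (nrow(motifs) == 0L) stop("motif library is empty")
    bad <- vapply(strsplit(toupper(motifs$sequence), ""), function(ch)
        any(!ch %in% .IUPAC), TRUE)
    if (any(bad))
        stop("motif contains non-IUPAC characters: ",
             paste(motifs$name[bad], collapse = ", "))
    proms <- if (is(promoters, "DNAStringSet")) promoters
             else DNAStringSet(.normalizeSeq(promoters))
    if (is.null(names(proms)))
        names(proms) <- paste0("promoter_", seq_along(proms))
    out <- list()
    for (k in seq_len(nrow(motifs))) {
        pat <- DNAString(.normalizeSeq(motifs$sequence[k]))
        for (i in seq_along(proms)) {
            hp <- matchPattern(pat, proms[[i]], fixed = "subject")
            if (length(hp))
                out[[length(out) + 1L]] <- data.frame(
                    promoter = names(proms)[i], motif = motifs$name[k],
                    strand = "+", offset = start(hp),
                    matched = as.character(hp))
            hm <- matchPattern(reverseComplement(pat), proms[[i]],
                               fixed = "subject")
            if (length(hm))
                out[[length(out) + 1L]] <- data.frame(
                    promoter = names(proms)[i], motif = motifs$name[k],
                    strand = "-", offset = start(hm),
                    matched = as.character(hm))
        }
    }
    if (!length(out))
        return(data.frame(promoter = character(), motif = character(),
                          strand = character(), offset = integer(),
                          matched = character()))
    res <- do.call(rbind, out)
    res[order(res$promoter, res$offset, res$motif, res$strand), ,
        drop = FALSE]
}

#' Summarise defense-related cis-elements per promoter
#'
#' Collapses motif hits to per-promoter booleans and counts for the three
#' defense-response categories (SA, MeJA, defense/stress), flagging
#' promoters that carry all three.
#'
#' @param hits [scanMotifs()] output.
#' @param motifs motif library with a `category` column mapping motif names
#'   to element categories.
#' @param promoterIds promoters to report (zero-hit promoters included);
#'   defaults to those present in `hits`.
#' @return data.frame with one row per promoter: per-category counts,
#'   `hasSA`, `hasMeJA`, `hasDefenseStress`, `anyDefenseElement`,
#'   `allThree`.
#' @export
classifyDefenseElements <- function(hits, motifs = defaultMotifLibrary(),
                                    promoterIds = unique(hits$promoter)) {
    catOf <- setNames(motifs$category, motifs$name)
    cats <- c("SA", "MeJA", "defense-stress")
    rows <- lapply(promoterIds, function(p) {
        h <- hits[hits$promoter == p, , drop = FALSE]
        cnt <- vapply(cats, function(cc)
            sum(catOf[h$motif] == cc, na.rm = TRUE), 0L)
        data.frame(promoter = p, nSA = cnt[1], nMeJA = cnt[2],
                   nDefenseStress = cnt[3],
                   hasSA = cnt[1] > 0, hasMeJA = cnt[2] > 0,
                   hasDefenseStress = cnt[3] > 0,
                   anyDefenseElement = any(cnt > 0),
                   allThree = all(cnt > 0))
    })
    res <- do.call(rbind, rows)
    if (is.null(res))
        res <- data.frame(promoter = character(), nSA = integer(),
                          nMeJA = integer(), nDefenseStress = integer(),
                          hasSA = logical(), hasMeJA = logical(),
                          hasDefenseStress = logical(),
                          anyDefenseElement = logical(),
                          allThree = logical())
    rownames(res) <- NULL
    res
}
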