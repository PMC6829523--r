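# Synthetic fixture generation with planted ground truth.
#
# The generator emulates the study design this package targets: nine small
# RNA libraries (3 conditions x 3 replicates) in which a chosen subset of
# known miRNAs is repressed only in the ISR-inducing treatment, a
# single-chromosome genome carrying hairpin miRNA loci whose upstream genes
# are laid out to exercise every promoter-extraction rule, a transcriptome
# with embedded miRNA target sites, and per-condition degradome tag pools
# with Poisson pile-ups at the true cleavage sites over positional noise.

# miRBase-style name generation; the repressed set is always included.
.mirnaNames <- function(n, repressedSet) {
    fams <- c(156L, 159L, 160L, 164L, 166L, 167L, 168L, 169L, 171L, 319L,
              390L, 393L, 394L, 395L, 396L, 398L, 399L, 408L, 482L, 528L)
    out <- repressedSet
    fi <- 0L
    letterOf <- integer(length(fams))
    while (length(out) < n) {
        fi <- fi %% length(fams) + 1L
        letterOf[fi] <- letterOf[fi] + 1L
        if (letterOf[fi] > 26L) next
        base <- paste0("zma-miR", fams[fi], letters[letterOf[fi]])
        nm <- if (length(out) %% 7L == 6L) base else paste0(base, "-5p")
        if (!nm %in% out && !base %in% sub("-[35]p$", "", out))
            out <- c(out, nm)
    }
    out[seq_len(n)]
}

# one hairpin precursor: 5' flank | mature | loop | revcomp(mature) | 3' flank
.makePrecursor <- function(mature) {
    f5 <- sample(4:80, 1L)
    loop <- sample(12:40, 1L)
    f3 <- sample(2:60, 1L)
    prec <- paste0(.randDNA(f5), mature, .randDNA(loop),
                   .revcomp(mature), .randDNA(f3))
    m <- nchar(mature)
    # star with 2-nt 3' overhangs relative to the mature duplex
    starStart <- f5 + m + loop + 3L
    starEnd <- f5 + loop + 2L * m + 2L
    list(seq = prec, matOffset = f5 + 1L, len = nchar(prec),
         star = substr(prec, starStart, starEnd))
}

# disrupt incidental occurrences of the motif set inside a promoter so that
# planted motifs are the only hits at noise-free settings
.scrubPromoter <- function(genomeStr, prom, motifs) {
    pstrand <- as.character(strand(prom))
    for (iter in 1:10) {
        seqF <- substr(genomeStr, start(prom), end(prom))
        oriented <- if (pstrand == "-") .revcomp(seqF) else seqF
        subj <- DNAString(oriented)
        hitMid <- integer(0)
        for (m in motifs$sequence) {
            for (pat in c(m, .revcomp(m))) {
                mt <- matchPattern(DNAString(pat), subj,
                                   fixed = "subject")
                if (length(mt))
                    hitMid <- c(hitMid, start(mt) + nchar(pat) %/% 2L)
            }
        }
        if (!length(hitMid)) break
        for (off in unique(hitMid)) {
            gpos <- if (pstrand == "-") end(prom) - off + 1L
                    else start(prom) + off - 1L
            old <- substr(genomeStr, gpos, gpos)
            subst <- c(A = "C", C = "A", G = "T", T = "G")[[old]]
            genomeStr <- .writeSeq(genomeStr, gpos, subst)
        }
    }
    genomeStr
}

.plantMotif <- function(genomeStr, prom, offset, motif, motifStrand) {
    oriented <- if (motifStrand == "-") .revcomp(motif) else motif
    pstrand <- as.character(strand(prom))
    if (pstrand == "+") {
        .writeSeq(genomeStr, start(prom) + offset - 1L, oriented)
    } else {
        gstart <- end(prom) - offset - nchar(oriented) + 2L
        .writeSeq(genomeStr, gstart, .revcomp(oriented))
    }
}

#' Generate the synthetic genome, annotation and truth
#'
#' Builds a single synthetic chromosome carrying hairpin miRNA precursors
#' (known and novel) embedded as inverted repeats, upstream genes laid out to
#' exercise every promoter-rule branch, a transcriptome with embedded target
#' sites for the repressed miRNAs, a flat GO annotation in which one term
#' tags exactly the true target set, and planted promoter cis-elements.
#' Incidental occurrences of the motif library inside promoter regions are
#' disrupted so planted motifs are the only hits.
#'
#' Precursor lengths are drawn in 60--244 nt, inside the 58--247 nt range
#' reported for plant pri-miRNA hairpins.
#'
#' @param config a [SimConfig-class].
#' @param motifLibrary motif table used for planting; see
#'   [defaultMotifLibrary()].
#' @return a [SyntheticFixture-class].
#' @examples
#' fx <- makeGenome(simConfig(seed = 1, genomeLength = 1e5,
#'                            nKnownMirnas = 10, nNovelMirnas = 2,
#'                            nTranscripts = 15))
#' fx
#' @export
makeGenome <- function(config, motifLibrary = defaultMotifLibrary()) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    nK <- config@nKnownMirnas
    nN <- config@nNovelMirnas
    n <- nK + nN
    knownNames <- .mirnaNames(nK, config@repressedSet)
    novelNames <- paste0("novel_mir_", seq_len(nN))
    allNames <- c(knownNames, novelNames)

    # distinct mature sequences
    matures <- character(n)
    seen <- character(0)
    for (i in seq_len(n)) {
        repeat {
            m <- .randDNA(22L)
            if (!m %in% seen) break
        }
        matures[i] <- m
        seen <- c(seen, m)
    }

    prec <- lapply(matures, .makePrecursor)

    # locus layout along the chromosome; geometry cases cycle so that every
    # promoter-rule branch occurs: (1) same direction, gap 1 kb -> between
    # rule; (2) same direction, gap 3 kb -> default 2 kb; (3) opposite, gap
    # 5 kb -> midpoint rule; (4) opposite, gap 1 kb and (5) opposite, gap
    # 3 kb -> default 2 kb; (6) no upstream gene -> default 2 kb.
    caseGap <- c(1000L, 3000L, 5000L, 1000L, 3000L, NA)
    caseSame <- c(TRUE, TRUE, FALSE, FALSE, FALSE, NA)
    cursor <- 1L
    loc <- vector("list", n)
    for (i in seq_len(n)) {
        cs <- (i - 1L) %% 6L + 1L
        gap <- caseGap[cs]
        priStrand <- if (i %% 5L == 0L) "-" else "+"
        geneLen <- sample(400:1500, 1L)
        pl <- prec[[i]]$len
        if (cs == 6L) {
            if (priStrand == "+") {
                priStart <- cursor + 2200L
                priEnd <- priStart + pl - 1L
                cursor <- priEnd + 300L
            } else {
                priStart <- cursor + 300L
                priEnd <- priStart + pl - 1L
                cursor <- priEnd + 2200L
            }
            loc[[i]] <- list(case = cs, priStart = priStart, priEnd = priEnd,
                             priStrand = priStrand, geneStart = NA_integer_,
                             geneEnd = NA_integer_, geneStrand = NA_character_)
            next
        }
        sameDir <- caseSame[cs]
        pad <- max(400L, 2200L - gap - geneLen)
        if (priStrand == "+") {
            geneStart <- cursor + pad
            geneEnd <- geneStart + geneLen - 1L
            priStart <- geneEnd + gap + 1L
            priEnd <- priStart + pl - 1L
            geneStrand <- if (sameDir) "+" else "-"
            cursor <- priEnd + 300L
        } else {
            priStart <- cursor + 300L
            priEnd <- priStart + pl - 1L
            geneStart <- priEnd + gap + 1L
            geneEnd <- geneStart + geneLen - 1L
            geneStrand <- if (sameDir) "-" else "+"
            cursor <- geneEnd + pad
        }
        loc[[i]] <- list(case = cs, priStart = priStart, priEnd = priEnd,
                         priStrand = priStrand, geneStart = geneStart,
                         geneEnd = geneEnd, geneStrand = geneStrand)
    }
    if (cursor + 1000L > config@genomeLength)
        stop("genomeLength (", config@genomeLength,
             ") too small to place ", n, " miRNA loci (needs >= ",
             cursor + 1000L, " bp)")

    genomeStr <- .randDNA(config@genomeLength)
    for (i in seq_len(n)) {
        s <- prec[[i]]$seq
        if (loc[[i]]$priStrand == "-") s <- .revcomp(s)
        genomeStr <- .writeSeq(genomeStr, loc[[i]]$priStart, s)
    }

    priIds <- paste0("pri-", sub("-[35]p$", "", allNames))
    priGR <- GRanges("chr1",
                     IRanges(vapply(loc, `[[`, 1L, "priStart"),
                             vapply(loc, `[[`, 1L, "priEnd")),
                     strand = vapply(loc, `[[`, "", "priStrand"))
    names(priGR) <- priIds

    # promoters under the same rules the analysis applies, for motif work
    promoters <- vector("list", n)
    for (i in seq_len(n)) {
        up <- if (loc[[i]]$case == 6L) NULL else
            GRanges("chr1", IRanges(loc[[i]]$geneStart, loc[[i]]$geneEnd),
                    strand = loc[[i]]$geneStrand)
        promoters[[i]] <- extractPromoter(priGR[i], up,
                                          chromLength = config@genomeLength)
    }

    for (i in seq_len(n))
        genomeStr <- .scrubPromoter(genomeStr, promoters[[i]], motifLibrary)

    # plant cis-elements: candidates 1 and 3 get all three element types
    # (the two-miR169 pattern), the other repressed candidates two, and
    # every fourth remaining known locus one
    planted <- list()
    motSeq <- setNames(motifLibrary$sequence, motifLibrary$name)
    repIdx <- match(config@repressedSet, allNames)
    for (r in seq_along(repIdx)) {
        i <- repIdx[r]
        if (is.na(i)) next
        if (r %in% c(1L, 3L)) {
            sel <- seq_len(nrow(motifLibrary))
            offs <- c(50L, 120L, 200L)
            strs <- c("+", "-", "+")
        } else {
            sel <- 1:2
            offs <- c(60L, 140L)
            strs <- c("+", "-")
        }
        for (k in seq_along(sel)) {
            nmotif <- motifLibrary$name[sel[k]]
            genomeStr <- .plantMotif(genomeStr, promoters[[i]], offs[k],
                                     motSeq[[nmotif]], strs[k])
            planted[[length(planted) + 1L]] <-
                data.frame(pri = priIds[i], motif = nmotif,
                           strand = strs[k], offset = offs[k])
        }
    }
    others <- setdiff(seq_len(nK), repIdx)
    for (j in seq_along(others)) {
        if (j %% 4L != 0L) next
        i <- others[j]
        k <- (j %/% 4L - 1L) %% nrow(motifLibrary) + 1L
        str <- if (j %% 8L == 0L) "-" else "+"
        genomeStr <- .plantMotif(genomeStr, promoters[[i]], 80L,
                                 motSeq[[motifLibrary$name[k]]], str)
        planted[[length(planted) + 1L]] <-
            data.frame(pri = priIds[i], motif = motifLibrary$name[k],
                       strand = str, offset = 80L)
    }
    plantedMotifs <- if (length(planted)) do.call(rbind, planted) else
        data.frame(pri = character(), motif = character(),
                   strand = character(), offset = integer())

    # transcriptome with embedded target sites for the repressed candidates
    # plus two expressed non-candidates
    txLen <- sample(500:1200, config@nTranscripts, replace = TRUE)
    txSeqs <- vapply(txLen, .randDNA, "")
    txNames <- sprintf("tx%04d", seq_len(config@nTranscripts))
    tmir <- c(config@repressedSet,
              utils::head(setdiff(knownNames, config@repressedSet), 2L))
    nPer <- ifelse(tmir %in% config@repressedSet, 2L, 1L)
    need <- sum(nPer)
    txPick <- sample(seq_len(config@nTranscripts), need)
    tt <- list()
    p <- 0L
    for (k in seq_along(tmir)) {
        mi <- match(tmir[k], allNames)
        site <- .revcomp(matures[mi])
        for (u in seq_len(nPer[k])) {
            p <- p + 1L
            ti <- txPick[p]
            pos <- sample(50:(txLen[ti] - 80L), 1L)
            substr(txSeqs[ti], pos, pos + 21L) <- site
            tt[[p]] <- data.frame(mirna = tmir[k], transcript = txNames[ti],
                                  sitePos = pos, cleavagePos = pos + 12L)
        }
    }
    trueTargets <- do.call(rbind, tt)

    # flat GO annotation; one defense term tags exactly the true target set
    goVocab <- data.frame(
        term = sprintf("GO:%07d", c(6952, 9733, 3700, 16874, 16211,
                                    5515, 6355, 9058, 15979, 16301,
                                    4672, 3824, 5634, 5737, 16020)),
        name = c("defense response", "response to auxin",
                 "DNA-binding transcription factor activity",
                 "ligase activity", "ammonia ligase activity",
                 "protein binding", "regulation of transcription",
                 "biosynthetic process", "photosynthesis",
                 "kinase activity", "protein kinase activity",
                 "catalytic activity", "nucleus", "cytoplasm", "membrane"),
        namespace = c("biological_process", "biological_process",
                      "molecular_function", "molecular_function",
                      "molecular_function", "molecular_function",
                      "biological_process", "biological_process",
                      "biological_process", "molecular_function",
                      "molecular_function", "molecular_function",
                      "cellular_component", "cellular_component",
                      "cellular_component"))
    goRows <- list(data.frame(gene = unique(trueTargets$transcript),
                              term = goVocab$term[1], name = goVocab$name[1],
                              namespace = goVocab$namespace[1]))
    for (g in 2:nrow(goVocab)) {
        genes <- sample(txNames, sample(3:10, 1L))
        goRows[[g]] <- data.frame(gene = genes, term = goVocab$term[g],
                                  name = goVocab$name[g],
                                  namespace = goVocab$namespace[g])
    }
    goAnnotation <- do.call(rbind, goRows)

    # per-locus baseline expression (log-normal relative abundance)
    baseAbundance <- exp(stats::rnorm(n, 0, 0.8))

    # assemble annotation: genes, pri-miRNAs, mature miRNA features; novel
    # loci are deliberately absent (they are undiscovered -- the truth
    # object records their intervals)
    grGene <- grPri <- grMat <- list()
    for (i in seq_len(n)) {
        l <- loc[[i]]
        if (!is.na(l$geneStart))
            grGene[[length(grGene) + 1L]] <- GRanges(
                "chr1", IRanges(l$geneStart, l$geneEnd),
                strand = l$geneStrand, type = "gene",
                ID = paste0("gene_", i), Name = paste0("gene_", i))
        if (i > nK) next
        grPri[[i]] <- GRanges("chr1", IRanges(l$priStart, l$priEnd),
                              strand = l$priStrand,
                              type = "miRNA_primary_transcript",
                              ID = priIds[i], Name = priIds[i])
        mo <- prec[[i]]$matOffset
        if (l$priStrand == "+") {
            ms <- l$priStart + mo - 1L
            grMat[[i]] <- GRanges("chr1", IRanges(ms, ms + 21L), strand = "+",
                                  type = "miRNA", ID = allNames[i],
                                  Name = allNames[i])
        } else {
            me <- l$priEnd - mo + 1L
            grMat[[i]] <- GRanges("chr1", IRanges(me - 21L, me), strand = "-",
                                  type = "miRNA", ID = allNames[i],
                                  Name = allNames[i])
        }
    }
    drop <- function(x) x[!vapply(x, is.null, TRUE)]
    annotation <- suppressWarnings(c(
        do.call(c, drop(grGene)), do.call(c, drop(grPri)),
        do.call(c, drop(grMat))))
    seqlengths(annotation) <- c(chr1 = config@genomeLength)

    mirnas <- DataFrame(
        name = allNames,
        family = suppressWarnings(assignFamily(allNames)),
        arm = ifelse(grepl("-5p$", allNames), "5p",
                     ifelse(grepl("-3p$", allNames), "3p", "unknown")),
        known = c(rep(TRUE, nK), rep(FALSE, nN)),
        mature = matures,
        star = vapply(prec, `[[`, "", "star"),
        context = vapply(seq_len(n), function(i)
            substr(prec[[i]]$seq, prec[[i]]$matOffset,
                   prec[[i]]$matOffset + 26L), ""),
        chrom = "chr1",
        start = vapply(loc, `[[`, 1L, "priStart"),
        end = vapply(loc, `[[`, 1L, "priEnd"),
        strand = vapply(loc, `[[`, "", "priStrand"),
        matOffset = vapply(prec, `[[`, 1L, "matOffset"),
        precLen = vapply(prec, `[[`, 1L, "len"),
        baseAbundance = baseAbundance,
        geometryCase = vapply(loc, `[[`, 1L, "case"),
        geneStart = vapply(loc, function(l) as.integer(l$geneStart), 1L),
        geneEnd = vapply(loc, function(l) as.integer(l$geneEnd), 1L),
        geneStrand = vapply(loc, function(l) as.character(l$geneStrand), ""),
        priId = priIds)

    truthObj <- new("SyntheticTruth",
                    repressedMirnas = intersect(config@repressedSet,
                                                knownNames),
                    trueTargets = trueTargets,
                    plantedMotifs = plantedMotifs,
                    novelLoci = priGR[nK + seq_len(nN)])

    genome <- DNAStringSet(setNames(genomeStr, "chr1"))
    matureKnown <- DNAStringSet(setNames(matures[seq_len(nK)], knownNames))
    transcripts <- DNAStringSet(setNames(txSeqs, txNames))

    new("SyntheticFixture", config = config, genome = genome,
        annotation = annotation, mirnas = mirnas, matureKnown = matureKnown,
        transcripts = transcripts, goAnnotation = goAnnotation,
        truth = truthObj)
}

#' Simulate a per-miRNA count matrix
#'
#' Draws per-library miRNA counts from a negative binomial around condition
#' means (Poisson when `dispersion` is 0).  MiRNAs in the configured
#' repressed set have their mean divided by `repressionFactor` in the first
#' condition only.  This is the count layer underneath
#' [simulateSrnaLibraries()], exposed directly so statistical calibration
#' studies can run without generating reads.
#'
#' @param config a [SimConfig-class]; `nKnownMirnas + nNovelMirnas` rows are
#'   simulated unless `abundance` is given.
#' @param abundance optional positive relative abundances (one per miRNA,
#'   names used as miRNA names).
#' @param mirnaNames row names when `abundance` is unnamed.
#' @param seed RNG seed; defaults to the config seed.
#' @return a [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay, library metadata in `colData` and a logical `repressed` column
#'   in `rowData`.
#' @examples
#' se <- simulateCounts(simConfig(seed = 2, nKnownMirnas = 20))
#' head(SummarizedExperiment::assay(se))
#' @export
simulateCounts <- function(config, abundance = NULL, mirnaNames = NULL,
                           seed = config@seed) {
    stopifnot(is(config, "SimConfig"))
    set.seed(seed)
    if (is.null(abundance)) {
        nm <- config@nKnownMirnas + config@nNovelMirnas
        abundance <- exp(stats::rnorm(nm, 0, 0.8))
        names(abundance) <- if (config@nKnownMirnas > 0)
            c(.mirnaNames(config@nKnownMirnas, config@repressedSet),
              if (config@nNovelMirnas > 0)
                  paste0("novel_mir_", seq_len(config@nNovelMirnas)))
        else NULL
    }
    if (is.null(names(abundance)))
        names(abundance) <- if (!is.null(mirnaNames)) mirnaNames else
            paste0("mir_", seq_along(abundance))
    share <- abundance / sum(abundance)
    muBase <- share * config@depthPerLibrary * (1 - config@backgroundFraction)
    repressed <- names(abundance) %in% config@repressedSet
    conds <- rep(config@conditions, each = config@nLibrariesPerCondition)
    reps <- rep(seq_len(config@nLibrariesPerCondition),
                times = length(config@conditions))
    libs <- paste0(conds, "_rep", reps)
    counts <- matrix(0L, nrow = length(abundance), ncol = length(libs),
                     dimnames = list(names(abundance), libs))
    for (j in seq_along(libs)) {
        mu <- muBase
        if (conds[j] == config@conditions[1])
            mu[repressed] <- mu[repressed] / config@repressionFactor
        counts[, j] <- if (config@dispersion > 0)
            rnbinom(length(mu), mu = mu, size = 1 / config@dispersion)
        else rpois(length(mu), mu)
    }
    SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(library = libs, condition = conds,
                            replicate = reps, row.names = libs),
        rowData = DataFrame(repressed = repressed))
}

# sample background genomic fragment coordinates avoiding precursor loci
.sampleBackground <- function(nbg, genomeLen, precRanges, lens, probs) {
    starts <- integer(0)
    guard <- 0L
    while (length(starts) < nbg && guard < 50L) {
        guard <- guard + 1L
        cand <- sample.int(genomeLen - 30L, nbg)
        bad <- IRanges::overlapsAny(IRanges(cand, cand + 29L), precRanges)
        starts <- c(starts, cand[!bad])
    }
    starts <- starts[seq_len(nbg)]
    L <- sample(lens, nbg, replace = TRUE, prob = probs)
    minus <- sample(c(TRUE, FALSE), nbg, replace = TRUE)
    list(start = starts, len = L, minus = minus)
}

#' Simulate small RNA FASTQ libraries
#'
#' Writes one FASTQ per library.  Reads are drawn from the mature miRNAs
#' (counts from [simulateCounts()]), as 5'-anchored sequences whose lengths
#' follow the configured length distribution (3' heterogeneity into the
#' hairpin), plus low-abundance star-strand reads and a pool of random
#' genomic background fragments.  The 3' adapter is appended and reads are
#' written at constant Q30 so adapter trimming and quality filtering are both
#' exercised; a small, fixed number of background reads carry low qualities
#' or an N to give the cleaning filters true positives.
#'
#' @param config a [SimConfig-class].
#' @param fixture the matching [SyntheticFixture-class].
#' @param dir output directory (created if needed).
#' @return data.frame with columns library, condition, replicate, path,
#'   reads; the true per-library miRNA counts are attached as attribute
#'   `trueCounts`.
#' @export
simulateSrnaLibraries <- function(config, fixture, dir) {
    stopifnot(is(fixture, "SyntheticFixture"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    mir <- fixture@mirnas
    se <- simulateCounts(config,
                         abundance = setNames(mir$baseAbundance, mir$name),
                         seed = config@seed + 1L)
    counts <- assay(se)
    cd <- as.data.frame(colData(se))
    lens <- as.integer(names(config@lengthDist))
    probs <- as.numeric(config@lengthDist)
    precRanges <- IRanges(mir$start, mir$end)
    genomeStr <- as.character(fixture@genome[[1]])
    adapterPad <- strrep(config@adapter3,
                         ceiling(config@readLength / nchar(config@adapter3)) + 1L)
    qConst <- strrep("?", config@readLength)  # constant Q30 placeholder
    out <- vector("list", nrow(cd))
    for (j in seq_len(nrow(cd))) {
        set.seed(config@seed + 1000L + j)
        idx <- rep(seq_len(nrow(mir)), counts[, j])
        L <- sample(lens, length(idx), replace = TRUE, prob = probs)
        inserts <- substring(mir$context[idx], 1L, L)
        # star reads at ~4% of the mature mean
        starN <- rpois(nrow(mir), pmax(0.4, 0.04 * counts[, j]))
        starIns <- rep(mir$star, starN)
        # genomic background
        nbg <- round(config@backgroundFraction * config@depthPerLibrary)
        bg <- .sampleBackground(nbg, config@genomeLength, precRanges,
                                lens, probs)
        bgIns <- substring(genomeStr, bg$start, bg$start + bg$len - 1L)
        if (any(bg$minus))
            bgIns[bg$minus] <- .revcomp(bgIns[bg$minus])
        allIns <- c(inserts, starIns, bgIns)
        quals <- rep(qConst, length(allIns))
        # fixed QC spice at the head of the background block
        nb0 <- length(inserts) + length(starIns)
        if (nbg >= 60L) {
            quals[nb0 + 1:30] <- strrep("#", config@readLength)
            substr(allIns[nb0 + 31:60], 5L, 5L) <- "N"
        }
        reads <- substr(paste0(allIns, adapterPad), 1L, config@readLength)
        ord <- sample(length(reads))
        path <- file.path(dir, paste0(cd$library[j], ".fastq"))
        .writeFastq(path, paste0(cd$library[j], "_", seq_along(reads)),
                    reads[ord], quals[ord])
        out[[j]] <- data.frame(library = cd$library[j],
                               condition = cd$condition[j],
                               replicate = cd$replicate[j],
                               path = path, reads = length(reads))
    }
    res <- do.call(rbind, out)
    attr(res, "trueCounts") <- counts
    res
}

#' Simulate degradome (PARE) tag pools
#'
#' For every true target the 5' ends of Poisson(`degradomeSignal`) tags pile
#' at the planted cleavage position; background tags are scattered over all
#' transcript positions at `degradomeNoiseRate` per position.  Tags are
#' 20-nt prefixes of the cleaved transcript suffix, one FASTA per condition.
#'
#' @param config a [SimConfig-class].
#' @param fixture the matching [SyntheticFixture-class].
#' @param dir output directory.
#' @return data.frame with columns condition, path, tags.
#' @export
simulateDegradome <- function(config, fixture, dir) {
    stopifnot(is(fixture, "SyntheticFixture"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tt <- truth(fixture)@trueTargets
    txs <- fixture@transcripts
    out <- vector("list", length(config@conditions))
    for (ci in seq_along(config@conditions)) {
        set.seed(config@seed + 2000L + ci)
        tags <- character(0)
        for (r in seq_len(nrow(tt))) {
            k <- rpois(1L, config@degradomeSignal)
            if (k == 0L) next
            s <- as.character(subseq(txs[[tt$transcript[r]]],
                                     tt$cleavagePos[r],
                                     tt$cleavagePos[r] + 19L))
            tags <- c(tags, rep(s, k))
        }
        for (tn in names(txs)) {
            len <- nchar(as.character(txs[[tn]]))
            npos <- len - 19L
            cnt <- rpois(npos, config@degradomeNoiseRate)
            nz <- which(cnt > 0L)
            if (length(nz)) {
                sq <- as.character(txs[[tn]])
                tags <- c(tags, rep(substring(sq, nz, nz + 19L), cnt[nz]))
            }
        }
        path <- file.path(dir,
                          paste0("degradome_", config@conditions[ci], ".fa"))
        writeXStringSet(DNAStringSet(setNames(tags, paste0(
            config@conditions[ci], "_tag_", seq_along(tags)))), path)
        out[[ci]] <- data.frame(condition = config@conditions[ci],
                                path = path, tags = length(tags))
    }
    do.call(rbind, out)
}

#' Write a complete fixture dataset to disk
#'
#' Materialises everything the pipeline consumes: genome FASTA, GFF3
#' annotation (1-based inclusive), known-mature FASTA, transcriptome FASTA,
#' GO annotation TSV, per-library small RNA FASTQ, per-condition degradome
#' FASTA, a machine-readable `truth.tsv` and a `manifest.yaml` recording the
#' configuration (including the adapter sequence).
#'
#' @param config a [SimConfig-class].
#' @param dir output directory.
#' @param fixture optionally a pre-built [SyntheticFixture-class] (rebuilt
#'   from `config` otherwise).
#' @return invisibly, a list with all file paths, the library table and the
#'   fixture object.
#' @export
writeFixture <- function(config, dir, fixture = NULL) {
    if (is.null(fixture)) fixture <- makeGenome(config)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
        genome = file.path(dir, "genome.fa"),
        annotation = file.path(dir, "annotation.gff3"),
        mature = file.path(dir, "mature_known.fa"),
        transcriptome = file.path(dir, "transcriptome.fa"),
        go = file.path(dir, "go_annotation.tsv"),
        truth = file.path(dir, "truth.tsv"),
        manifest = file.path(dir, "manifest.yaml"))
    writeXStringSet(fixture@genome, paths$genome)
    rtracklayer::export(fixture@annotation, paths$annotation, format = "gff3")
    writeXStringSet(fixture@matureKnown, paths$mature)
    writeXStringSet(fixture@transcripts, paths$transcriptome)
    .writeTsv(fixture@goAnnotation, paths$go)

    libs <- simulateSrnaLibraries(config, fixture, dir)
    deg <- simulateDegradome(config, fixture, dir)

    tr <- truth(fixture)
    truthTab <- rbind(
        data.frame(record = "repressed", name = tr@repressedMirnas,
                   transcript = NA, cleavage_pos = NA, motif = NA,
                   strand = NA, offset = NA, chrom = NA, start = NA,
                   end = NA),
        data.frame(record = "target", name = tr@trueTargets$mirna,
                   transcript = tr@trueTargets$transcript,
                   cleavage_pos = tr@trueTargets$cleavagePos, motif = NA,
                   strand = NA, offset = NA, chrom = NA, start = NA,
                   end = NA),
        data.frame(record = "motif", name = tr@plantedMotifs$pri,
                   transcript = NA, cleavage_pos = NA,
                   motif = tr@plantedMotifs$motif,
                   strand = tr@plantedMotifs$strand,
                   offset = tr@plantedMotifs$offset, chrom = NA, start = NA,
                   end = NA),
        data.frame(record = "novel_locus", name = names(tr@novelLoci),
                   transcript = NA, cleavage_pos = NA, motif = NA,
                   strand = as.character(strand(tr@novelLoci)), offset = NA,
                   chrom = as.character(seqnames(tr@novelLoci)),
                   start = start(tr@novelLoci), end = end(tr@novelLoci)))
    .writeTsv(truthTab, paths$truth)

    manifest <- list(
        generator = "mirISR synthetic fixture",
        seed = config@seed,
        adapter3 = config@adapter3,
        conditions = as.list(config@conditions),
        librariesPerCondition = config@nLibrariesPerCondition,
        depthPerLibrary = config@depthPerLibrary,
        repressedSet = as.list(config@repressedSet),
        repressionFactor = config@repressionFactor,
        lengthDist = as.list(config@lengthDist),
        dispersion = config@dispersion,
        backgroundFraction = config@backgroundFraction,
        degradomeSignal = config@degradomeSignal,
        degradomeNoiseRate = config@degradomeNoiseRate,
        files = lapply(paths, basename),
        libraries = lapply(seq_len(nrow(libs)), function(i)
            list(id = libs$library[i], condition = libs$condition[i],
                 replicate = libs$replicate[i],
                 fastq = basename(libs$path[i]))),
        degradome = lapply(seq_len(nrow(deg)), function(i)
            list(condition = deg$condition[i],
                 fasta = basename(deg$path[i]))))
    yaml::write_yaml(manifest, paths$manifest)

    invisible(c(paths, list(libraries = libs, degradome = deg,
                            fixture = fixture)))
}
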