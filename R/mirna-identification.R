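# Known-miRNA matching, family assignment, hairpin folding and novel
# candidate calling.

#' Match collapsed tags to a reference set of mature miRNAs
#'
#' A tag is assigned to a reference mature if, anchored at the 5' end, it
#' agrees over the shared prefix with at most `maxMismatches` mismatches and
#' the length difference is at most `maxShift` (3' heterogeneity).  Each tag
#' receives at most one miRNA: fewest mismatches, then smallest length
#' difference, then reference order.
#'
#' @param tags [collapseTags()] output, or a character vector of tag
#'   sequences.
#' @param reference named character vector or `DNAStringSet` of mature
#'   miRNA sequences (miRBase-style names).
#' @param maxMismatches maximum mismatches over the shared prefix.
#' @param maxShift maximum 5'-anchored length difference in nt.
#' @return data.frame with columns `sequence`, `mirna`, `family`,
#'   `mismatches`, `lengthDiff` (tag length minus reference length), one row
#'   per assigned tag.
#' @examples
#' ref <- c(`zma-miR169a-5p` = "TAGCCAAGGATGACTTGCCTGC")
#' matchKnown("TAGCCAAGGATGACTTGCCTGC", ref)
#' @export
matchKnown <- function(tags, reference, maxMismatches = 0L, maxShift = 2L) {
    refSeq <- .normalizeSeq(as.character(reference))
    refName <- names(reference)
    if (length(refSeq) == 0L) stop("reference must be non-empty")
    if (is.null(refName) || any(!nzchar(refName)))
        stop("reference sequences must be named")
    if (anyDuplicated(refName))
        stop("duplicate reference names: ",
             paste(unique(refName[duplicated(refName)]), collapse = ", "))
    tagSeq <- if (is.data.frame(tags)) tags$sequence else as.character(tags)
    tagSeq <- .normalizeSeq(tagSeq)
    tagLen <- nchar(tagSeq)
    refLen <- nchar(refSeq)
    n <- length(tagSeq)
    bestMm <- rep(NA_integer_, n)
    bestShift <- rep(NA_integer_, n)
    bestRef <- rep(NA_integer_, n)
    for (j in seq_along(refSeq)) {
        dl <- tagLen - refLen[j]
        cand <- which(abs(dl) <= maxShift)
        if (!length(cand)) next
        k <- pmin(tagLen[cand], refLen[j])
        if (maxMismatches == 0L) {
            ok <- substring(tagSeq[cand], 1L, k) ==
                substring(refSeq[j], 1L, k)
            mm <- ifelse(ok, 0L, NA_integer_)
        } else {
            mm <- vapply(seq_along(cand), function(ii) {
                a <- charToRaw(substr(tagSeq[cand[ii]], 1L, k[ii]))
                b <- charToRaw(substr(refSeq[j], 1L, k[ii]))
                sum(a != b)
            }, 0L)
            mm[mm > maxMismatches] <- NA_integer_
        }
        hit <- which(!is.na(mm))
        for (ii in hit) {
            i <- cand[ii]
            better <- is.na(bestMm[i]) ||
                mm[ii] < bestMm[i] ||
                (mm[ii] == bestMm[i] && abs(dl[i]) < abs(bestShift[i]))
            if (better) {
                bestMm[i] <- mm[ii]
                bestShift[i] <- dl[i]
                bestRef[i] <- j
            }
        }
    }
    sel <- which(!is.na(bestRef))
    data.frame(sequence = tagSeq[sel],
               mirna = refName[bestRef[sel]],
               family = suppressWarnings(assignFamily(refName[bestRef[sel]])),
               mismatches = bestMm[sel],
               lengthDiff = bestShift[sel],
               stringsAsFactors = FALSE)
}

#' Assign a miRNA family label from a name
#'
#' `<species>-miR<number><letters>` names map to `miR<number>`; novel
#' identifiers form their own singleton family; anything unparseable gets an
#' explicit `"unknown"` label with a warning.
#'
#' @param name character vector of miRNA names.
#' @return character vector of family labels.
#' @examples
#' assignFamily(c("zma-miR169a-5p", "zma-miR399j", "novel_mir_17"))
#' @export
assignFamily <- function(name) {
    fam <- rep(NA_character_, length(name))
    m <- regmatches(name, regexec("^[A-Za-z]+-miR([0-9]+)", name))
    hit <- lengths(m) == 2L
    fam[hit] <- paste0("miR", vapply(m[hit], `[`, "", 2L))
    novel <- !hit & grepl("^novel[_-]", name)
    fam[novel] <- name[novel]
    bad <- is.na(fam)
    if (any(bad)) {
        warning("unparseable miRNA name(s): ",
                paste(unique(name[bad]), collapse = ", "))
        fam[bad] <- "unknown"
    }
    fam
}

# run RNAfold (ViennaRNA) on a set of sequences, returning dot-brackets
.rnafold <- function(seqs) {
    exe <- Sys.which("RNAfold")
    if (!nzchar(exe))
        stop("RNAfold backend requested but the RNAfold executable was ",
             "not found on PATH")
    inp <- tempfile(fileext = ".fa")
    writeLines(paste0(">s", seq_along(seqs), "\n", seqs), inp)
    out <- system2(exe, c("--noPS", "-i", inp), stdout = TRUE)
    db <- out[seq(3L, by = 3L, length.out = length(seqs))]
    sub("^([().]+).*$", "\\1", db)
}

#' Fold a hairpin precursor candidate
#'
#' Returns a pseudoknot-free secondary structure.  The built-in backend is
#' Nussinov base-pair maximisation (minimum loop 3 nt, G-U pairs allowed);
#' the `rnafold` backend calls ViennaRNA's RNAfold for a minimum free energy
#' structure when the executable is available.  The backend actually used is
#' recorded in the result.
#'
#' @param sequence nucleotide string (T and U both accepted).
#' @param backend `"nussinov"`, `"rnafold"`, or `"auto"` (RNAfold when
#'   available, otherwise Nussinov).
#' @param minLoop minimum hairpin loop size for the Nussinov backend.
#' @return list with `structure` (dot-bracket), `pairs` (base-pair count),
#'   `partner` (1-based partner vector, 0 = unpaired) and `backend`.
#' @examples
#' foldHairpin("GGGAAACCC")
#' @export
foldHairpin <- function(sequence, backend = c("nussinov", "rnafold", "auto"),
                        minLoop = 3L) {
    backend <- match.arg(backend)
    sequence <- .normalizeSeq(sequence)
    .checkNucleotides(sequence, "precursor sequence")
    if (backend == "auto")
        backend <- if (nzchar(Sys.which("RNAfold"))) "rnafold" else "nussinov"
    if (backend == "rnafold") {
        db <- .rnafold(sequence)[1]
        partner <- .dotBracketPartner(db)
        list(structure = db, pairs = sum(partner > seq_along(partner)),
             partner = partner, backend = "rnafold")
    } else {
        r <- .nussinov_fold(sequence, as.integer(minLoop))
        list(structure = r$structure, pairs = r$pairs, partner = r$partner,
             backend = "nussinov")
    }
}

# expected star-strand interval from the pair table, using the 2-nt 3'
# overhang rule; coordinates are within the folded window
.expectedStar <- function(partner, matStart, matEnd, overhang = 2L) {
    idx <- matStart:matEnd
    pp <- partner[idx]
    paired <- which(pp > 0L)
    if (!length(paired)) return(NULL)
    # partner of the base at (or nearest below) matEnd - overhang
    hi3 <- paired[paired <= (matEnd - overhang - matStart + 1L)]
    lo <- if (length(hi3)) pp[max(hi3)] else min(pp[paired])
    hi <- pp[min(paired)] + overhang
    c(lo, hi)
}

#' Call novel miRNA candidates from unassigned tags
#'
#' Maps each sufficiently abundant unassigned tag to the genome by exact
#' match (both strands), extracts two flanking windows around each hit (the
#' tag could sit on either hairpin arm), folds them, and accepts a candidate
#' when the mature tag lies on one arm of a single stem with at least
#' `minPairedMature` of its bases paired, the trimmed precursor length falls
#' in `[minPrecursor, maxPrecursor]`, the hairpin pairing fraction reaches
#' `minPairingFraction`, and a star-compatible tag (2-nt 3' overhang rule,
#' tolerance `overhangTol`) exists or the star region is unexpressed.
#' Overlapping candidates are deduplicated keeping the highest mature count;
#' candidates overlapping `excludeRanges` (e.g. known miRNA loci) are
#' dropped.  Tags with more than `maxHits` genomic hits are skipped as
#' repeat-like.
#'
#' @param tags [collapseTags()]-style data.frame of unassigned tags.
#' @param genome `DNAStringSet` genome.
#' @param flank upstream/downstream window sizes around the tag.
#' @param minCount minimum total tag count to seed a candidate.
#' @param minPairedMature minimum paired mature bases in the duplex.
#' @param minPairingFraction minimum 2*pairs/length over the precursor.
#' @param minPrecursor,maxPrecursor precursor length bounds in nt.
#' @param overhang,overhangTol star overhang rule and tolerance.
#' @param maxHits maximum genomic hits before a tag is skipped.
#' @param excludeRanges optional `GRanges` of loci to exclude.
#' @param backend folding backend passed to [foldHairpin()].
#' @return data.frame of candidates: locus, strand, mature and expected star
#'   sequences, precursor sequence and structure, counts and pairing
#'   statistics, and the folding backend used.
#' @export
callNovel <- function(tags, genome, flank = c(20L, 160L), minCount = 5L,
                      minPairedMature = 16L, minPairingFraction = 0.55,
                      minPrecursor = 58L, maxPrecursor = 250L,
                      overhang = 2L, overhangTol = 1L, maxHits = 20L,
                      excludeRanges = NULL,
                      backend = c("auto", "rnafold", "nussinov")) {
    backend <- match.arg(backend)
    stopifnot(is.data.frame(tags))
    if (nrow(tags) == 0L) return(.emptyNovel())
    libCols <- setdiff(names(tags), c("sequence", "length", "total"))
    total <- if ("total" %in% names(tags)) tags$total
             else rowSums(tags[libCols])
    chrNames <- names(genome)
    # genomic hits for every tag (also needed for star-tag lookups)
    seed <- which(total >= minCount)
    hits <- list()
    for (i in seed) {
        pat <- DNAString(tags$sequence[i])
        for (ch in chrNames) {
            mp <- matchPattern(pat, genome[[ch]])
            if (length(mp))
                hits[[length(hits) + 1L]] <- data.frame(
                    tag = i, chrom = ch, start = start(mp), end = end(mp),
                    strand = "+")
            mm <- matchPattern(reverseComplement(pat), genome[[ch]])
            if (length(mm))
                hits[[length(hits) + 1L]] <- data.frame(
                    tag = i, chrom = ch, start = start(mm), end = end(mm),
                    strand = "-")
        }
    }
    if (!length(hits)) return(.emptyNovel())
    hits <- do.call(rbind, hits)
    nPerTag <- table(hits$tag)
    repeatLike <- as.integer(names(nPerTag)[nPerTag > maxHits])
    if (length(repeatLike))
        message("skipping ", length(repeatLike),
                " repeat-like tag(s) with > ", maxHits, " genomic hits")
    hits <- hits[!hits$tag %in% repeatLike, , drop = FALSE]
    if (nrow(hits) == 0L) return(.emptyNovel())

    # collect candidate windows first so all folds run in one batch
    win <- list()
    for (r in seq_len(nrow(hits))) {
        h <- hits[r, ]
        chromLen <- length(genome[[h$chrom]])
        for (w in 1:2) {
            fu <- flank[w]; fd <- flank[3L - w]
            if (h$strand == "+") {
                ws <- max(1L, h$start - fu); we <- min(chromLen, h$end + fd)
            } else {
                ws <- max(1L, h$start - fd); we <- min(chromLen, h$end + fu)
            }
            wgr <- GRanges(h$chrom, IRanges(ws, we), strand = h$strand)
            matStart <- if (h$strand == "+") h$start - ws + 1L
                        else we - h$end + 1L
            win[[length(win) + 1L]] <- data.frame(
                r = r, ws = ws, we = we,
                matStart = matStart,
                matEnd = matStart + nchar(tags$sequence[h$tag]) - 1L,
                wseq = .getSeq(genome, wgr))
        }
    }
    win <- do.call(rbind, win)
    if (is.null(win) || nrow(win) == 0L) return(.emptyNovel())
    if (backend == "auto")
        backend <- if (nzchar(Sys.which("RNAfold"))) "rnafold" else
            "nussinov"
    useq <- unique(win$wseq)
    folds <- if (backend == "rnafold") {
        db <- .rnafold(useq)
        lapply(seq_along(useq), function(i) {
            partner <- .dotBracketPartner(db[i])
            list(structure = db[i], partner = partner,
                 backend = "rnafold")
        })
    } else {
        lapply(useq, function(s) {
            r <- .nussinov_fold(s, 3L)
            list(structure = r$structure, partner = r$partner,
                 backend = "nussinov")
        })
    }
    names(folds) <- useq

    cand <- list()
    for (q in seq_len(nrow(win))) {
        h <- hits[win$r[q], ]
        ws <- win$ws[q]; we <- win$we[q]
        matStart <- win$matStart[q]; matEnd <- win$matEnd[q]
        wseq <- win$wseq[q]
        fold <- folds[[wseq]]
        {
            ev <- .evaluateHairpin(fold$partner, matStart, matEnd,
                                   minPairedMature, minPairingFraction,
                                   minPrecursor, maxPrecursor)
            if (is.null(ev)) next
            # star support: another mapped tag at the expected star interval
            # (within tolerance), or no expression over the star region
            starIv <- .expectedStar(fold$partner, matStart, matEnd, overhang)
            starOK <- TRUE
            starCount <- 0L
            starSeq <- NA_character_
            if (!is.null(starIv)) {
                starSeq <- substr(wseq, max(1L, starIv[1]),
                                  min(nchar(wseq), starIv[2]))
                inWin <- which(hits$chrom == h$chrom &
                               hits$strand == h$strand &
                               hits$start >= ws & hits$end <= we &
                               hits$tag != h$tag)
                if (length(inWin)) {
                    os <- if (h$strand == "+") hits$start[inWin] - ws + 1L
                          else we - hits$end[inWin] + 1L
                    oe <- os + (hits$end[inWin] - hits$start[inWin])
                    isStar <- abs(os - starIv[1]) <= overhangTol &
                              abs(oe - starIv[2]) <= overhangTol
                    overlapsStar <- os <= starIv[2] & oe >= starIv[1]
                    if (any(isStar)) {
                        starCount <- sum(total[hits$tag[inWin[isStar]]])
                    } else if (any(overlapsStar)) {
                        starOK <- FALSE  # star region expressed but wrong
                    }
                }
            }
            if (!starOK) next
            precGR <- if (h$strand == "+")
                GRanges(h$chrom, IRanges(ws + ev$lo - 1L, ws + ev$hi - 1L),
                        strand = "+")
            else GRanges(h$chrom, IRanges(we - ev$hi + 1L, we - ev$lo + 1L),
                         strand = "-")
            cand[[length(cand) + 1L]] <- data.frame(
                chrom = h$chrom, start = start(precGR), end = end(precGR),
                strand = h$strand,
                matureSeq = tags$sequence[h$tag],
                starSeq = starSeq,
                precursorSeq = substr(wseq, ev$lo, ev$hi),
                structure = substr(fold$structure, ev$lo, ev$hi),
                matureCount = total[h$tag], starCount = starCount,
                pairedMature = ev$pairedMature,
                pairingFraction = ev$pairingFraction,
                backend = fold$backend)
        }
    }
    if (!length(cand)) return(.emptyNovel())
    cand <- do.call(rbind, cand)
    # total support: all mapped tags falling inside the precursor on the
    # candidate strand; 3' heterogeneity reads break the strand tie that a
    # perfect inverted repeat would otherwise leave
    cand$supportCount <- vapply(seq_len(nrow(cand)), function(i) {
        sel <- hits$chrom == cand$chrom[i] &
            hits$strand == cand$strand[i] &
            hits$start >= cand$start[i] & hits$end <= cand$end[i]
        sum(total[unique(hits$tag[sel])])
    }, 0)
    # deduplicate by locus overlap (strand-blind: a hairpin reads as a
    # hairpin from both strands), keeping the best-supported candidate
    cand <- cand[order(-cand$supportCount, -cand$matureCount, cand$chrom,
                       cand$start), ]
    gr <- GRanges(cand$chrom, IRanges(cand$start, cand$end),
                  strand = cand$strand)
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
        if (!keep[i]) next
        ov <- which(keep & seq_len(nrow(cand)) > i &
                    as.logical(IRanges::overlapsAny(gr, gr[i],
                                                    ignore.strand = TRUE)))
        keep[ov] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
    if (!is.null(excludeRanges) && nrow(cand)) {
        gr <- GRanges(cand$chrom, IRanges(cand$start, cand$end),
                      strand = cand$strand)
        drop <- IRanges::overlapsAny(gr, excludeRanges,
                                     ignore.strand = TRUE)
        cand <- cand[!drop, , drop = FALSE]
    }
    if (nrow(cand)) {
        cand <- cand[order(-cand$supportCount, -cand$matureCount,
                           cand$chrom, cand$start), ]
        cand$name <- paste0("novel_mir_", seq_len(nrow(cand)))
        rownames(cand) <- NULL
    }
    cand
}

.emptyNovel <- function() {
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), matureSeq = character(),
               starSeq = character(), precursorSeq = character(),
               structure = character(), matureCount = numeric(),
               starCount = numeric(), pairedMature = integer(),
               pairingFraction = numeric(), backend = character(),
               supportCount = numeric(), name = character())
}

# hairpin acceptance rules shared by callNovel; returns NULL on rejection
.evaluateHairpin <- function(partner, matStart, matEnd, minPairedMature,
                             minPairingFraction, minPrecursor,
                             maxPrecursor) {
    idx <- matStart:matEnd
    if (matEnd > length(partner)) return(NULL)
    pp <- partner[idx]
    paired <- pp[pp > 0L]
    if (length(paired) < minPairedMature) return(NULL)
    # one arm of a single stem: no self-pairing, all partners on one side,
    # spanning a compact region
    if (any(paired >= matStart & paired <= matEnd)) return(NULL)
    oneSide <- all(paired > matEnd) || all(paired < matStart)
    if (!oneSide) return(NULL)
    if (max(paired) - min(paired) + 1L > length(idx) + 8L) return(NULL)
    lo <- min(c(idx, paired)) - 2L
    hi <- max(c(idx, paired)) + 2L
    lo <- max(1L, lo)
    hi <- min(length(partner), hi)
    plen <- hi - lo + 1L
    if (plen < minPrecursor || plen > maxPrecursor) return(NULL)
    sub <- partner[lo:hi]
    within <- sum(sub >= lo & sub <= hi & sub > 0L)
    frac <- within / plen
    if (frac < minPairingFraction) return(NULL)
    list(lo = lo, hi = hi, pairedMature = length(paired),
         pairingFraction = frac)
}
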