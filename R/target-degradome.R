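# Plant-style target prediction, degradome mapping, and cleavage-site
# category classification.

#' Score a miRNA : target-site duplex
#'
#' Plant complementarity scoring: the miRNA is aligned antiparallel to the
#' target window; per position a Watson-Crick pair costs 0, a G:U wobble
#' 0.5, a mismatch 1, and each bulged nucleotide 1, with penalties at miRNA
#' positions 2--13 (seed-proximal region, 5' end = position 1) doubled.
#' All placements of at most one single-nucleotide bulge (on either strand)
#' are enumerated and the minimum-score alignment returned.  The predicted
#' cleavage position sits opposite miRNA position 10, the canonical slicing
#' register.
#'
#' @param mirna miRNA sequence, 5'->3', 18--26 nt.
#' @param target target window, 5'->3'; width within 1 nt of the miRNA
#'   length.
#' @return list with `score`, `pairing` (one symbol per miRNA position,
#'   5'->3': `|` pair, `o` G:U, `.` mismatch, `-` bulge), `cleavageOffset`
#'   (1-based position within the window opposite miRNA position 10), and
#'   the bulge placement.
#' @examples
#' scoreDuplex("TAGCCAAGGATGACTTGCCTGC",
#'             as.character(Biostrings::reverseComplement(
#'                 Biostrings::DNAString("TAGCCAAGGATGACTTGCCTGC"))))
#' @export
scoreDuplex <- function(mirna, target) {
    mirna <- .normalizeSeq(mirna)
    target <- .normalizeSeq(target)
    .checkNucleotides(mirna, "miRNA")
    .checkNucleotides(target, "target window")
    if (nchar(mirna) < 18L || nchar(mirna) > 26L)
        stop("miRNA length must be 18-26 nt")
    if (abs(nchar(target) - nchar(mirna)) > 1L)
        stop("target window width must be within 1 nt of the miRNA length")
    r <- .score_duplex_cpp(mirna, target)
    list(score = r$score, pairing = r$pairing,
         cleavageOffset = r$cleavage_offset,
         gap = c("none", "target", "mirna")[r$gap + 1L], bulge = r$bulge)
}

#' Predict miRNA target sites across a transcriptome
#'
#' Slides every miRNA over every transcript (window widths within 1 nt of
#' the miRNA length), scores each window with [scoreDuplex()]'s model, and
#' keeps alignments with score `<= maxScore`.  Duplicates -- the same
#' (miRNA, transcript, cleavage site) reached by different windows -- are
#' merged keeping the best score.
#'
#' @param mirnas named character vector / `DNAStringSet` of mature miRNAs.
#' @param transcripts named `DNAStringSet` (or character) transcriptome.
#' @param maxScore maximum duplex penalty (default 4.0).
#' @return data.frame: `mirna`, `transcript`, `start`, `width`, `score`,
#'   `cleavage` (transcript coordinate opposite miRNA position 10),
#'   `pairing`.
#' @export
findTargets <- function(mirnas, transcripts, maxScore = 4.0) {
    mseq <- setNames(.normalizeSeq(as.character(mirnas)), names(mirnas))
    if (is.null(names(mseq))) stop("mirnas must be named")
    txs <- setNames(as.character(transcripts), names(transcripts))
    if (length(txs) == 0L) stop("transcriptome is empty")
    if (is.null(names(txs))) stop("transcripts must be named")
    out <- list()
    for (mi in seq_along(mseq)) {
        for (ti in seq_along(txs)) {
            df <- .scan_transcript_cpp(mseq[mi], txs[ti], maxScore)
            if (nrow(df)) {
                df$mirna <- names(mseq)[mi]
                df$transcript <- names(txs)[ti]
                out[[length(out) + 1L]] <- df
            }
        }
    }
    if (!length(out))
        return(data.frame(mirna = character(), transcript = character(),
                          start = integer(), width = integer(),
                          score = numeric(), cleavage = integer(),
                          pairing = character()))
    res <- do.call(rbind, out)
    # merge duplicates per (miRNA, transcript, cleavage site): best score,
    # then the ungapped / leftmost alignment
    mlen <- nchar(mseq[res$mirna])
    res <- res[order(res$mirna, res$transcript, res$cleavage, res$score,
                     abs(res$width - mlen), res$start), ]
    key <- paste(res$mirna, res$transcript, res$cleavage)
    res <- res[!duplicated(key), ]
    rownames(res) <- NULL
    res[, c("mirna", "transcript", "start", "width", "score", "cleavage",
            "pairing")]
}

#' Map degradome tags to transcripts as 5'-end profiles
#'
#' Each tag's diagnostic prefix (first `prefixLength` nt) is matched exactly
#' against the transcriptome; every match increments the profile at the
#' tag's 5' position.  Tags matching several transcripts are counted once
#' per matching transcript and flagged in the stats; unmapped tags are
#' counted.
#'
#' @param tags degradome reads (`DNAStringSet`, character vector, or a
#'   FASTA/FASTQ path).
#' @param transcripts named `DNAStringSet` transcriptome.
#' @param prefixLength diagnostic prefix length (default 20 nt).
#' @return list with `profiles` (named list of integer vectors, one per
#'   transcript, length = transcript length) and `stats` (total, mapped,
#'   unmapped, multiTranscript tag events).
#' @export
mapDegradome <- function(tags, transcripts, prefixLength = 20L) {
    if (is.character(tags) && length(tags) == 1L && file.exists(tags))
        tags <- readDNAStringSet(tags,
                                 format = if (grepl("\\.f(ast)?q$", tags))
                                     "fastq" else "fasta")
    tagSeq <- .normalizeSeq(as.character(tags))
    txs <- if (is(transcripts, "DNAStringSet")) transcripts
           else DNAStringSet(.normalizeSeq(transcripts))
    tooShort <- nchar(tagSeq) < prefixLength
    prefixes <- substr(tagSeq[!tooShort], 1L, prefixLength)
    ptab <- table(prefixes)
    uniq <- names(ptab)
    profiles <- lapply(as.list(width(txs)), integer)
    names(profiles) <- names(txs)
    mappedPrefix <- rep(FALSE, length(uniq))
    multiPrefix <- rep(0L, length(uniq))
    if (length(uniq)) {
        pd <- PDict(DNAStringSet(uniq))
        for (ti in seq_along(txs)) {
            m <- matchPDict(pd, txs[[ti]])
            cnt <- lengths(m)
            hit <- which(cnt > 0L)
            for (u in hit) {
                st <- start(m[[u]])
                profiles[[ti]][st] <- profiles[[ti]][st] + as.integer(ptab[u])
            }
            mappedPrefix[hit] <- TRUE
            multiPrefix[hit] <- multiPrefix[hit] + 1L
        }
    }
    mappedTags <- sum(ptab[mappedPrefix])
    multiTags <- sum(ptab[multiPrefix > 1L])
    list(profiles = profiles,
         stats = list(total = length(tagSeq),
                      mapped = as.integer(mappedTags),
                      unmapped = length(tagSeq) - as.integer(mappedTags),
                      multiTranscript = as.integer(multiTags),
                      tooShort = sum(tooShort)))
}

#' Classify degradome support at a predicted cleavage site
#'
#' With `a` the maximum tag abundance within `site +/- window`, `max*` the
#' profile maximum and `med` the median abundance over positions carrying at
#' least one tag:
#'
#' * `a == 0`: `"unsupported"`.
#' * `a == max*`, maximum attained at exactly one position: category `"0"`.
#' * `a == max*`, maximum attained at several positions: category `"1"`.
#' * `a < max*` and `a > 1`: `"2"` if `a > med`, else `"3"` (ties at the
#'   median read "higher than" strictly).
#' * `a == 1` (and below the maximum): category `"4"`.
#'
#' @param profile integer vector of per-position degradome 5'-end counts.
#' @param site predicted cleavage position (1-based).
#' @param window half-width of the site window accommodating the 10/11
#'   register ambiguity (default 1).
#' @return list with `category` (character), `siteAbundance`, `profileMax`,
#'   `profileMedian`.
#' @examples
#' categorizeCleavage(c(0, 0, 9, 0, 1), 3)   # single peak at the site
#' categorizeCleavage(c(0, 9, 9, 0, 0), 3)   # tied maxima
#' @export
categorizeCleavage <- function(profile, site, window = 1L) {
    n <- length(profile)
    if (n == 0L) stop("profile is empty")
    if (site < 1L || site > n)
        stop("cleavage position ", site, " outside the transcript (length ",
             n, ")")
    lo <- max(1L, site - window)
    hi <- min(n, site + window)
    a <- max(profile[lo:hi])
    mx <- max(profile)
    med <- if (any(profile >= 1)) median(profile[profile >= 1]) else NA_real_
    category <- if (a == 0) "unsupported"
        else if (a == mx && sum(profile == mx) == 1L) "0"
        else if (a == mx) "1"
        else if (a == 1) "4"
        else if (a > med) "2"
        else "3"
    list(category = category, siteAbundance = a, profileMax = mx,
         profileMedian = med)
}

#' Per-position table for a target plot (T-plot)
#'
#' @param profile degradome profile vector.
#' @param site predicted cleavage position.
#' @return data.frame with `position`, `count`, `isCleavageSite`.
#' @export
tplotData <- function(profile, site) {
    data.frame(position = seq_along(profile), count = as.integer(profile),
               isCleavageSite = seq_along(profile) == site)
}

#' Attach per-condition degradome categories to target alignments
#'
#' @param alignments [findTargets()] output.
#' @param profilesByCondition named list (condition -> `profiles` list from
#'   [mapDegradome()]).
#' @param window site window passed to [categorizeCleavage()].
#' @return data.frame, one row per alignment x condition, with `category`,
#'   `siteAbundance`, `profileMax`, `profileMedian`.
#' @export
targetEvidence <- function(alignments, profilesByCondition, window = 1L) {
    out <- list()
    for (cond in names(profilesByCondition)) {
        profs <- profilesByCondition[[cond]]
        for (r in seq_len(nrow(alignments))) {
            tx <- alignments$transcript[r]
            prof <- profs[[tx]]
            if (is.null(prof) || sum(prof) == 0L) {
                cl <- list(category = "unsupported", siteAbundance = 0L,
                           profileMax = 0L, profileMedian = NA_real_)
            } else {
                cl <- categorizeCleavage(prof, alignments$cleavage[r],
                                         window)
            }
            out[[length(out) + 1L]] <- cbind(
                alignments[r, , drop = FALSE],
                data.frame(condition = cond, category = cl$category,
                           siteAbundance = cl$siteAbundance,
                           profileMax = cl$profileMax,
                           profileMedian = cl$profileMedian))
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Intersect degradome-supported targets between conditions
#'
#' Mirrors the contrast-intersection logic at the target level: the
#' (miRNA, transcript) pairs supported (category at most `maxCategory`) in
#' every listed condition.
#'
#' @param evidence [targetEvidence()] output.
#' @param conditions conditions that must all support the pair.
#' @param maxCategory highest category still counted as supported
#'   (default 3).
#' @return data.frame of supported `mirna` / `transcript` pairs.
#' @export
supportedTargetIntersection <- function(evidence,
                                        conditions =
                                            unique(evidence$condition),
                                        maxCategory = 3L) {
    supp <- evidence[evidence$category %in% as.character(0:maxCategory), ]
    keys <- lapply(conditions, function(cc) {
        s <- supp[supp$condition == cc, ]
        paste(s$mirna, s$transcript)
    })
    common <- Reduce(intersect, keys)
    if (!length(common))
        return(data.frame(mirna = character(), transcript = character()))
    parts <- do.call(rbind, strsplit(common, " "))
    res <- data.frame(mirna = parts[, 1], transcript = parts[, 2])
    res[order(res$mirna, res$transcript), , drop = FALSE]
}
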