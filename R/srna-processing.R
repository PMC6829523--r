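# Read cleaning, tag collapsing and length distributions.

# strict FASTQ structural validation with record-indexed errors, returning
# sequence and quality character vectors
.parseFastq <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
        stop("malformed FASTQ '", basename(path), "': truncated record ",
             length(lines) %/% 4L + 1L)
    n <- length(lines) %/% 4L
    h <- lines[seq(1L, by = 4L, length.out = n)]
    s <- lines[seq(2L, by = 4L, length.out = n)]
    p <- lines[seq(3L, by = 4L, length.out = n)]
    q <- lines[seq(4L, by = 4L, length.out = n)]
    bad <- which(!startsWith(h, "@"))
    if (length(bad))
        stop("malformed FASTQ '", basename(path), "': record ", bad[1],
             " does not start with '@'")
    bad <- which(!startsWith(p, "+"))
    if (length(bad))
        stop("malformed FASTQ '", basename(path), "': record ", bad[1],
             " lacks the '+' separator")
    bad <- which(nchar(s) != nchar(q))
    if (length(bad))
        stop("malformed FASTQ '", basename(path), "': record ", bad[1],
             " sequence/quality length mismatch")
    list(seq = s, qual = q)
}

#' Clean raw small RNA reads
#'
#' Locates the 3' adapter by its best (leftmost admissible) prefix match --
#' requiring at least `minOverlap` matching bases at up to `maxErrorRate`
#' mismatches -- removes it, and discards reads that have mean quality below
#' `minQuality`, contain an N, fall outside `[minLen, maxLen]` after
#' trimming, or exactly match a blocklist sequence (the reduced stand-in for
#' rRNA/tRNA/sn(o)RNA filtering).  Input U bases are normalised to T; output
#' is always in the DNA alphabet.
#'
#' The defaults (minimum overlap 6 nt, error rate 0.1, length 18--30, mean
#' quality Q20) follow conventional small RNA-seq practice.
#'
#' @param fastq path to a FASTQ file, or a list with elements `seq` and
#'   `qual` (character vectors) for pre-parsed reads.
#' @param adapter3 3' adapter sequence (non-empty).
#' @param minLen,maxLen post-trim length window.
#' @param minQuality minimum mean Phred quality.
#' @param minOverlap,maxErrorRate adapter-match stringency.
#' @param blocklist optional character vector / `DNAStringSet` of sequences
#'   removed by exact match after trimming.
#' @param libraryId label recorded in the stats.
#' @param qualOffset Phred offset (Sanger 33).
#' @return list with `reads` (character vector of clean inserts) and `stats`
#'   (libraryId, rawReads, cleanReads, a named `discarded` breakdown, and
#'   `lengthHistogram`, a named count vector over insert lengths).
#' @examples
#' fq <- list(seq = paste0("ACGTACGTACGTACGTACGTAC",
#'                         "TGGAATTCTCGGGTGCCAAGG"),
#'            qual = strrep("I", 43))
#' cleanReads(fq, "TGGAATTCTCGGGTGCCAAGG")$reads
#' @export
cleanReads <- function(fastq, adapter3, minLen = 18L, maxLen = 30L,
                       minQuality = 20, minOverlap = 6L, maxErrorRate = 0.1,
                       blocklist = NULL, libraryId = NA_character_,
                       qualOffset = 33L) {
    if (!nzchar(adapter3))
        stop("adapter3 must be non-empty")
    if (!(minLen > 0L && minLen <= maxLen))
        stop("need 0 < minLen <= maxLen")
    rec <- if (is.character(fastq) && length(fastq) == 1L)
        .parseFastq(fastq) else fastq
    seqs <- .normalizeSeq(rec$seq)
    raw <- length(seqs)
    if (raw == 0L)
        return(list(reads = character(0),
                    stats = list(libraryId = libraryId, rawReads = 0L,
                                 cleanReads = 0L,
                                 discarded = c(lowQuality = 0L,
                                               containsN = 0L,
                                               lengthOut = 0L,
                                               blocklist = 0L),
                                 lengthHistogram = integer(0))))
    qc <- .read_qc_cpp(seqs, rec$qual, .normalizeSeq(adapter3),
                       as.integer(minOverlap), maxErrorRate,
                       as.integer(qualOffset))
    inserts <- substr(seqs, 1L, qc$insert_len)
    lowQ <- qc$mean_q < minQuality
    hasN <- !lowQ & grepl("N", inserts, fixed = TRUE)
    ilen <- nchar(inserts)
    lenOut <- !lowQ & !hasN & (ilen < minLen | ilen > maxLen)
    block <- rep(FALSE, raw)
    if (!is.null(blocklist)) {
        bl <- .normalizeSeq(as.character(blocklist))
        block <- !lowQ & !hasN & !lenOut & inserts %in% bl
    }
    keep <- !(lowQ | hasN | lenOut | block)
    clean <- inserts[keep]
    hist <- table(factor(nchar(clean), levels = seq(minLen, maxLen)))
    list(reads = clean,
         stats = list(libraryId = libraryId, rawReads = raw,
                      cleanReads = length(clean),
                      discarded = c(lowQuality = sum(lowQ),
                                    containsN = sum(hasN),
                                    lengthOut = sum(lenOut),
                                    blocklist = sum(block)),
                      lengthHistogram = setNames(as.integer(hist),
                                                 names(hist))))
}

#' Collapse clean reads to unique tags with per-library counts
#'
#' @param cleanList named list, one character vector of clean reads per
#'   library.  All libraries must have been cleaned with identical
#'   parameters.
#' @return data.frame with columns `sequence`, `length`, one count column
#'   per library, and `total`; sorted by total count descending, ties broken
#'   lexicographically by sequence.  Counts are conserved: the column sum of
#'   each library equals its clean read count.
#' @examples
#' collapseTags(list(libA = c("ACGT", "ACGT", "TTTT"), libB = "ACGT"))
#' @export
collapseTags <- function(cleanList) {
    stopifnot(is.list(cleanList), !is.null(names(cleanList)))
    libs <- names(cleanList)
    pieces <- lapply(libs, function(l) {
        if (length(cleanList[[l]]) == 0L)
            return(NULL)
        data.table(sequence = cleanList[[l]], library = l)
    })
    dt <- rbindlist(pieces)
    if (is.null(dt) || nrow(dt) == 0L) {
        out <- data.frame(sequence = character(0), length = integer(0))
        for (l in libs) out[[l]] <- integer(0)
        out$total <- integer(0)
        return(out)
    }
    counted <- dt[, .N, by = c("sequence", "library")]
    wide <- data.table::dcast(counted, sequence ~ library,
                              value.var = "N", fill = 0L)
    for (l in setdiff(libs, names(wide)))
        data.table::set(wide, j = l, value = 0L)
    data.table::setcolorder(wide, c("sequence", libs))
    wide[, `:=`(length = nchar(sequence),
                total = rowSums(.SD)), .SDcols = libs]
    setorder(wide, -total, sequence)
    data.table::setcolorder(wide, c("sequence", "length", libs, "total"))
    as.data.frame(wide)
}

#' Per-library read-length distribution of collapsed tags
#'
#' Counts are read-weighted (a tag seen 5 times contributes 5), the analogue
#' of the classic small RNA length-distribution figure.
#'
#' @param tags output of [collapseTags()].
#' @param libraries which count columns to tabulate (default: all).
#' @return long data.frame with columns `length`, `library`, `count`.
#' @export
lengthDistribution <- function(tags,
                               libraries = setdiff(names(tags),
                                                   c("sequence", "length",
                                                     "total"))) {
    out <- lapply(libraries, function(l) {
        agg <- tapply(tags[[l]], tags$length, sum)
        data.frame(length = as.integer(names(agg)), library = l,
                   count = as.integer(agg))
    })
    do.call(rbind, out)
}
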