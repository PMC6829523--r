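# shared low-level helpers (not exported)

.BASES <- c("A", "C", "G", "T")
.IUPAC <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

# random DNA as a single character scalar
.randDNA <- function(n) {
    paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))
}

.normalizeSeq <- function(x) {
    out <- chartr("U", "T", toupper(x))
    names(out) <- names(x)
    out
}

.checkNucleotides <- function(x, what = "sequence") {
    bad <- grepl("[^ACGTU]", toupper(x))
    if (any(bad))
        stop(what, " contains non-nucleotide characters: ",
             paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
    invisible(TRUE)
}

# strand-aware sequence extraction from a DNAStringSet genome
.getSeq <- function(genome, gr) {
    out <- character(length(gr))
    chr <- as.character(seqnames(gr))
    st <- as.character(strand(gr))
    for (i in seq_along(gr)) {
        s <- subseq(genome[[chr[i]]], start(gr)[i], end(gr)[i])
        if (st[i] == "-") s <- reverseComplement(s)
        out[i] <- as.character(s)
    }
    names(out) <- names(gr)
    out
}

# in-place substring replacement on a character scalar genome
.writeSeq <- function(genomeStr, start, replacement) {
    substr(genomeStr, start, start + nchar(replacement) - 1L) <- replacement
    genomeStr
}

.writeFastq <- function(path, ids, seqs, quals) {
    stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
    con <- file(path, "w")
    on.exit(close(con))
    if (length(ids)) {
        rec <- paste0("@", ids, "\n", seqs, "\n+\n", quals)
        writeLines(rec, con)
    }
    invisible(path)
}

.writeTsv <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

# dot-bracket string -> 1-based partner vector (0 = unpaired)
.dotBracketPartner <- function(db) {
    v <- strsplit(db, "")[[1]]
    partner <- integer(length(v))
    stack <- integer(0)
    for (i in seq_along(v)) {
        if (v[i] == "(") {
            stack <- c(stack, i)
        } else if (v[i] == ")") {
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            partner[i] <- j
            partner[j] <- i
        }
    }
    partner
}
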