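# TPM normalisation, the random-sampling two-proportion DE test, candidate
# selection by contrast intersection, and the 2^-ddCt utility.

#' Build a miRNA count matrix from tag assignments
#'
#' Sums per-library tag counts over assigned miRNAs.
#'
#' @param tags [collapseTags()] output.
#' @param assignments [matchKnown()] output (tag sequence -> miRNA).
#' @param libraryInfo data.frame with columns `library`, `condition`,
#'   `replicate` matching the count columns of `tags`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay (rows: miRNAs, columns: libraries).
#' @export
mirnaCountMatrix <- function(tags, assignments, libraryInfo) {
    libs <- libraryInfo$library
    stopifnot(all(libs %in% names(tags)))
    m <- merge(assignments[, c("sequence", "mirna")],
               tags[, c("sequence", libs)], by = "sequence")
    dt <- as.data.table(m)[, lapply(.SD, sum), by = "mirna", .SDcols = libs]
    counts <- as.matrix(dt[, libs, with = FALSE])
    rownames(counts) <- dt$mirna
    storage.mode(counts) <- "integer"
    SummarizedExperiment(
        assays = list(counts = counts[order(rownames(counts)), ,
                                      drop = FALSE]),
        colData = DataFrame(libraryInfo, row.names = libs))
}

#' Transcripts-per-million normalisation
#'
#' `tpm[i, j] = counts[i, j] / N_j * 1e6` with `N_j` the library total.
#'
#' @param x count matrix or `SummarizedExperiment` with a `counts` assay.
#' @param librarySizes per-library totals; defaults to column sums.
#' @return matrix of TPM values (or the `SummarizedExperiment` with an added
#'   `tpm` assay).
#' @examples
#' tpmNormalize(matrix(c(5, 0), 2, 1,
#'                     dimnames = list(c("a", "b"), "lib1")),
#'              librarySizes = 1e6)
#' @export
tpmNormalize <- function(x, librarySizes = NULL) {
    se <- NULL
    if (is(x, "SummarizedExperiment")) {
        se <- x
        x <- assay(se, "counts")
    }
    if (any(x < 0)) stop("counts must be non-negative")
    if (is.null(librarySizes)) librarySizes <- colSums(x)
    zero <- librarySizes == 0
    if (any(zero))
        stop("library total is zero for: ",
             paste(colnames(x)[zero], collapse = ", "))
    tpm <- sweep(x, 2L, librarySizes, "/") * 1e6
    if (!is.null(se)) {
        SummarizedExperiment::assay(se, "tpm") <- tpm
        return(se)
    }
    tpm
}

#' Two-proportion random-sampling test for count differences
#'
#' The formula-level model behind MA-plot style DE calling on pooled
#' sequencing counts: with proportions `p1 = C1/N1`, `p2 = C2/N2` and the
#' pooled estimate `p = (C1+C2)/(N1+N2)`,
#' `z = (p1 - p2) / sqrt(p (1-p) (1/N1 + 1/N2))` is referred to the standard
#' normal (two-sided).  `M` and `A` are the log2 ratio and mean of the
#' pseudocounted normalised proportions (display only; the pseudocount never
#' enters the test).  Rows with `C1 + C2 == 0` get `NA` statistics and are
#' excluded from testing.
#'
#' @param C1,C2 counts in the two conditions (vectors).
#' @param N1,N2 library totals.
#' @param pseudocount added to counts for `M`/`A` only.
#' @return data.frame with columns `C1`, `C2`, `N1`, `N2`, `M`, `A`, `z`,
#'   `p`.
#' @examples
#' deTest(20, 1e6, 80, 1e6)
#' @export
deTest <- function(C1, N1, C2, N2, pseudocount = 0.5) {
    if (any(C1 < 0) || any(C2 < 0)) stop("counts must be non-negative")
    if (any(N1 <= 0) || any(N2 <= 0)) stop("totals must be positive")
    p1 <- C1 / N1
    p2 <- C2 / N2
    pp <- (C1 + C2) / (N1 + N2)
    se <- sqrt(pp * (1 - pp) * (1 / N1 + 1 / N2))
    z <- ifelse(p1 == p2, 0, (p1 - p2) / se)
    p <- 2 * pnorm(-abs(z))
    none <- (C1 + C2) == 0
    z[none] <- NA_real_
    p[none] <- NA_real_
    l1 <- log2((C1 + pseudocount) / N1)
    l2 <- log2((C2 + pseudocount) / N2)
    data.frame(C1 = C1, C2 = C2, N1 = N1, N2 = N2,
               M = l1 - l2, A = (l1 + l2) / 2, z = z, p = p)
}

#' Test one contrast on a miRNA count matrix
#'
#' Replicate libraries are pooled (summed) per condition, giving a single
#' test per miRNA per contrast; BH-adjusted q-values are reported alongside
#' the raw p-values.
#'
#' @param se `SummarizedExperiment` with a `counts` assay and a `condition`
#'   column in `colData`.
#' @param condA,condB condition labels; `condA` is the first-named
#'   condition (direction `"down"` means lower in `condA`).
#' @return data.frame, one row per miRNA: contrast, pooled counts and
#'   totals, `M`, `A`, `z`, `p`, `q`, `direction`.
#' @export
runContrast <- function(se, condA, condB) {
    cond <- colData(se)$condition
    if (!condA %in% cond || !condB %in% cond)
        stop("conditions not found in colData: ", condA, " / ", condB)
    counts <- assay(se, "counts")
    C1 <- rowSums(counts[, cond == condA, drop = FALSE])
    C2 <- rowSums(counts[, cond == condB, drop = FALSE])
    N1 <- sum(counts[, cond == condA, drop = FALSE])
    N2 <- sum(counts[, cond == condB, drop = FALSE])
    res <- deTest(C1, N1, C2, N2)
    res <- cbind(mirna = rownames(counts),
                 contrast = paste(condA, "vs", condB), res)
    res$q <- NA_real_
    tested <- !is.na(res$p)
    res$q[tested] <- p.adjust(res$p[tested], method = "BH")
    res$direction <- ifelse(res$M < 0, "down", "up")
    rownames(res) <- NULL
    res
}

#' Select differentially expressed miRNAs
#'
#' Selection is on raw `p < alpha` (the BH q-values in the results table let
#' users be stricter).
#'
#' @param results [runContrast()] output.
#' @param alpha significance level; selection is strict (`p < alpha`).
#' @return character vector of selected miRNA names.
#' @export
callDE <- function(results, alpha = 0.05) {
    sel <- !is.na(results$p) & results$p < alpha
    results$mirna[sel]
}

#' Select ISR-candidate miRNAs from two contrasts
#'
#' Candidates are the miRNAs differentially expressed in both contrasts
#' (treatment vs control and treatment vs non-inducing mutant) with the
#' stated direction in both -- repression in the ISR-inducing treatment, by
#' default.
#'
#' @param resA,resB [runContrast()] results for the two contrasts, over the
#'   same miRNA universe.
#' @param alpha significance level for each contrast.
#' @param direction `"down"` (default), `"up"`, or `"any"` to disable the
#'   direction filter.
#' @return list with elements `deA`, `deB`, `intersection`, `candidates`.
#' @export
selectIsrCandidates <- function(resA, resB, alpha = 0.05,
                                direction = c("down", "up", "any")) {
    direction <- match.arg(direction)
    deA <- callDE(resA, alpha)
    deB <- callDE(resB, alpha)
    both <- intersect(deA, deB)
    if (direction == "any") {
        cand <- both
    } else {
        dirA <- resA$direction[match(both, resA$mirna)]
        dirB <- resB$direction[match(both, resB$mirna)]
        cand <- both[dirA == direction & dirB == direction]
    }
    list(deA = deA, deB = deB, intersection = both,
         candidates = sort(cand))
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (ctTarget - ctRef) - (ctTargetCalibrator - ctRefCalibrator)`;
#' returns `2^-ddCt`.
#'
#' @param ctTarget,ctRef Ct values of target and reference gene in the
#'   sample of interest.
#' @param ctTargetCalibrator,ctRefCalibrator the same in the calibrator
#'   sample.
#' @return relative expression (1 when ddCt is 0, 0.5 when ddCt is 1).
#' @examples
#' ddctFoldChange(25, 20, 24, 20)
#' @export
ddctFoldChange <- function(ctTarget, ctRef, ctTargetCalibrator,
                           ctRefCalibrator) {
    stopifnot(all(is.finite(c(ctTarget, ctRef, ctTargetCalibrator,
                              ctRefCalibrator))))
    ddct <- (ctTarget - ctRef) - (ctTargetCalibrator - ctRefCalibrator)
    2^(-ddct)
}
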