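library(GenomicRanges)

# place a pri-miRNA and an upstream gene with a given intergenic gap
geom <- function(gap, orientation, priStrand = "+", chromLen = 60000L,
                 geneLen = 1000L) {
    if (priStrand == "+") {
        pri <- GRanges("chr1", IRanges(30000, 30150), strand = "+")
        if (orientation == "none") return(list(pri = pri, up = NULL,
                                               chromLen = chromLen))
        gs <- 30000 - gap - geneLen
        up <- GRanges("chr1", IRanges(gs, gs + geneLen - 1),
                      strand = if (orientation == "same") "+" else "-")
    } else {
        pri <- GRanges("chr1", IRanges(30000, 30150), strand = "-")
        if (orientation == "none") return(list(pri = pri, up = NULL,
                                               chromLen = chromLen))
        gs <- 30151 + gap
        up <- GRanges("chr1", IRanges(gs, gs + geneLen - 1),
                      strand = if (orientation == "same") "-" else "+")
    }
    list(pri = pri, up = up, chromLen = chromLen)
}

test_that("all six promoter geometries match the hand-written rule table", {
    cases <- expand.grid(gap = c(1000L, 3000L, 5000L),
                         orientation = c("same", "opposite"),
                         priStrand = c("+", "-"),
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cases))) {
        cs <- cases[i, ]
        g <- geom(cs$gap, cs$orientation, cs$priStrand)
        pr <- extractPromoter(g$pri, g$up, g$chromLen)
        exp <- oraclePromoterRule(cs$orientation, cs$gap)
        info <- paste(cs$orientation, cs$gap, cs$priStrand)
        expect_equal(pr$branch, exp$branch, info = info)
        expect_equal(width(pr), exp$length, info = info)
        # the promoter must abut the pri-miRNA 5' end
        if (cs$priStrand == "+")
            expect_equal(end(pr), start(g$pri) - 1L, info = info)
        else
            expect_equal(start(pr), end(g$pri) + 1L, info = info)
        expect_false(pr$clipped)
    }
    # no upstream gene at all
    g <- geom(0L, "none")
    pr <- extractPromoter(g$pri, g$up, g$chromLen)
    expect_equal(pr$branch, "default_2kb")
    expect_equal(width(pr), 2000L)
})

test_that("worked distance cases give 600 and 2500 bp promoters", {
    g <- geom(1000L, "same")
    expect_equal(width(extractPromoter(g$pri, g$up, g$chromLen)), 600L)
    g <- geom(5000L, "opposite")
    expect_equal(width(extractPromoter(g$pri, g$up, g$chromLen)), 2500L)
    g <- geom(3000L, "same")
    expect_equal(width(extractPromoter(g$pri, g$up, g$chromLen)), 2000L)
})

test_that("degenerate geometries fall back to the 2 kb branch with warning",
{
    pri <- GRanges("chr1", IRanges(30000, 30150), strand = "+")
    overlapping <- GRanges("chr1", IRanges(29900, 30050), strand = "+")
    expect_warning(pr <- extractPromoter(pri, overlapping, 60000L),
                   "overlap")
    expect_equal(pr$branch, "default_2kb")
    g <- geom(300L, "same")   # gap inside the 400 bp downstream shift
    expect_warning(pr <- extractPromoter(g$pri, g$up, g$chromLen),
                   "downstream shift")
    expect_equal(pr$branch, "default_2kb")
    # chromosome-edge clipping
    priEdge <- GRanges("chr1", IRanges(500, 650), strand = "+")
    pr <- extractPromoter(priEdge, NULL, 60000L)
    expect_true(pr$clipped)
    expect_equal(start(pr), 1L)
    expect_equal(width(pr), 499L)
})

test_that("motif scanning reports IUPAC-aware hits on both strands", {
    lib <- data.frame(name = c("CGTCA-motif", "degenerate"),
                      sequence = c("CGTCA", "GRTNC"))
    prom <- c(p1 = paste0(strrep("A", 9), "CGTCA", strrep("A", 6)))
    hits <- scanMotifs(prom, lib[1, , drop = FALSE])
    expect_equal(hits$offset, 10L)
    expect_equal(hits$strand, "+")
    expect_equal(hits$matched, "CGTCA")
    # TGACG is the reverse complement of CGTCA
    hits <- scanMotifs(c(p1 = "AAAATGACGAAAA"), lib[1, , drop = FALSE])
    expect_equal(hits$strand, "-")
    expect_equal(hits$offset, 5L)
    # IUPAC degeneracy in the pattern
    hits <- scanMotifs(c(p1 = "TTGATACTT"), lib[2, , drop = FALSE])
    expect_equal(hits$offset, 3L)
    expect_error(scanMotifs(prom, data.frame(name = "bad",
                                             sequence = "CGT!A")),
                 "non-IUPAC")
})

test_that("reverse-complementing a promoter swaps strand labels exactly", {
    set.seed(31)
    lib <- defaultMotifLibrary()
    prom <- paste0(randomSeq(40), "CGTCA", randomSeq(30), "TGACG",
                   randomSeq(40), "CCATCTTTTT", randomSeq(20))
    fwd <- scanMotifs(c(p = prom), lib)
    rev <- scanMotifs(c(p = oracleRevcomp(prom)), lib)
    L <- nchar(prom)
    mapBack <- data.frame(
        motif = rev$motif,
        strand = ifelse(rev$strand == "+", "-", "+"),
        offset = L - rev$offset - nchar(rev$matched) + 2L)
    expect_setequal(paste(fwd$motif, fwd$strand, fwd$offset),
                    paste(mapBack$motif, mapBack$strand, mapBack$offset))
})

test_that("planted cis-elements are recovered exactly on the fixture", {
    fx <- smallFixture()
    mt <- as.data.frame(mirnaTable(fx))
    pm <- truth(fx)@plantedMotifs
    proms <- list()
    for (pid in unique(pm$pri)) {
        i <- match(pid, mt$priId)
        pri <- GRanges(mt$chrom[i], IRanges(mt$start[i], mt$end[i]),
                       strand = mt$strand[i])
        up <- if (is.na(mt$geneStart[i])) NULL else
            GRanges(mt$chrom[i], IRanges(mt$geneStart[i], mt$geneEnd[i]),
                    strand = mt$geneStrand[i])
        pr <- extractPromoter(pri, up, smallConfig()@genomeLength)
        names(pr) <- pid
        proms[[pid]] <- pr
    }
    seqs <- vapply(proms, function(pr)
        getFromNamespace(".getSeq", "mirISR")(genomeSequence(fx),
                                              pr)[[1]], "")
    hits <- scanMotifs(seqs, defaultMotifLibrary())
    expect_setequal(paste(hits$promoter, hits$motif, hits$strand,
                          hits$offset),
                    paste(pm$pri, pm$motif, pm$strand, pm$offset))
})

test_that("defense-element summaries aggregate hit categories", {
    lib <- defaultMotifLibrary()
    empty <- classifyDefenseElements(
        data.frame(promoter = character(), motif = character(),
                   strand = character(), offset = integer(),
                   matched = character()),
        lib, promoterIds = "p1")
    expect_false(empty$anyDefenseElement)
    one <- classifyDefenseElements(
        data.frame(promoter = "p1", motif = "CGTCA-motif", strand = "+",
                   offset = 5L, matched = "CGTCA"), lib)
    expect_true(one$hasMeJA)
    expect_false(one$hasSA || one$hasDefenseStress || one$allThree)
    # fixture: every planted-candidate promoter carries a defense element
    # and the two fully planted ones carry all three categories
    run <- smallRunDir()
    ds <- readRun(run, "defense_summary.tsv")
    tr <- read.delim(file.path(smallFixtureDir(), "truth.tsv"))
    plantedPri <- paste0("pri-", sub("-[35]p$", "",
                                     tr$name[tr$record == "repressed"]))
    dsp <- ds[ds$promoter %in% plantedPri, ]
    expect_true(all(dsp$anyDefenseElement))
    expect_setequal(dsp$promoter[dsp$allThree],
                    c("pri-zma-miR169a", "pri-zma-miR169i"))
})
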