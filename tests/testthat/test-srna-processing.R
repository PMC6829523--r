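ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

fq <- function(seqs, quals = NULL) {
    if (is.null(quals)) quals <- strrep("I", nchar(seqs))
    list(seq = seqs, qual = quals)
}

test_that("the 3' adapter is located and removed", {
    insert <- "ACGTACGTACGTACGTACGTAC"  # 22 nt
    cl <- cleanReads(fq(paste0(insert, ADAPTER)), ADAPTER)
    expect_equal(cl$reads, insert)
    # partial adapter at the read end, above the minimum overlap
    cl <- cleanReads(fq(paste0(insert, substr(ADAPTER, 1, 8))), ADAPTER)
    expect_equal(cl$reads, insert)
    # adapter dimer collapses to an empty insert and is length-filtered
    cl <- cleanReads(fq(paste0(ADAPTER, ADAPTER)), ADAPTER)
    expect_length(cl$reads, 0)
    expect_equal(unname(cl$stats$discarded["lengthOut"]), 1L)
})

test_that("contamination and quality rules discard reads", {
    insert <- "ACGTACGTACGTACGTACGTAC"
    nread <- paste0(substr(insert, 1, 10), "N",
                    substr(insert, 12, 22), ADAPTER)
    cl <- cleanReads(fq(nread), ADAPTER)
    expect_length(cl$reads, 0)
    expect_equal(unname(cl$stats$discarded["containsN"]), 1L)
    low <- fq(paste0(insert, ADAPTER),
              strrep("#", nchar(insert) + nchar(ADAPTER)))
    cl <- cleanReads(low, ADAPTER)
    expect_equal(unname(cl$stats$discarded["lowQuality"]), 1L)
    # blocklist removal by exact match
    cl <- cleanReads(fq(paste0(insert, ADAPTER)), ADAPTER,
                     blocklist = insert)
    expect_equal(unname(cl$stats$discarded["blocklist"]), 1L)
    # U bases are normalised to T on input
    cl <- cleanReads(fq(paste0(chartr("T", "U", insert), ADAPTER)),
                     ADAPTER)
    expect_equal(cl$reads, insert)
})

test_that("malformed FASTQ records raise errors naming the record", {
    d <- tempfile(fileext = ".fastq")
    writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), d)
    expect_error(cleanReads(d, ADAPTER), "truncated record 2")
    writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), d)
    expect_error(cleanReads(d, ADAPTER), "record 2 does not start")
    writeLines(c("@r1", "ACGT", "+", "IIIII"), d)
    expect_error(cleanReads(d, ADAPTER), "record 1 sequence/quality")
    expect_error(cleanReads(fq("ACGT"), ""), "non-empty")
    expect_error(cleanReads(fq("ACGT"), ADAPTER, minLen = 0),
                 "0 < minLen")
})

test_that("counts are conserved through cleaning and collapsing", {
    cfg <- smallConfig()
    fqf <- file.path(smallFixtureDir(), "control_rep1.fastq")
    cl <- cleanReads(fqf, cfg@adapter3, libraryId = "control_rep1")
    s <- cl$stats
    expect_equal(s$rawReads, s$cleanReads + sum(s$discarded))
    expect_gt(s$discarded[["lowQuality"]], 0)  # planted QC spice
    expect_gt(s$discarded[["containsN"]], 0)
    expect_equal(sum(s$lengthHistogram), s$cleanReads)
    tags <- collapseTags(list(control_rep1 = cl$reads, empty = character(0)))
    expect_equal(sum(tags$control_rep1), s$cleanReads)
    expect_equal(sum(tags$empty), 0L)
    ld <- lengthDistribution(tags)
    expect_equal(sum(ld$count[ld$library == "control_rep1"]), s$cleanReads)
})

test_that("cleaning adapter-free clean reads is a no-op", {
    set.seed(42)
    reads <- vapply(rep(24, 400), randomSeq, "")
    # drop reads whose 3' end could partially match the adapter prefix
    ok <- !vapply(reads, function(s) {
        any(vapply(6:12, function(o)
            substr(s, 25 - o, 24) == substr(ADAPTER, 1, o), TRUE))
    }, TRUE)
    reads <- reads[ok & !grepl(substr(ADAPTER, 1, 6), reads, fixed = TRUE)]
    cl1 <- cleanReads(fq(reads), ADAPTER)
    expect_identical(cl1$reads, unname(reads))
    cl2 <- cleanReads(fq(cl1$reads), ADAPTER)
    expect_identical(cl2$reads, cl1$reads)
})

test_that("tags sort by total count then sequence", {
    tags <- collapseTags(list(
        l1 = c("CCCC", "AAAA", "TTTT", "AAAA"),
        l2 = c("GGGG", "AAAA", "TTTT")))
    expect_equal(tags$sequence[1], "AAAA")        # total 3
    expect_equal(tags$total[1], 3L)
    expect_equal(tags$sequence[2], "TTTT")        # total 2
    # ties at total 1 break lexicographically
    expect_equal(tags$sequence[3:4], c("CCCC", "GGGG"))
    expect_equal(tags$l1, c(2L, 1L, 1L, 0L))
})

test_that("length histograms are read-weighted, not tag-weighted", {
    tags <- collapseTags(list(l1 = c(rep("AAAAA", 5), "CCCCC", "GGGGGG")))
    ld <- lengthDistribution(tags)
    expect_equal(ld$count[ld$length == 5], 6L)   # 5 + 1 reads, 2 tags
    expect_equal(ld$count[ld$length == 6], 1L)
    # single length bin for uniform input
    tags24 <- collapseTags(list(l1 = vapply(rep(24, 10), randomSeq, "")))
    ld24 <- lengthDistribution(tags24)
    expect_equal(nrow(ld24), 1L)
    expect_equal(ld24$length, 24L)
})
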