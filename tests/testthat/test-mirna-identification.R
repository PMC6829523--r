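test_that("tags match known matures 5'-anchored with bounded shift", {
    ref <- c(`zma-miR169a-5p` = "TAGCCAAGGATGACTTGCCTGC",
             `zma-miR399j` = "GGGCAACTTCTCCTTTGGCAGA")
    expect_equal(matchKnown("TAGCCAAGGATGACTTGCCTGC", ref)$mirna,
                 "zma-miR169a-5p")
    # 3' heterogeneity within +/- 2 nt
    expect_equal(matchKnown("TAGCCAAGGATGACTTGCCT", ref)$mirna,
                 "zma-miR169a-5p")
    expect_equal(matchKnown("TAGCCAAGGATGACTTGCCTGCAA", ref)$lengthDiff, 2L)
    expect_equal(nrow(matchKnown("TAGCCAAGGATGACTTGC", ref)), 0L)  # -4 nt
    # mismatches rejected at the default tolerance
    bad <- "TAGCCAAGGATGACTTGCCAAA"
    expect_equal(nrow(matchKnown(bad, ref, maxMismatches = 0)), 0L)
    expect_equal(nrow(matchKnown(bad, ref, maxMismatches = 3)), 1L)
    # ties break by reference order
    ref2 <- c(a = "ACGTACGTACGTACGTACGTAA", b = "ACGTACGTACGTACGTACGTAA")
    expect_error(matchKnown("x", setNames(ref2, c("a", "a"))), "duplicate")
    expect_equal(matchKnown("ACGTACGTACGTACGTACGTAA", ref2)$mirna, "a")
})

test_that("family labels parse from miRBase-style names", {
    expect_equal(assignFamily("zma-miR169a-5p"), "miR169")
    expect_equal(assignFamily("zma-miR399j"), "miR399")
    expect_equal(assignFamily("novel_mir_17"), "novel_mir_17")
    expect_warning(out <- assignFamily("scrambled!!"), "unparseable")
    expect_equal(out, "unknown")
})

test_that("hairpin folding maximises pairs and matches brute force", {
    f <- foldHairpin("GGGAAACCC")
    expect_equal(f$pairs, 3L)
    expect_equal(f$structure, "(((...)))")
    expect_equal(f$backend, "nussinov")
    expect_equal(foldHairpin(strrep("A", 60))$pairs, 0L)
    # perfect 30 bp inverted repeat with a 4 nt loop
    set.seed(3)
    arm <- randomSeq(30)
    hp <- paste0(arm, "AAAA", oracleRevcomp(arm))
    expect_gte(foldHairpin(hp)$pairs, 30L)
    expect_error(foldHairpin("ACGTX"), "non-nucleotide")
    # brute-force enumeration agreement on short random sequences
    set.seed(4)
    for (i in 1:15) {
        s <- randomSeq(sample(8:12, 1))
        expect_equal(foldHairpin(s)$pairs, oracleMaxPairs(s), info = s)
    }
})

test_that("fixture matures are recovered with no background assignments", {
    run <- smallRunDir()
    fx <- smallFixture()
    asg <- readRun(run, "known_mirnas.tsv")
    expect_setequal(unique(asg$mirna), names(matureSequences(fx)))
    # every assigned tag is a 5'-anchored variant of its mature
    ref <- as.character(matureSequences(fx))
    k <- pmin(nchar(asg$sequence), nchar(ref[asg$mirna]))
    expect_true(all(substring(asg$sequence, 1, k) ==
                    substring(ref[asg$mirna], 1, k)))
    expect_true(all(abs(asg$lengthDiff) <= 2))
})

test_that("planted novel hairpins are called at the right loci and strands",
{
    run <- smallRunDir()
    fx <- smallFixture()
    nov <- readRun(run, "novel_candidates.tsv")
    nl <- truth(fx)@novelLoci
    expect_equal(nrow(nov), length(nl))
    got <- GenomicRanges::GRanges(nov$chrom,
                                  IRanges::IRanges(nov$start, nov$end),
                                  strand = nov$strand)
    ov <- GenomicRanges::findOverlaps(got, nl)
    expect_equal(length(ov), length(nl))   # strand-aware 1:1 overlap
    expect_true(all(nov$pairedMature >= 16))
    expect_true(all(nov$pairingFraction >= 0.55))
    expect_true(all(nchar(nov$precursorSeq) >= 58 &
                    nchar(nov$precursorSeq) <= 250))
    # known/novel exclusivity: candidates never overlap known pri loci
    ann <- annotationRanges(fx)
    pris <- ann[ann$type == "miRNA_primary_transcript"]
    expect_false(any(IRanges::overlapsAny(got, pris,
                                          ignore.strand = TRUE)))
})

test_that("tags in unstructured sequence are mostly rejected", {
    rejected <- 0L
    for (s in 1:25) {
        set.seed(1000 + s)
        g <- randomSeq(4000)
        tag <- substr(g, 1500, 1521)
        tags <- data.frame(sequence = tag, length = 22L, lib1 = 10L,
                           total = 10L)
        cand <- callNovel(tags, Biostrings::DNAStringSet(c(chr1 = g)))
        if (nrow(cand) == 0L) rejected <- rejected + 1L
    }
    # random sequence occasionally contains a genuine >=16 bp stem, so the
    # structural filter alone rejects most (not all) background tags
    expect_gte(rejected, 20L)
})

test_that("repeat-like tags are skipped", {
    set.seed(9)
    unit <- randomSeq(22)
    g <- paste(rep(c(unit, randomSeq(20)), 30), collapse = "")
    tags <- data.frame(sequence = unit, length = 22L, lib1 = 50L,
                       total = 50L)
    expect_message(
        cand <- callNovel(tags, Biostrings::DNAStringSet(c(chr1 = g))),
        "repeat-like")
    expect_equal(nrow(cand), 0L)
})
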