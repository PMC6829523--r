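test_that("fixture generation is deterministic for a fixed config", {
    fx1 <- makeGenome(smallConfig())
    fx2 <- makeGenome(smallConfig())
    expect_identical(as.character(genomeSequence(fx1)),
                     as.character(genomeSequence(fx2)))
    expect_identical(as.data.frame(mirnaTable(fx1)),
                     as.data.frame(mirnaTable(fx2)))
    expect_identical(truth(fx1)@trueTargets, truth(fx2)@trueTargets)
    expect_identical(truth(fx1)@plantedMotifs, truth(fx2)@plantedMotifs)
})

test_that("written fixture files are byte-identical between runs", {
    d2 <- file.path(tempdir(), "mirisr-fixture-repeat")
    unlink(d2, recursive = TRUE)
    writeFixture(smallConfig(), d2)
    f1 <- list.files(smallFixtureDir(), full.names = TRUE)
    f2 <- file.path(d2, basename(f1))
    expect_true(all(file.exists(f2)))
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
    unlink(d2, recursive = TRUE)
})

test_that("annotation carries one pri-miRNA feature per known locus", {
    fx <- smallFixture()
    ann <- annotationRanges(fx)
    expect_equal(sum(ann$type == "miRNA_primary_transcript"),
                 smallConfig()@nKnownMirnas)
    expect_equal(sum(ann$type == "miRNA"), smallConfig()@nKnownMirnas)
})

test_that("precursor lengths stay in the 58-247 nt hairpin range", {
    lens <- mirnaTable(smallFixture())$precLen
    expect_true(all(lens >= 58 & lens <= 247))
})

test_that("a genome too small for the requested loci is a sizing error", {
    cfg <- simConfig(seed = 1, genomeLength = 5e4, nKnownMirnas = 30L)
    expect_error(makeGenome(cfg), "too small")
})

test_that("planted truth is internally consistent", {
    fx <- smallFixture()
    tr <- truth(fx)
    expect_true(all(tr@repressedMirnas %in% names(matureSequences(fx))))
    tt <- tr@trueTargets
    txw <- setNames(Biostrings::width(transcriptSequences(fx)),
                    names(transcriptSequences(fx)))
    expect_true(all(tt$transcript %in% names(txw)))
    expect_true(all(tt$cleavagePos >= 1 &
                    tt$cleavagePos <= txw[tt$transcript]))
    # every planted motif lies inside the promoter the rules return
    mt <- as.data.frame(mirnaTable(fx))
    for (r in seq_len(nrow(tr@plantedMotifs))) {
        pm <- tr@plantedMotifs[r, ]
        i <- match(pm$pri, mt$priId)
        pri <- GenomicRanges::GRanges(mt$chrom[i],
                                      IRanges::IRanges(mt$start[i],
                                                       mt$end[i]),
                                      strand = mt$strand[i])
        up <- if (is.na(mt$geneStart[i])) NULL else
            GenomicRanges::GRanges(mt$chrom[i],
                                   IRanges::IRanges(mt$geneStart[i],
                                                    mt$geneEnd[i]),
                                   strand = mt$geneStrand[i])
        prom <- extractPromoter(pri, up, smallConfig()@genomeLength)
        expect_lte(pm$offset + 9, GenomicRanges::width(prom))
    }
})

test_that("simulated counts repress the planted set only in the treatment",
{
    cfg <- simConfig(seed = 5, nKnownMirnas = 30L, nNovelMirnas = 0L,
                     depthPerLibrary = 1e6, dispersion = 0)
    se <- simulateCounts(cfg)
    counts <- SummarizedExperiment::assay(se)
    cond <- SummarizedExperiment::colData(se)$condition
    rep <- SummarizedExperiment::rowData(se)$repressed
    expect_equal(sum(rep), 4L)
    trt <- rowMeans(counts[rep, cond == "FZB42", drop = FALSE])
    ctl <- rowMeans(counts[rep, cond == "control", drop = FALSE])
    mut <- rowMeans(counts[rep, cond == "mutant", drop = FALSE])
    expect_true(all(ctl / trt > 3 & ctl / trt < 5))
    expect_true(all(abs(log2(mut / ctl)) < 0.3))
})

test_that("read lengths track the configured distribution within 3 points",
{
    cfg <- smallConfig()
    fq <- file.path(smallFixtureDir(), "FZB42_rep1.fastq")
    cl <- cleanReads(fq, cfg@adapter3)
    emp <- table(factor(nchar(cl$reads),
                        levels = names(cfg@lengthDist))) / length(cl$reads)
    expect_true(all(abs(as.numeric(emp) - as.numeric(cfg@lengthDist))
                    <= 0.03))
})

test_that("degradome tags pile at true sites and vanish at zero signal", {
    fx <- smallFixture()
    cfg <- smallConfig()
    d <- file.path(tempdir(), "mirisr-degradome-test")
    dg <- simulateDegradome(cfg, fx, d)
    expect_equal(nrow(dg), 3L)
    prof <- mapDegradome(dg$path[1], transcriptSequences(fx))$profiles
    tt <- truth(fx)@trueTargets
    for (r in seq_len(nrow(tt)))
        expect_equal(categorizeCleavage(prof[[tt$transcript[r]]],
                                        tt$cleavagePos[r])$category, "0")
    # zero signal: no pile-up anywhere near the planted sites
    cfg0 <- simConfig(seed = 101L, genomeLength = 1.5e5,
                      nKnownMirnas = 12L, nNovelMirnas = 3L,
                      nTranscripts = 20L, depthPerLibrary = 8000,
                      degradomeSignal = 0)
    dg0 <- simulateDegradome(cfg0, fx, d)
    prof0 <- mapDegradome(dg0$path[1], transcriptSequences(fx))$profiles
    for (r in seq_len(nrow(tt))) {
        p <- prof0[[tt$transcript[r]]]
        cl <- categorizeCleavage(p, tt$cleavagePos[r])
        expect_lte(cl$siteAbundance, 1)
        expect_false(cl$category %in% c("0", "1") && cl$siteAbundance > 1)
    }
    unlink(d, recursive = TRUE)
})

test_that("the null configuration produces no systematic condition shift", {
    cfg <- simConfig(seed = 11, nKnownMirnas = 200L, nNovelMirnas = 0L,
                     repressedSet = character(0), repressionFactor = 1,
                     dispersion = 0)
    se <- simulateCounts(cfg)
    res <- runContrast(se, "FZB42", "control")
    expect_lt(abs(mean(res$p < 0.05, na.rm = TRUE) - 0.05), 0.05)
    expect_lt(abs(mean(res$M, na.rm = TRUE)), 0.05)
})
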