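test_that("duplex scores follow the plant penalty rules", {
    set.seed(41)
    m <- randomSeq(22)
    expect_equal(scoreDuplex(m, oracleRevcomp(m))$score, 0)
    # G:U at miRNA position 5 inside the doubled 2-13 region: 0.5 x 2
    m2 <- m
    substr(m2, 5, 5) <- "G"
    win <- oracleRevcomp(m2)
    p <- nchar(win) + 1 - 5
    substr(win, p, p) <- "T"     # G:T wobble opposite position 5
    expect_equal(scoreDuplex(m2, win)$score, 1.0)
    expect_equal(substr(scoreDuplex(m2, win)$pairing, 5, 5), "o")
    # plain mismatch at position 20, outside the doubled region
    m3 <- m
    win3 <- oracleRevcomp(m3)
    p3 <- nchar(win3) + 1 - 20
    old <- substr(win3, p3, p3)
    substr(win3, p3, p3) <- c(A = "C", C = "A", G = "A", T = "C")[[
        chartr("ACGT", "TGCA", substr(m3, 20, 20))]]
    sc <- scoreDuplex(m3, win3)
    expect_equal(sc$score, 1.0)
    expect_equal(substr(sc$pairing, 20, 20), ".")
    expect_error(scoreDuplex("ACGTN" , "ACGT"), "non-nucleotide")
    expect_error(scoreDuplex(randomSeq(10), randomSeq(10)), "18-26")
})

test_that("duplex scoring equals the exhaustive enumeration oracle", {
    set.seed(42)
    for (i in 1:100) {
        m <- randomSeq(21)
        w <- randomSeq(sample(20:22, 1))
        expect_equal(scoreDuplex(m, w)$score, oracleDuplexScore(m, w),
                     info = paste(m, w))
    }
})

test_that("target search finds embedded sites at the slicing register", {
    set.seed(43)
    m <- randomSeq(22)
    tx <- paste0(randomSeq(200), oracleRevcomp(m), randomSeq(150))
    tg <- findTargets(setNames(m, "mir"), setNames(tx, "tx"))
    hit <- tg[tg$score == 0, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$start, 201L)
    # window [201, 222]; miRNA position 10 pairs transcript base e - 9
    expect_equal(hit$cleavage, 222L - 9L)
    expect_error(findTargets(setNames(m, "mir"),
                             Biostrings::DNAStringSet()), "empty")
})

test_that("degradome tags build conserved 5'-end profiles", {
    set.seed(44)
    txs <- Biostrings::DNAStringSet(c(t1 = randomSeq(300),
                                      t2 = randomSeq(250)))
    tag <- as.character(Biostrings::subseq(txs[["t1"]], 100, 124))
    md <- mapDegradome(c(tag, tag, randomSeq(25)), txs)
    expect_equal(md$profiles$t1[100], 2L)
    expect_equal(sum(unlist(md$profiles)), md$stats$mapped)
    expect_equal(md$stats$unmapped, 1L)
    # a prefix shared by two transcripts counts once per transcript
    shared <- randomSeq(25)
    txs2 <- Biostrings::DNAStringSet(
        c(a = paste0(randomSeq(50), shared, randomSeq(30)),
          b = paste0(shared, randomSeq(60))))
    md2 <- mapDegradome(shared, txs2)
    expect_equal(md2$profiles$a[51], 1L)
    expect_equal(md2$profiles$b[1], 1L)
    expect_equal(md2$stats$multiTranscript, 1L)
})

test_that("cleavage categories follow the published rule set", {
    expect_equal(categorizeCleavage(c(0, 0, 9, 0, 1), 3)$category, "0")
    expect_equal(categorizeCleavage(c(0, 9, 9, 0, 0), 3)$category, "1")
    # a = 3 < max 10, above the expressed median 2 -> category 2
    prof <- c(10, 0, 3, 0, 1, 2, 2)
    expect_equal(categorizeCleavage(prof, 3)$category, "2")
    # a = 1 below the maximum -> category 4
    expect_equal(categorizeCleavage(c(10, 0, 0, 0, 1), 5)$category, "4")
    # ties at the median read strictly -> category 3
    expect_equal(categorizeCleavage(c(10, 0, 2, 0, 2, 2), 3)$category, "3")
    expect_equal(categorizeCleavage(c(0, 0, 0), 2)$category, "unsupported")
    # the +/-1 window picks up an off-by-one register
    expect_equal(categorizeCleavage(c(0, 0, 9, 0, 0), 2)$category, "0")
    expect_equal(categorizeCleavage(c(0, 0, 9, 0, 0), 2,
                                    window = 0)$category, "unsupported")
    expect_error(categorizeCleavage(c(1, 2), 5), "outside")
    # two planted sites with equal signal share the maximum -> category 1
    tie <- integer(60); tie[20] <- 7L; tie[45] <- 7L
    expect_equal(categorizeCleavage(tie, 20)$category, "1")
    expect_equal(categorizeCleavage(tie, 45)$category, "1")
})

test_that("raising the site abundance never worsens the category", {
    rank <- c(unsupported = 6, `4` = 5, `3` = 4, `2` = 3, `1` = 2, `0` = 1)
    set.seed(45)
    for (i in 1:200) {
        prof <- rpois(20, 1.2)
        site <- sample(20, 1)
        base <- categorizeCleavage(prof, site, window = 0)
        prof2 <- prof
        prof2[site] <- prof2[site] + sample(1:5, 1)
        up <- categorizeCleavage(prof2, site, window = 0)
        expect_lte(rank[[up$category]], rank[[base$category]])
    }
})

test_that("T-plot tables carry positions, counts and the site flag", {
    prof <- c(0, 3, 1, 0)
    tp <- tplotData(prof, 2)
    expect_equal(nrow(tp), length(prof))
    expect_equal(sum(tp$count), sum(prof))
    expect_equal(which(tp$isCleavageSite), 2L)
})

test_that("evidence tables and cross-condition support behave", {
    aln <- data.frame(mirna = c("m1", "m2"), transcript = c("t1", "t2"),
                      start = c(10L, 20L), width = c(22L, 22L),
                      score = c(0, 1), cleavage = c(22L, 32L),
                      pairing = c("|", "|"))
    profs <- list(
        A = list(t1 = {p <- integer(60); p[22] <- 9L; p},
                 t2 = {p <- integer(60); p[32] <- 5L; p[10] <- 9L; p}),
        B = list(t1 = {p <- integer(60); p[22] <- 4L; p},
                 t2 = integer(60)))
    ev <- targetEvidence(aln, profs)
    expect_equal(nrow(ev), 4L)
    expect_equal(ev$category[ev$condition == "A" & ev$mirna == "m1"], "0")
    expect_equal(ev$category[ev$condition == "B" & ev$mirna == "m2"],
                 "unsupported")
    supp <- supportedTargetIntersection(ev, c("A", "B"))
    expect_equal(supp$mirna, "m1")   # m2 unsupported in B
    expect_equal(supportedTargetIntersection(ev, "A")$mirna, c("m1", "m2"))
})
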