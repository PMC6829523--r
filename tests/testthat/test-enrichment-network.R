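test_that("hypergeometric enrichment matches exact arithmetic", {
    ann <- data.frame(gene = paste0("g", 1:20),
                      term = rep(c("T1", "T2", "T3", "T4"), each = 5))
    # all five T1 genes drawn in a 5-gene set from a 20-gene universe
    res <- enrichTargets(paste0("g", 1:5), ann)
    expect_equal(res$p[res$term == "T1"], 1 / choose(20, 5))
    expect_equal(res$p[res$term == "T1"], 1 / 15504)
    # target set equal to the universe leaves nothing enrichable
    resAll <- enrichTargets(paste0("g", 1:20), ann)
    expect_true(all(resAll$p == 1))
    expect_error(enrichTargets("g1", ann, universe = character(0)),
                 "empty")
    expect_warning(enrichTargets(c("g1", "zzz"), ann), "outside")
})

test_that("enrichment p-values equal the combinatorial oracle for N <= 25",
{
    set.seed(51)
    for (i in 1:25) {
        N <- sample(8:25, 1)
        genes <- paste0("g", seq_len(N))
        terms <- paste0("T", sample(1:4, N, replace = TRUE))
        ann <- data.frame(gene = genes, term = terms)
        n <- sample(2:(N - 1), 1)
        targets <- sample(genes, n)
        res <- enrichTargets(targets, ann)
        for (r in seq_len(nrow(res)))
            expect_equal(res$p[r],
                         oracleHyperP(res$k[r], res$K[r], res$n[r],
                                      res$N[r]))
        # BH q is monotone along the p-ranking
        expect_true(all(diff(res$q) >= -1e-12))
        expect_true(all(res$q >= res$p - 1e-12))
    }
})

test_that("the planted defense term ranks first on the fixture", {
    run <- smallRunDir()
    enr <- readRun(run, "enrichment.tsv")
    expect_equal(enr$name[1], "defense response")
    supp <- readRun(run, "supported_targets.tsv")
    tr <- read.delim(file.path(smallFixtureDir(), "truth.tsv"))
    cand <- readRun(run, "candidates.tsv")$mirna
    tt <- tr[tr$record == "target" & tr$name %in% cand, ]
    expect_setequal(paste(supp$mirna, supp$transcript),
                    paste(tt$name, tt$transcript))
})

test_that("the regulatory network keeps its bipartite shape", {
    ev <- data.frame(mirna = c("m1", "m2", "m3", "m1"),
                     transcript = c("t1", "t1", "t1", "t2"),
                     category = c("0", "1", "2", "4"))
    enr <- data.frame(term = c("GO:1", "GO:2"), q = c(0.01, 0.5))
    ann <- data.frame(gene = c("t1", "t2"), term = c("GO:1", "GO:2"))
    g <- buildNetwork(c("m1", "m2", "m3"), ev, enr, ann)
    expect_equal(igraph::vcount(g), 5L)  # 3 miRNAs + t1 + GO:1
    expect_equal(igraph::degree(g, "t1"), c(t1 = 4))
    types <- igraph::vertex_attr(g, "type")
    expect_false("GO:2" %in% igraph::V(g)$name)   # no orphan terms
    # node count arithmetic
    expect_equal(igraph::vcount(g),
                 sum(types == "mirna") + sum(types == "target") +
                 sum(types == "term"))
    # nothing supported -> empty network
    g0 <- buildNetwork("mX", ev, enr, ann)
    expect_equal(igraph::vcount(g0), 0L)
})

test_that("networks round-trip through SIF and GraphML", {
    ev <- data.frame(mirna = c("m1", "m2"), transcript = c("t1", "t2"),
                     category = c("0", "0"))
    enr <- data.frame(term = "GO:1", q = 0.001)
    ann <- data.frame(gene = "t1", term = "GO:1")
    g <- buildNetwork(c("m1", "m2"), ev, enr, ann)
    sif <- tempfile(fileext = ".sif")
    gml <- tempfile(fileext = ".graphml")
    exportNetwork(g, sif, "sif")
    exportNetwork(g, gml, "graphml")
    expect_equal(length(readLines(sif)), igraph::ecount(g))
    g2 <- importNetwork(sif, "sif")
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
    g3 <- importNetwork(gml, "graphml")
    expect_setequal(igraph::V(g3)$name, igraph::V(g)$name)
    expect_equal(igraph::ecount(g3), igraph::ecount(g))
    # empty network still writes a valid (empty) file
    g0 <- igraph::make_empty_graph(directed = FALSE)
    exportNetwork(g0, sif, "sif")
    expect_equal(igraph::vcount(importNetwork(sif, "sif")), 0L)
    expect_error(exportNetwork(g, sif, "dot"))
})
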