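# End-to-end orchestration from a single validated config, with per-stage
# checkpoints and a run manifest.

.KNOWN_TOP <- c("version", "seed", "outdir", "inputs", "contrasts",
                "parameters", "stages")
.KNOWN_INPUTS <- c("genome", "annotation", "mature", "transcriptome",
                   "go_annotation", "motifs", "libraries", "degradome")
.STAGES <- c("collapse", "identify", "de", "candidates", "promoter",
             "scan", "targets", "degradome", "enrich", "network")

#' Validate a pipeline configuration
#'
#' Schema, file-existence and cross-field checks (for example, contrasts
#' must reference declared library conditions).  Unknown keys are rejected.
#'
#' @param config a config list, or the path to a YAML config.
#' @return character vector of problems; empty when the config is valid.
#' @export
validateConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    probs <- character()
    unknown <- setdiff(names(config), .KNOWN_TOP)
    if (length(unknown))
        probs <- c(probs, paste0("unknown config key(s): ",
                                 paste(unknown, collapse = ", ")))
    inp <- config$inputs
    if (is.null(inp)) {
        probs <- c(probs, "missing 'inputs' block")
        return(probs)
    }
    unknown <- setdiff(names(inp), .KNOWN_INPUTS)
    if (length(unknown))
        probs <- c(probs, paste0("unknown inputs key(s): ",
                                 paste(unknown, collapse = ", ")))
    for (key in c("genome", "annotation", "mature", "transcriptome",
                  "go_annotation")) {
        if (is.null(inp[[key]]))
            probs <- c(probs, paste0("missing inputs$", key))
        else if (!file.exists(inp[[key]]))
            probs <- c(probs, paste0("inputs$", key, " not found: ",
                                     inp[[key]]))
    }
    if (!is.null(inp$motifs) && !file.exists(inp$motifs))
        probs <- c(probs, paste0("inputs$motifs not found: ", inp$motifs))
    conds <- character()
    if (is.null(inp$libraries) || !length(inp$libraries)) {
        probs <- c(probs, "inputs$libraries must list at least one library")
    } else {
        for (i in seq_along(inp$libraries)) {
            lb <- inp$libraries[[i]]
            miss <- setdiff(c("id", "condition", "replicate", "fastq"),
                            names(lb))
            if (length(miss)) {
                probs <- c(probs, paste0("library ", i, " missing field(s): ",
                                         paste(miss, collapse = ", ")))
                next
            }
            if (!file.exists(lb$fastq))
                probs <- c(probs, paste0("library ", lb$id,
                                         " fastq not found: ", lb$fastq))
            conds <- c(conds, lb$condition)
        }
    }
    if (!is.null(inp$degradome)) {
        for (i in seq_along(inp$degradome)) {
            dg <- inp$degradome[[i]]
            if (is.null(dg$condition) || is.null(dg$fasta)) {
                probs <- c(probs, paste0("degradome entry ", i,
                                         " needs condition and fasta"))
                next
            }
            if (!file.exists(dg$fasta))
                probs <- c(probs, paste0("degradome fasta not found: ",
                                         dg$fasta))
            if (length(conds) && !dg$condition %in% conds)
                probs <- c(probs, paste0("degradome condition '",
                                         dg$condition,
                                         "' matches no library condition"))
        }
    }
    if (is.null(config$contrasts) || length(config$contrasts) != 2L) {
        probs <- c(probs,
                   "exactly two contrasts are required for ISR selection")
    } else {
        for (ct in config$contrasts) {
            if (length(ct) != 2L) {
                probs <- c(probs, "each contrast must name two conditions")
                next
            }
            bad <- setdiff(unlist(ct), unique(conds))
            if (length(bad))
                probs <- c(probs, paste0("contrast names unknown condition: ",
                                         paste(bad, collapse = ", ")))
        }
    }
    alpha <- config$parameters$de$alpha
    if (!is.null(alpha) && (!is.numeric(alpha) || alpha <= 0 || alpha >= 1))
        probs <- c(probs, "parameters$de$alpha must be in (0, 1)")
    q <- config$parameters$enrich$q_cutoff
    if (!is.null(q) && (!is.numeric(q) || q <= 0 || q > 1))
        probs <- c(probs, "parameters$enrich$q_cutoff must be in (0, 1]")
    if (!is.null(config$stages)) {
        unknown <- setdiff(names(config$stages), .STAGES)
        if (length(unknown))
            probs <- c(probs, paste0("unknown stage flag(s): ",
                                     paste(unknown, collapse = ", ")))
    }
    probs
}

#' Build a pipeline config from a written fixture
#'
#' Reads the fixture `manifest.yaml` produced by [writeFixture()] and
#' returns a ready-to-run configuration pointing at the fixture files, with
#' contrasts (treatment vs control, treatment vs mutant) derived from the
#' condition labels.
#'
#' @param fixtureDir directory written by [writeFixture()].
#' @param outdir pipeline output directory.
#' @param seed pipeline seed (recorded in the config).
#' @return a config list accepted by [runPipeline()].
#' @export
pipelineConfigFromFixture <- function(fixtureDir, outdir,
                                      seed = 1L) {
    man <- yaml::read_yaml(file.path(fixtureDir, "manifest.yaml"))
    conds <- unlist(man$conditions)
    list(
        version = 1L,
        seed = as.integer(seed),
        outdir = outdir,
        inputs = list(
            genome = file.path(fixtureDir, "genome.fa"),
            annotation = file.path(fixtureDir, "annotation.gff3"),
            mature = file.path(fixtureDir, "mature_known.fa"),
            transcriptome = file.path(fixtureDir, "transcriptome.fa"),
            go_annotation = file.path(fixtureDir, "go_annotation.tsv"),
            libraries = lapply(man$libraries, function(lb)
                list(id = lb$id, condition = lb$condition,
                     replicate = lb$replicate,
                     fastq = file.path(fixtureDir, lb$fastq))),
            degradome = lapply(man$degradome, function(dg)
                list(condition = dg$condition,
                     fasta = file.path(fixtureDir, dg$fasta)))),
        contrasts = list(c(conds[1], conds[3]), c(conds[1], conds[2])),
        parameters = list(clean = list(adapter3 = man$adapter3)))
}

.hashParams <- function(params) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(deparse(params), tf)
    unname(tools::md5sum(tf))
}

.fingerprint <- function(files, params) {
    md5 <- tools::md5sum(files)
    md5[is.na(md5)] <- "missing"
    list(files = as.list(md5), params = .hashParams(params))
}

.param <- function(config, stage, key, default) {
    v <- config$parameters[[stage]][[key]]
    if (is.null(v)) default else v
}

#' Run the full ISR-miRNA pipeline
#'
#' Executes the stages in dependency order (clean+collapse -> identify ->
#' de -> candidates -> promoter -> scan -> targets -> degradome -> enrich
#' -> network), writing each stage's outputs under `outdir` together with a
#' run manifest recording parameters and input checksums.  On a rerun,
#' stages whose inputs and parameters are unchanged are skipped unless
#' `force = TRUE`.  A stage failure halts the run with the failing stage
#' named; outputs of completed stages are retained.
#'
#' @param config config list or YAML path (see [validateConfig()]).
#' @param force rerun stages even when up to date.
#' @return invisibly, a list with the output directory and the manifest.
#' @export
runPipeline <- function(config, force = FALSE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    probs <- validateConfig(config)
    if (length(probs))
        stop("invalid pipeline config:\n  - ",
             paste(probs, collapse = "\n  - "))
    outdir <- config$outdir
    if (is.null(outdir)) stop("config$outdir is required to run")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(config$seed)) set.seed(as.integer(config$seed))
    manifestPath <- file.path(outdir, "run_manifest.yaml")
    manifest <- if (file.exists(manifestPath))
        yaml::read_yaml(manifestPath) else list(stages = list())
    enabled <- function(st) {
        flag <- config$stages[[st]]
        is.null(flag) || isTRUE(flag)
    }
    out <- function(...) file.path(outdir, ...)
    inp <- config$inputs
    libInfo <- do.call(rbind, lapply(inp$libraries, function(lb)
        data.frame(library = lb$id, condition = lb$condition,
                   replicate = lb$replicate, fastq = lb$fastq)))

    runStage <- function(name, files, params, outputs, fun) {
        if (!enabled(name)) {
            message("[", name, "] disabled, skipping")
            return(invisible(FALSE))
        }
        fp <- .fingerprint(files, params)
        st <- manifest$stages[[name]]
        if (!force && !is.null(st) && identical(st$fingerprint, fp) &&
            all(file.exists(outputs))) {
            message("[", name, "] up to date, skipping")
            return(invisible(FALSE))
        }
        message("[", name, "] running")
        ok <- tryCatch({ fun(); TRUE }, error = function(e) {
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
        manifest$stages[[name]] <<- list(fingerprint = fp,
                                         outputs = as.list(outputs))
        yaml::write_yaml(manifest, manifestPath)
        invisible(TRUE)
    }

    cleanP <- list(adapter3 = .param(config, "clean", "adapter3", NULL),
                   minLen = .param(config, "clean", "min_len", 18L),
                   maxLen = .param(config, "clean", "max_len", 30L),
                   minQuality = .param(config, "clean", "min_quality", 20),
                   minOverlap = .param(config, "clean", "min_overlap", 6L),
                   maxErrorRate = .param(config, "clean", "max_error_rate",
                                         0.1))
    if (is.null(cleanP$adapter3))
        stop("parameters$clean$adapter3 is required")

    runStage("collapse", libInfo$fastq, cleanP,
             out(c("tag_counts.tsv", "length_dist.tsv",
                   "library_stats.tsv")), function() {
        cleanList <- list()
        statRows <- list()
        for (i in seq_len(nrow(libInfo))) {
            cl <- cleanReads(libInfo$fastq[i], cleanP$adapter3,
                             cleanP$minLen, cleanP$maxLen, cleanP$minQuality,
                             cleanP$minOverlap, cleanP$maxErrorRate,
                             libraryId = libInfo$library[i])
            cleanList[[libInfo$library[i]]] <- cl$reads
            s <- cl$stats
            statRows[[i]] <- data.frame(
                library = s$libraryId, rawReads = s$rawReads,
                cleanReads = s$cleanReads,
                lowQuality = s$discarded[["lowQuality"]],
                containsN = s$discarded[["containsN"]],
                lengthOut = s$discarded[["lengthOut"]],
                blocklist = s$discarded[["blocklist"]])
            message("  ", s$libraryId, ": ", s$rawReads, " raw -> ",
                    s$cleanReads, " clean reads")
        }
        tags <- collapseTags(cleanList)
        .writeTsv(tags, out("tag_counts.tsv"))
        .writeTsv(lengthDistribution(tags), out("length_dist.tsv"))
        .writeTsv(do.call(rbind, statRows), out("library_stats.tsv"))
        message("  ", nrow(tags), " unique tags")
    })

    idP <- list(maxMismatches = .param(config, "identify", "max_mismatches",
                                       0L),
                maxShift = .param(config, "identify", "max_shift", 2L),
                minCount = .param(config, "identify", "min_count", 5L),
                backend = .param(config, "identify", "backend", "auto"))
    runStage("identify",
             c(out("tag_counts.tsv"), inp$mature, inp$genome,
               inp$annotation), idP,
             out(c("known_mirnas.tsv", "counts.tsv",
                   "novel_candidates.tsv")), function() {
        tags <- read.delim(out("tag_counts.tsv"))
        mature <- readDNAStringSet(inp$mature)
        assignments <- matchKnown(tags, setNames(as.character(mature),
                                                 names(mature)),
                                  idP$maxMismatches, idP$maxShift)
        .writeTsv(assignments, out("known_mirnas.tsv"))
        se <- mirnaCountMatrix(tags, assignments, libInfo)
        .writeTsv(cbind(mirna = rownames(assay(se)),
                        as.data.frame(assay(se))), out("counts.tsv"))
        genome <- readDNAStringSet(inp$genome)
        names(genome) <- sub("\\s.*$", "", names(genome))
        ann <- rtracklayer::import(inp$annotation)
        excl <- ann[ann$type == "miRNA_primary_transcript"]
        unassigned <- tags[!tags$sequence %in% assignments$sequence, ,
                           drop = FALSE]
        novel <- callNovel(unassigned, genome, minCount = idP$minCount,
                           excludeRanges = excl, backend = idP$backend)
        .writeTsv(novel, out("novel_candidates.tsv"))
        message("  ", length(unique(assignments$mirna)),
                " known miRNAs; ", nrow(novel), " novel candidates")
    })

    deP <- list(alpha = .param(config, "de", "alpha", 0.05))
    runStage("de", out("counts.tsv"),
             c(deP, list(contrasts = config$contrasts)),
             out("de_results.tsv"), function() {
        cnt <- read.delim(out("counts.tsv"))
        counts <- as.matrix(cnt[, libInfo$library, drop = FALSE])
        rownames(counts) <- cnt$mirna
        se <- SummarizedExperiment(
            assays = list(counts = counts),
            colData = DataFrame(libInfo, row.names = libInfo$library))
        res <- do.call(rbind, lapply(config$contrasts, function(ct)
            runContrast(se, ct[[1]], ct[[2]])))
        .writeTsv(res, out("de_results.tsv"))
        message("  ", sum(!is.na(res$p) & res$p < deP$alpha),
                " miRNA x contrast DE calls at p < ", deP$alpha)
    })

    candP <- list(alpha = deP$alpha,
                  direction = .param(config, "candidates", "direction",
                                     "down"))
    runStage("candidates", out("de_results.tsv"), candP,
             out(c("candidates.tsv", "venn.tsv")), function() {
        res <- read.delim(out("de_results.tsv"))
        labs <- vapply(config$contrasts, function(ct)
            paste(ct[[1]], "vs", ct[[2]]), "")
        resA <- res[res$contrast == labs[1], ]
        resB <- res[res$contrast == labs[2], ]
        sel <- selectIsrCandidates(resA, resB, candP$alpha,
                                   candP$direction)
        .writeTsv(data.frame(mirna = sel$candidates),
                  out("candidates.tsv"))
        .writeTsv(data.frame(
            set = c(labs[1], labs[2], "intersection", "candidates"),
            n = c(length(sel$deA), length(sel$deB),
                  length(sel$intersection), length(sel$candidates))),
            out("venn.tsv"))
        message("  candidates: ", paste(sel$candidates, collapse = ", "))
    })

    runStage("promoter", c(out("candidates.tsv"), inp$annotation,
                           inp$genome), list(),
             out(c("promoters.tsv", "promoters.fa", "promoters.bed")),
             function() {
        cand <- read.delim(out("candidates.tsv"))$mirna
        ann <- rtracklayer::import(inp$annotation)
        genome <- readDNAStringSet(inp$genome)
        names(genome) <- sub("\\s.*$", "", names(genome))
        pris <- ann[ann$type == "miRNA_primary_transcript"]
        genes <- ann[ann$type == "gene"]
        priIds <- paste0("pri-", sub("-[35]p$", "", cand))
        sel <- pris[pris$ID %in% priIds]
        chromLens <- setNames(width(genome), names(genome))
        proms <- list()
        for (i in seq_along(sel)) {
            pri <- sel[i]
            up <- .upstreamGene(pri, genes)
            pr <- extractPromoter(pri, up,
                                  chromLens[[as.character(seqnames(pri))]])
            names(pr) <- pri$ID
            proms[[i]] <- pr
        }
        proms <- do.call(c, proms)
        seqs <- .getSeq(genome, proms)
        writeXStringSet(DNAStringSet(seqs), out("promoters.fa"))
        rtracklayer::export(proms, out("promoters.bed"), format = "BED")
        .writeTsv(data.frame(pri = names(proms),
                             chrom = as.character(seqnames(proms)),
                             start = start(proms), end = end(proms),
                             strand = as.character(strand(proms)),
                             branch = proms$branch, clipped = proms$clipped,
                             gap = proms$gap,
                             orientation = proms$orientation),
                  out("promoters.tsv"))
        message("  ", length(proms), " promoters extracted")
    })

    motifPath <- if (!is.null(inp$motifs)) inp$motifs else
        system.file("extdata", "motifs_plantcare.tsv", package = "mirISR")
    runStage("scan", c(out("promoters.fa"), motifPath), list(),
             out(c("motif_hits.tsv", "defense_summary.tsv")), function() {
        proms <- readDNAStringSet(out("promoters.fa"))
        motifs <- read.delim(motifPath)
        hits <- scanMotifs(proms, motifs)
        .writeTsv(hits, out("motif_hits.tsv"))
        .writeTsv(classifyDefenseElements(hits, motifs,
                                          promoterIds = names(proms)),
                  out("defense_summary.tsv"))
        message("  ", nrow(hits), " motif hits")
    })

    tgtP <- list(maxScore = .param(config, "targets", "max_score", 4.0))
    runStage("targets", c(out("candidates.tsv"), inp$mature,
                          inp$transcriptome), tgtP,
             out("targets.tsv"), function() {
        cand <- read.delim(out("candidates.tsv"))$mirna
        mature <- readDNAStringSet(inp$mature)
        txs <- readDNAStringSet(inp$transcriptome)
        mseq <- setNames(as.character(mature), names(mature))[cand]
        tg <- findTargets(mseq, txs, tgtP$maxScore)
        .writeTsv(tg, out("targets.tsv"))
        message("  ", nrow(tg), " target alignments at score <= ",
                tgtP$maxScore)
    })

    degP <- list(prefixLength = .param(config, "degradome",
                                       "prefix_length", 20L),
                 window = .param(config, "degradome", "window", 1L))
    degFiles <- vapply(inp$degradome, `[[`, "", "fasta")
    runStage("degradome", c(out("targets.tsv"), inp$transcriptome,
                            degFiles), degP,
             out("target_evidence.tsv"), function() {
        tg <- read.delim(out("targets.tsv"))
        txs <- readDNAStringSet(inp$transcriptome)
        profs <- list()
        for (dg in inp$degradome) {
            md <- mapDegradome(dg$fasta, txs, degP$prefixLength)
            profs[[dg$condition]] <- md$profiles
            message("  ", dg$condition, ": ", md$stats$mapped, "/",
                    md$stats$total, " tags mapped")
        }
        ev <- targetEvidence(tg, profs, degP$window)
        .writeTsv(ev, out("target_evidence.tsv"))
        dir.create(out("tplots"), showWarnings = FALSE)
        supp <- ev[ev$category != "unsupported", , drop = FALSE]
        for (r in seq_len(nrow(supp))) {
            prof <- profs[[supp$condition[r]]][[supp$transcript[r]]]
            .writeTsv(tplotData(prof, supp$cleavage[r]),
                      out("tplots", paste0(supp$mirna[r], "_",
                                           supp$transcript[r], "_",
                                           supp$condition[r], ".tsv")))
        }
    })

    enrP <- list(qCutoff = .param(config, "enrich", "q_cutoff", 0.05),
                 maxCategory = .param(config, "degradome", "max_category",
                                      3L))
    runStage("enrich", c(out("target_evidence.tsv"), inp$go_annotation),
             enrP, out(c("supported_targets.tsv", "enrichment.tsv")),
             function() {
        ev <- read.delim(out("target_evidence.tsv"),
                         colClasses = c(category = "character"))
        conds <- unique(unlist(config$contrasts))
        supp <- supportedTargetIntersection(ev, conds, enrP$maxCategory)
        .writeTsv(supp, out("supported_targets.tsv"))
        ann <- read.delim(inp$go_annotation)
        enr <- enrichTargets(unique(supp$transcript), ann)
        .writeTsv(enr, out("enrichment.tsv"))
        message("  ", nrow(supp), " supported targets; ",
                sum(!is.na(enr$q) & enr$q <= enrP$qCutoff),
                " terms at q <= ", enrP$qCutoff)
    })

    runStage("network", out(c("candidates.tsv", "target_evidence.tsv",
                              "enrichment.tsv")),
             enrP, out(c("network.sif", "network.graphml")), function() {
        cand <- read.delim(out("candidates.tsv"))$mirna
        ev <- read.delim(out("target_evidence.tsv"),
                         colClasses = c(category = "character"))
        enr <- read.delim(out("enrichment.tsv"))
        ann <- read.delim(inp$go_annotation)
        g <- buildNetwork(cand, ev, enr, ann, enrP$qCutoff,
                          enrP$maxCategory)
        exportNetwork(g, out("network.sif"), "sif")
        exportNetwork(g, out("network.graphml"), "graphml")
        message("  network: ", igraph::vcount(g), " nodes, ",
                igraph::ecount(g), " edges")
    })

    invisible(list(outdir = outdir, manifest = manifest))
}

# nearest annotated gene on the 5' side of a pri-miRNA (any strand)
.upstreamGene <- function(pri, genes) {
    if (!length(genes)) return(NULL)
    sameChrom <- as.character(seqnames(genes)) ==
        as.character(seqnames(pri))
    g <- genes[sameChrom]
    if (!length(g)) return(NULL)
    if (as.character(strand(pri)) == "+") {
        side <- end(g) < start(pri)
        if (!any(side)) return(NULL)
        g <- g[side]
        g[which.max(end(g))]
    } else {
        side <- start(g) > end(pri)
        if (!any(side)) return(NULL)
        g <- g[side]
        g[which.min(start(g))]
    }
}
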