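# Hypergeometric GO enrichment and the miRNA-target-GO network.

#' Hypergeometric term enrichment of a target set
#'
#' Upper-tail hypergeometric test per annotated term with at least one
#' target hit, BH-corrected across the tested terms.  The universe defaults
#' to all genes in the supplied annotation (configurable to expressed-only
#' by passing that set).
#'
#' @param targetSet character vector of target gene ids (subset of the
#'   universe; ids outside it are dropped with a warning).
#' @param annotation data.frame with columns `gene`, `term`, and optionally
#'   `name`, `namespace`.
#' @param universe background gene set.
#' @return data.frame sorted by p (ties by term id): `term`, `name`,
#'   `namespace`, `k` (targets with the term), `K` (universe genes with the
#'   term), `n` (target-set size), `N` (universe size), `p`, `q`.
#' @examples
#' ann <- data.frame(gene = paste0("g", 1:20),
#'                   term = rep(c("T1", "T2"), c(5, 15)))
#' enrichTargets(paste0("g", 1:5), ann)
#' @export
enrichTargets <- function(targetSet, annotation,
                          universe = unique(annotation$gene)) {
    if (length(universe) == 0L) stop("universe is empty")
    drop <- setdiff(targetSet, universe)
    if (length(drop))
        warning(length(drop), " target(s) outside the universe dropped")
    targetSet <- unique(intersect(targetSet, universe))
    N <- length(universe)
    n <- length(targetSet)
    ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
    terms <- unique(ann$term)
    rows <- list()
    for (tm in terms) {
        genes <- unique(ann$gene[ann$term == tm])
        k <- length(intersect(genes, targetSet))
        if (k < 1L) next
        K <- length(genes)
        p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        nm <- if ("name" %in% names(ann))
            ann$name[match(tm, ann$term)] else NA_character_
        ns <- if ("namespace" %in% names(ann))
            ann$namespace[match(tm, ann$term)] else NA_character_
        rows[[length(rows) + 1L]] <- data.frame(
            term = tm, name = nm, namespace = ns, k = k, K = K, n = n,
            N = N, p = p)
    }
    if (!length(rows))
        return(data.frame(term = character(), name = character(),
                          namespace = character(), k = integer(),
                          K = integer(), n = integer(), N = integer(),
                          p = numeric(), q = numeric()))
    res <- do.call(rbind, rows)
    res$q <- p.adjust(res$p, method = "BH")
    res <- res[order(res$p, res$term), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Build the miRNA-target-GO regulatory network
#'
#' Nodes are typed `mirna`, `target` and `term`; edges are `targets`
#' (miRNA -> target, for degradome-supported targets of the candidate
#' miRNAs) and `annotated-to` (target -> enriched term at `q <= qCutoff`).
#' GO nodes unconnected to any included target are not created.
#'
#' @param candidates candidate miRNA names.
#' @param evidence [targetEvidence()] output (or any data.frame with
#'   `mirna`, `transcript`, `category`).
#' @param enrichment [enrichTargets()] output.
#' @param annotation gene -> term table used for the `annotated-to` edges.
#' @param qCutoff BH q-value cutoff for included terms.
#' @param maxCategory highest degradome category counted as supported.
#' @return an [igraph::graph] with vertex attribute `type` and edge
#'   attribute `relation`.
#' @export
buildNetwork <- function(candidates, evidence, enrichment, annotation,
                         qCutoff = 0.05, maxCategory = 3L) {
    supp <- evidence[evidence$mirna %in% candidates &
                     evidence$category %in% as.character(0:maxCategory),
                     c("mirna", "transcript")]
    supp <- unique(supp)
    if (nrow(supp) == 0L)
        return(igraph::make_empty_graph(directed = FALSE))
    terms <- enrichment$term[!is.na(enrichment$q) &
                             enrichment$q <= qCutoff]
    annEdges <- unique(annotation[annotation$gene %in% supp$transcript &
                                  annotation$term %in% terms,
                                  c("gene", "term")])
    nodes <- rbind(
        data.frame(name = unique(supp$mirna), type = "mirna"),
        data.frame(name = unique(supp$transcript), type = "target"),
        if (nrow(annEdges))
            data.frame(name = unique(annEdges$term), type = "term"))
    edges <- rbind(
        data.frame(from = supp$mirna, to = supp$transcript,
                   relation = "targets"),
        if (nrow(annEdges))
            data.frame(from = annEdges$gene, to = annEdges$term,
                       relation = "annotated-to"))
    igraph::graph_from_data_frame(edges, directed = FALSE,
                                  vertices = nodes)
}

#' Export a regulatory network
#'
#' Writes SIF (one `node relation node` line per edge) or GraphML.
#' Reading the file back preserves the node and edge sets.
#'
#' @param network igraph object from [buildNetwork()].
#' @param file output path.
#' @param format `"sif"` or `"graphml"`.
#' @return the path, invisibly.
#' @export
exportNetwork <- function(network, file, format = c("sif", "graphml")) {
    format <- match.arg(format)
    if (format == "sif") {
        if (igraph::ecount(network) == 0L) {
            writeLines(character(0), file)
        } else {
            el <- igraph::as_edgelist(network)
            rel <- igraph::edge_attr(network, "relation")
            if (is.null(rel)) rel <- rep("edge", nrow(el))
            writeLines(paste(el[, 1], rel, el[, 2], sep = "\t"), file)
        }
    } else {
        igraph::write_graph(network, file, format = "graphml")
    }
    invisible(file)
}

#' Read a network written by [exportNetwork()]
#'
#' @param file path.
#' @param format `"sif"` or `"graphml"`.
#' @return an igraph object.
#' @export
importNetwork <- function(file, format = c("sif", "graphml")) {
    format <- match.arg(format)
    if (format == "sif") {
        lines <- readLines(file)
        lines <- lines[nzchar(lines)]
        if (!length(lines))
            return(igraph::make_empty_graph(directed = FALSE))
        parts <- do.call(rbind, strsplit(lines, "\t"))
        g <- igraph::graph_from_data_frame(
            data.frame(from = parts[, 1], to = parts[, 3],
                       relation = parts[, 2]), directed = FALSE)
        g
    } else {
        igraph::read_graph(file, format = "graphml")
    }
}
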