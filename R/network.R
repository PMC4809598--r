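#' Assemble the annotated gene network
#'
#' Builds the node table (non-exclusive DE/TS/TF/SNP class flags plus the
#' tissue of highest relative expression) and attaches the accepted edge
#' list. Nodes are the union of the four classes; every edge endpoint
#' must be an annotated node.
#'
#' @param edges accepted edge list (\code{gene_a}, \code{gene_b},
#'   optionally \code{r}, \code{z}); typically
#'   \code{subset(threshold_edges(...), accepted)}.
#' @param ts_genes,de_genes,tf_genes,snp_genes character vectors of class
#'   members.
#' @param tissue_of named character vector: tissue of highest relative
#'   expression per gene (argmax tissue share; required for every node).
#' @param meta optional provenance list (thresholds, seed) stored on the
#'   network.
#' @return an object of class \code{gene_network} with \code{nodes} and
#'   \code{edges} data frames.
#' @export
build_network <- function(edges, ts_genes, de_genes, tf_genes, snp_genes,
                          tissue_of, meta = list()) {
  nodes <- sort(unique(c(ts_genes, de_genes, tf_genes, snp_genes)))
  if (length(nodes) == 0) stop("no nodes: all class sets empty")
  if (nrow(edges) > 0) {
    bad <- setdiff(unique(c(edges$gene_a, edges$gene_b)), nodes)
    if (length(bad))
      stop("edge endpoint(s) outside the DE/TS/TF/SNP union: ",
           paste(head(bad, 10), collapse = ", "))
  }
  miss <- setdiff(nodes, names(tissue_of))
  if (length(miss))
    stop("missing tissue annotation for node(s): ",
         paste(head(miss, 10), collapse = ", "))
  node_tab <- data.frame(
    gene = nodes,
    is_de = nodes %in% de_genes, is_ts = nodes %in% ts_genes,
    is_tf = nodes %in% tf_genes, is_snp = nodes %in% snp_genes,
    tissue = unname(tissue_of[nodes]),
    row.names = NULL, stringsAsFactors = FALSE)
  keep <- intersect(c("gene_a", "gene_b", "r", "z"), names(edges))
  structure(list(nodes = node_tab,
                 edges = edges[, keep, drop = FALSE], meta = meta),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes (%d DE, %d TS, %d TF, %d SNP), %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_de), sum(x$nodes$is_ts),
              sum(x$nodes$is_tf), sum(x$nodes$is_snp), nrow(x$edges)))
  invisible(x)
}

#' Node degrees, ranked
#'
#' @param net a [build_network()] result.
#' @return data frame gene, degree, class flags and tissue, sorted by
#'   decreasing degree with ties broken by gene id.
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  deg <- setNames(rep(0L, nrow(net$nodes)), net$nodes$gene)
  if (nrow(net$edges) > 0) {
    tab <- table(c(net$edges$gene_a, net$edges$gene_b))
    deg[names(tab)] <- as.integer(tab)
  }
  out <- net$nodes
  out$degree <- unname(deg[out$gene])
  out <- out[order(-out$degree, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Tissue composition of the edge set
#'
#' Computes the fraction of edges whose endpoints share the same tissue
#' of highest expression, per-tissue node and edge counts, and the R^2 of
#' a least-squares regression of each tissue's inter-tissue (outgoing)
#' edge count on its node count.
#'
#' @param net a [build_network()] result.
#' @return list with \code{within_fraction}, a \code{per_tissue} data
#'   frame (tissue, nodes, edges_within, edges_outgoing) and \code{r2}.
#' @export
tissue_edge_summary <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  tis_of <- setNames(net$nodes$tissue, net$nodes$gene)
  tissues <- sort(unique(net$nodes$tissue))
  e <- net$edges
  ta <- tis_of[e$gene_a]; tb <- tis_of[e$gene_b]
  within <- if (nrow(e) > 0) ta == tb else logical(0)
  per <- data.frame(
    tissue = tissues,
    nodes = as.integer(table(factor(net$nodes$tissue, tissues))),
    edges_within = vapply(tissues, function(tt)
      sum(within & ta == tt), integer(1)),
    edges_outgoing = vapply(tissues, function(tt)
      sum(!within & (ta == tt | tb == tt)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  r2 <- if (nrow(per) >= 3 && var(per$nodes) > 0 &&
            var(per$edges_outgoing) > 0)
    summary(lm(edges_outgoing ~ nodes, data = per))$r.squared else NA_real_
  list(within_fraction = if (nrow(e) > 0) mean(within) else NA_real_,
       per_tissue = per, r2 = r2)
}

#' Extract the transcription-factor subnetwork
#'
#' Keeps only edges incident to at least one TF; nodes are the TFs plus
#' their neighbours ("TF and genes connected to them by an edge").
#'
#' @param net a [build_network()] result.
#' @return a \code{gene_network}.
#' @export
extract_tf_subnetwork <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  tfs <- net$nodes$gene[net$nodes$is_tf]
  if (length(tfs) == 0) {
    warning("no TF nodes: subnetwork is empty")
    net$nodes <- net$nodes[0, ]
    net$edges <- net$edges[0, ]
    return(net)
  }
  inc <- net$edges$gene_a %in% tfs | net$edges$gene_b %in% tfs
  e <- net$edges[inc, , drop = FALSE]
  keep <- union(tfs, unique(c(e$gene_a, e$gene_b)))
  net$nodes <- net$nodes[net$nodes$gene %in% keep, , drop = FALSE]
  rownames(net$nodes) <- rownames(e) <- NULL
  net$edges <- e
  net
}

#' Fisher's exact over-representation test
#'
#' One-sided hypergeometric test of term over-representation in a gene
#' set against a universe: \code{p = P(X >= k)} for the observed overlap
#' k, computed per term. No multiple-testing correction is applied
#' (terms at \code{p < alpha} are flagged, mirroring the P<0.05 usage).
#'
#' @param gene_set character vector, subset of \code{universe}.
#' @param universe character vector of all eligible genes.
#' @param term_map named list mapping term id to member genes, or a data
#'   frame with columns \code{gene} and \code{term}.
#' @param alpha significance level for flagging.
#' @return data frame term, overlap \code{k}, set size \code{n}, term
#'   size in universe \code{K}, universe size \code{N}, \code{p} and
#'   \code{significant}, ordered by p.
#' @export
fisher_enrichment <- function(gene_set, universe, term_map, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  if (is.data.frame(term_map))
    term_map <- split(term_map$gene, term_map$term)
  N <- length(universe); n <- length(gene_set)
  res <- lapply(names(term_map), function(tm) {
    members <- intersect(unique(term_map[[tm]]), universe)
    K <- length(members)
    k <- length(intersect(gene_set, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Export a network to SIF, TSV or GraphML
#'
#' SIF writes one \code{geneA co geneB} line per edge; TSV writes an edge
#' table (with weights) and a companion \code{<path>.nodes.tsv} node
#' attribute table, a pair that [read_network_tsv()] round-trips exactly;
#' GraphML (via igraph) carries node class flags and tissue attributes
#' for external viewers.
#'
#' @param net a [build_network()] result.
#' @param path output file path.
#' @param format one of \code{"sif"}, \code{"tsv"}, \code{"graphml"}.
#' @return the path, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "tsv", "graphml")) {
  stopifnot(inherits(net, "gene_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- if (nrow(net$edges) > 0)
      paste(net$edges$gene_a, "co", net$edges$gene_b) else character(0)
    writeLines(lines, path)
  } else if (format == "tsv") {
    write_tsv(net$edges, path)
    write_tsv(net$nodes, paste0(path, ".nodes.tsv"))
  } else {
    g <- igraph::graph_from_data_frame(
      net$edges, directed = FALSE,
      vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back a TSV network export
#'
#' @param path the edge-table path given to [export_network()].
#' @return a \code{gene_network} identical to the exported one.
#' @export
read_network_tsv <- function(path) {
  edges <- read_tsv(path)
  nodes <- read_tsv(paste0(path, ".nodes.tsv"))
  structure(list(nodes = nodes, edges = edges, meta = list()),
            class = "gene_network")
}
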