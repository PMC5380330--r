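# Bipartite miRNA -> target-gene networks restricted to DEM sets and
# pathway gene sets: assembly, degree ranking, regulator-class gene
# labelling, and GraphML / SIF export for Cytoscape-style tools.

#' Filter a miRNA-target table to a miRNA set and a gene set
#'
#' Keeps edges whose miRNA is in `mirna_set` and whose (normalized) gene
#' symbol is in `gene_set`, in a stable (mirna, gene) order.
#'
#' @param mti an `MTITable` (see [read_mti()]) or data.frame with
#'   columns `mirna`, `gene`.
#' @param mirna_set character vector of miRNA ids.
#' @param gene_set character vector of gene symbols.
#' @return data.frame of retained edges.
#' @export
filter_mti <- function(mti, mirna_set, gene_set) {
  edges <- as.data.frame(mti)
  gene_set <- normalize_symbols(gene_set)
  keep <- edges$mirna %in% mirna_set &
    normalize_symbols(edges$gene) %in% gene_set
  out <- edges[keep, , drop = FALSE]
  out$gene <- normalize_symbols(out$gene)
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a bipartite miRNA-target network
#'
#' Directed edges run miRNA -> gene (repression is carried as an edge
#' attribute, not as a sign).  miRNA nodes are annotated with their DEM
#' status (`co_down`, `co_up`, `other`), gene nodes with their member
#' pathways.  A node id typed both as miRNA and gene is rejected.
#' Declared but isolated nodes are dropped unless `keep_isolates`.
#'
#' @param edges data.frame with columns `mirna`, `gene` (already
#'   filtered); duplicate edges collapse to one.
#' @param mirna_annotations optional named character: miRNA id -> DEM
#'   status.
#' @param gene_annotations optional named list: gene -> pathway ids.
#' @param declared_mirnas,declared_genes optional node sets to include
#'   even without edges (with `keep_isolates`).
#' @param keep_isolates keep declared nodes with no incident edge.
#' @return an `MTINetwork`: list with `mirnas`, `genes`, `edges`,
#'   `mirna_status`, `gene_pathways`.
#' @export
build_network <- function(edges, mirna_annotations = NULL,
                          gene_annotations = NULL,
                          declared_mirnas = character(0),
                          declared_genes = character(0),
                          keep_isolates = FALSE) {
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    edges$gene <- normalize_symbols(edges$gene)
    edges <- unique(edges[, c("mirna", "gene")])
    edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(mirna = character(0), gene = character(0))
  }
  mirnas <- sort(unique(c(edges$mirna,
                          if (keep_isolates) declared_mirnas)))
  genes <- sort(unique(c(edges$gene,
                         if (keep_isolates) normalize_symbols(declared_genes))))
  overlap <- intersect(mirnas, genes)
  if (length(overlap))
    input_error(paste("node id(s) typed both miRNA and gene:",
                      paste(overlap, collapse = ", ")))
  status <- setNames(rep("other", length(mirnas)), mirnas)
  if (!is.null(mirna_annotations)) {
    hit <- intersect(mirnas, names(mirna_annotations))
    status[hit] <- as.character(mirna_annotations[hit])
  }
  pathways <- setNames(vector("list", length(genes)), genes)
  if (!is.null(gene_annotations)) {
    hit <- intersect(genes, names(gene_annotations))
    pathways[hit] <- gene_annotations[hit]
  }
  structure(list(mirnas = mirnas, genes = genes, edges = edges,
                 mirna_status = status, gene_pathways = pathways),
            class = "MTINetwork")
}

#' @export
print.MTINetwork <- function(x, ...) {
  cat(sprintf("MTINetwork: %d miRNAs, %d genes, %d edges\n",
              length(x$mirnas), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Rank miRNAs by out-degree
#'
#' @param network an `MTINetwork`.
#' @return data.frame (`mirna`, `degree`) in descending degree order,
#'   ties broken lexicographically; attribute `n_active` counts distinct
#'   miRNAs with degree >= 1.
#' @export
mirna_degree_ranking <- function(network) {
  stopifnot(inherits(network, "MTINetwork"))
  deg <- setNames(rep(0L, length(network$mirnas)), network$mirnas)
  if (nrow(network$edges)) {
    tab <- table(network$edges$mirna)
    deg[names(tab)] <- as.integer(tab)
  }
  out <- data.frame(mirna = names(deg), degree = unname(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_active") <- sum(out$degree >= 1)
  out
}

#' Classify genes by the DEM class of their regulators
#'
#' A gene is `down_only` iff it has at least one incident edge and every
#' incident miRNA belongs to `down_set`; `up_only` symmetrically;
#' `mixed` iff it is incident to miRNAs of both sets; `none` iff it has
#' no incident edge, or only regulators outside both sets.
#'
#' @param network an `MTINetwork`.
#' @param down_set,up_set character vectors of miRNA ids.
#' @return named character vector over the network's gene nodes with
#'   values in `down_only`, `up_only`, `mixed`, `none`.
#' @export
classify_genes_by_regulators <- function(network, down_set, up_set) {
  stopifnot(inherits(network, "MTINetwork"))
  out <- setNames(rep("none", length(network$genes)), network$genes)
  if (!nrow(network$edges)) return(out)
  by_gene <- split(network$edges$mirna, network$edges$gene)
  for (g in names(by_gene)) {
    regs <- unique(by_gene[[g]])
    has_dn <- any(regs %in% down_set)
    has_up <- any(regs %in% up_set)
    out[g] <- if (has_dn && has_up) "mixed"
    else if (has_dn && all(regs %in% down_set)) "down_only"
    else if (has_up && all(regs %in% up_set)) "up_only"
    else "none"
  }
  out
}

#' Export a network to GraphML or SIF
#'
#' GraphML carries `type` (mirna/gene) and `dem_status` node attributes
#' (written via igraph); SIF writes one line per edge with relation
#' `targets`.  Both formats round-trip node and edge sets through
#' [import_network()].
#'
#' @param network an `MTINetwork`.
#' @param path output file.
#' @param format `"graphml"` or `"sif"`.
#' @return invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("graphml", "sif")) {
  stopifnot(inherits(network, "MTINetwork"))
  format <- tryCatch(match.arg(format),
                     error = function(e) usage_error(
                       paste("unknown network format:", format[1])))
  if (format == "sif") {
    lines <- if (nrow(network$edges))
      sprintf("%s\ttargets\t%s", network$edges$mirna, network$edges$gene)
    else character(0)
    # isolated nodes appear as bare names per SIF convention
    touched <- unique(c(network$edges$mirna, network$edges$gene))
    lines <- c(lines, setdiff(c(network$mirnas, network$genes), touched))
    writeLines(lines, path)
  } else {
    g <- igraph::make_empty_graph(directed = TRUE)
    g <- igraph::add_vertices(g, length(network$mirnas),
                              name = network$mirnas, type = "mirna",
                              dem_status = unname(network$mirna_status))
    g <- igraph::add_vertices(g, length(network$genes),
                              name = network$genes, type = "gene",
                              dem_status = "na")
    if (nrow(network$edges))
      g <- igraph::add_edges(
        g, rbind(match(network$edges$mirna,
                       c(network$mirnas, network$genes)),
                 match(network$edges$gene,
                       c(network$mirnas, network$genes))),
        relation = "targets")
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import an exported network
#'
#' @param path file written by [export_network()].
#' @param format `"graphml"` or `"sif"`.
#' @return list with `mirnas`, `genes` (GraphML only; SIF cannot type
#'   isolated nodes so they are returned under `nodes`), and `edges`.
#' @export
import_network <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    is_edge <- lengths(parts) >= 3
    edges <- if (any(is_edge))
      data.frame(mirna = vapply(parts[is_edge], `[`, "", 1),
                 gene = vapply(parts[is_edge], `[`, "", 3),
                 stringsAsFactors = FALSE)
    else data.frame(mirna = character(0), gene = character(0))
    nodes <- unique(c(edges$mirna, edges$gene,
                      unlist(parts[!is_edge], use.names = FALSE)))
    list(nodes = sort(nodes),
         edges = edges[order(edges$mirna, edges$gene), , drop = FALSE])
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nm <- igraph::vertex_attr(g, "name")
    ty <- igraph::vertex_attr(g, "type")
    el <- igraph::as_edgelist(g)
    edges <- data.frame(mirna = el[, 1], gene = el[, 2],
                        stringsAsFactors = FALSE)
    list(mirnas = sort(nm[ty == "mirna"]), genes = sort(nm[ty == "gene"]),
         nodes = sort(nm),
         edges = edges[order(edges$mirna, edges$gene), , drop = FALSE])
  }
}
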