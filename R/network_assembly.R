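# Multi-layer network assembly: typed gene / miRNA / SNP / drug nodes with
# mirna_gene, drug_gene and snp_gene edges, degree statistics over the
# miRNA-gene layer, top-k rankings, and Cytoscape-compatible export.

EDGE_TYPES <- c("mirna_gene", "drug_gene", "snp_gene")
NODE_TYPES <- c("gene", "miRNA", "SNP", "drug")
NODE_SHAPES <- c(gene = "circle", miRNA = "diamond", SNP = "square",
                 drug = "triangle")
# source-node type demanded by each edge type; the target is always a gene
EDGE_SOURCE_TYPE <- c(mirna_gene = "miRNA", drug_gene = "drug",
                      snp_gene = "SNP")

#' Construct a multi-layer network
#'
#' @param nodes data frame with columns `id`, `node_type` (one of gene,
#'   miRNA, SNP, drug) and optional logical `isolated`.
#' @param edges data frame with columns `from`, `to`, `edge_type` (one of
#'   mirna_gene, drug_gene, snp_gene). Edge sources must be typed as the
#'   edge type demands and targets must be genes; self-loops are rejected
#'   and duplicate edges collapsed.
#' @return object of class `multilayer_network` with deterministically
#'   ordered `nodes` (by type then id) and `edges` (by type, source,
#'   target).
#' @export
multilayer_network <- function(nodes, edges) {
  stopifnot(all(c("id", "node_type") %in% names(nodes)),
            all(c("from", "to", "edge_type") %in% names(edges)))
  if (!all(nodes$node_type %in% NODE_TYPES)) {
    stop("unknown node type(s): ",
         paste(setdiff(nodes$node_type, NODE_TYPES), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id(s) across layers", call. = FALSE)
  }
  if (!all(edges$edge_type %in% EDGE_TYPES)) {
    stop("unknown edge type(s)", call. = FALSE)
  }
  if (any(edges$from == edges$to)) stop("self-loops not allowed", call. = FALSE)
  type_of <- stats::setNames(nodes$node_type, nodes$id)
  if (anyNA(type_of[edges$from]) || anyNA(type_of[edges$to])) {
    stop("edge endpoint missing from node table", call. = FALSE)
  }
  need <- EDGE_SOURCE_TYPE[edges$edge_type]
  if (any(type_of[edges$from] != need) || any(type_of[edges$to] != "gene")) {
    stop("edge endpoints do not match their edge type", call. = FALSE)
  }
  edges <- edges[!duplicated(edges[c("from", "to", "edge_type")]), ,
                 drop = FALSE]
  if (!"isolated" %in% names(nodes)) nodes$isolated <- logical(nrow(nodes))
  nodes <- nodes[order(match(nodes$node_type, NODE_TYPES), nodes$id,
                       method = "radix"), c("id", "node_type", "isolated")]
  edges <- edges[order(edges$edge_type, edges$from, edges$to,
                       method = "radix"), c("from", "to", "edge_type")]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  tab <- table(factor(x$nodes$node_type, levels = NODE_TYPES))
  cat("multilayer_network:",
      paste(tab, names(tab), collapse = ", "), "|",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Build the multi-layer network of one term cluster
#'
#' Restricts all layers to a gene set (typically the union of enrichment
#' hit genes across one similarity cluster's terms): miRNA, drug and SNP
#' nodes enter only through an edge to a cluster gene; cluster genes with
#' no incident edge are retained but flagged `isolated`.
#'
#' @param cluster_genes non-empty character vector of gene symbols.
#' @param interactions an `interaction_set` (columns `mirna`, `gene`).
#' @param drugs optional data frame with columns `drug`, `gene`.
#' @param snps optional data frame with columns `rsid`, `gene`.
#' @return a [multilayer_network].
#' @export
build_cluster_network <- function(cluster_genes, interactions,
                                  drugs = NULL, snps = NULL) {
  cluster_genes <- unique(toupper(cluster_genes))
  if (length(cluster_genes) == 0) {
    stop("cluster_genes must be non-empty", call. = FALSE)
  }
  mg <- interactions[interactions$gene %in% cluster_genes, c("mirna", "gene")]
  dg <- if (is.null(drugs) || nrow(drugs) == 0) {
    data.frame(drug = character(0), gene = character(0))
  } else {
    unique(drugs[drugs$gene %in% cluster_genes, c("drug", "gene")])
  }
  sg <- if (is.null(snps) || nrow(snps) == 0) {
    data.frame(rsid = character(0), gene = character(0))
  } else {
    unique(snps[snps$gene %in% cluster_genes, c("rsid", "gene")])
  }
  linked <- unique(c(mg$gene, dg$gene, sg$gene))
  layer <- function(ids, type, isolated = logical(length(ids))) {
    data.frame(id = ids, node_type = rep(type, length(ids)),
               isolated = isolated, stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    layer(cluster_genes, "gene", !(cluster_genes %in% linked)),
    layer(unique(mg$mirna), "miRNA"),
    layer(unique(sg$rsid), "SNP"),
    layer(unique(dg$drug), "drug")
  )
  typed_edges <- function(from, to, type) {
    data.frame(from = from, to = to, edge_type = rep(type, length(from)),
               stringsAsFactors = FALSE)
  }
  edges <- rbind(
    typed_edges(mg$mirna, mg$gene, "mirna_gene"),
    typed_edges(dg$drug, dg$gene, "drug_gene"),
    typed_edges(sg$rsid, sg$gene, "snp_gene")
  )
  multilayer_network(nodes, edges)
}

#' Degree statistics over the miRNA-gene layer
#'
#' Gene degrees count distinct miRNA partners only; drug and SNP links are
#' excluded. Buckets use strict inequalities: "< 5" and "> 10", so genes
#' of degree 5-10 fall in neither. The mean is rounded half away from zero
#' to 1 decimal and percentages to 2 decimals.
#'
#' @param network a [multilayer_network] with >= 1 gene node.
#' @return one-row data frame of class `degree_summary` with columns
#'   `n_genes`, `n_mirnas`, `n_edges`, `mean_degree`, `n_lt5`, `pct_lt5`,
#'   `n_gt10`, `pct_gt10`.
#' @export
degree_summary <- function(network) {
  stopifnot(inherits(network, "multilayer_network"))
  genes <- network$nodes$id[network$nodes$node_type == "gene"]
  if (length(genes) == 0) {
    stop("degree summary undefined for a network with no gene nodes",
         call. = FALSE)
  }
  mg <- network$edges[network$edges$edge_type == "mirna_gene", , drop = FALSE]
  deg <- stats::setNames(rep(0L, length(genes)), genes)
  if (nrow(mg) > 0) {
    tab <- table(mg$to)
    deg[names(tab)] <- as.integer(tab)
  }
  n_genes <- length(genes)
  out <- data.frame(
    n_genes = n_genes,
    n_mirnas = sum(network$nodes$node_type == "miRNA"),
    n_edges = nrow(mg),
    mean_degree = round_half_away(sum(deg) / n_genes, 1),
    n_lt5 = sum(deg < 5),
    pct_lt5 = round_half_away(100 * sum(deg < 5) / n_genes, 2),
    n_gt10 = sum(deg > 10),
    pct_gt10 = round_half_away(100 * sum(deg > 10) / n_genes, 2)
  )
  class(out) <- c("degree_summary", "data.frame")
  out
}

#' Rank miRNAs by number of validated target genes
#'
#' @param interactions an `interaction_set` (columns `mirna`, `gene`).
#' @param snps optional SNP table (`rsid`, `gene`): `n_snps` counts
#'   distinct SNPs located in a miRNA's target genes.
#' @param drugs optional drug table (`drug`, `gene`): `n_drugs` counts
#'   distinct drugs hitting those targets.
#' @param disease_map optional association table (`mirna`, `term_name`):
#'   joined as a `"; "`-separated `diseases` column.
#' @param k number of rows to keep (default 10).
#' @return data frame of class `mirna_ranking` with columns `rank`,
#'   `mirna`, `targeted_genes`, `n_snps`, `n_drugs`, `diseases`; counts
#'   descending, ties broken lexicographically by miRNA name.
#' @export
rank_mirnas <- function(interactions, snps = NULL, drugs = NULL,
                        disease_map = NULL, k = 10) {
  stopifnot(k >= 1)
  pairs <- unique(as.data.frame(interactions)[, c("mirna", "gene")])
  if (nrow(pairs) == 0) {
    out <- data.frame(rank = integer(0), mirna = character(0),
                      targeted_genes = integer(0), n_snps = integer(0),
                      n_drugs = integer(0), diseases = character(0))
    class(out) <- c("mirna_ranking", "data.frame")
    return(out)
  }
  by_mirna <- split(pairs$gene, pairs$mirna)
  counts <- lengths(by_mirna)
  ord <- order(-counts, names(by_mirna), method = "radix")
  top <- utils::head(ord, k)
  mirnas <- names(by_mirna)[top]
  count_snps <- function(genes) {
    if (is.null(snps) || nrow(snps) == 0) return(0L)
    length(unique(snps$rsid[snps$gene %in% genes]))
  }
  count_drugs <- function(genes) {
    if (is.null(drugs) || nrow(drugs) == 0) return(0L)
    length(unique(drugs$drug[drugs$gene %in% genes]))
  }
  disease_lbl <- function(m) {
    if (is.null(disease_map) || nrow(disease_map) == 0) return("")
    paste(sort(unique(disease_map$term_name[disease_map$mirna == m])),
          collapse = "; ")
  }
  out <- data.frame(
    rank = seq_along(mirnas),
    mirna = mirnas,
    targeted_genes = unname(counts[top]),
    n_snps = vapply(by_mirna[top], count_snps, integer(1)),
    n_drugs = vapply(by_mirna[top], count_drugs, integer(1)),
    diseases = vapply(mirnas, disease_lbl, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("mirna_ranking", "data.frame")
  out
}

#' Rank miRNA-target genes by how many distinct drugs hit them
#'
#' Only genes that appear as miRNA targets are eligible.
#'
#' @param drugs data frame with columns `drug`, `gene`.
#' @param interactions an `interaction_set`.
#' @param k number of rows (default 10).
#' @return data frame with columns `rank`, `gene`, `n_drugs`; descending,
#'   ties lexicographic by gene.
#' @export
rank_genes_by_drug_count <- function(drugs, interactions, k = 10) {
  stopifnot(k >= 1)
  targets <- unique(interactions$gene)
  dg <- unique(drugs[drugs$gene %in% targets, c("drug", "gene")])
  if (nrow(dg) == 0) {
    return(data.frame(rank = integer(0), gene = character(0),
                      n_drugs = integer(0)))
  }
  counts <- lengths(split(dg$drug, dg$gene))
  ord <- order(-counts, names(counts), method = "radix")
  top <- utils::head(ord, k)
  data.frame(rank = seq_along(top), gene = names(counts)[top],
             n_drugs = unname(counts[top]), stringsAsFactors = FALSE)
}

#' Export a network for Cytoscape
#'
#' GraphML carries node attributes `node_type` and `shape` (gene = circle,
#' miRNA = diamond, SNP = square, drug = triangle) and the edge attribute
#' `edge_type`; SIF uses the edge type as the relation token, with isolated
#' nodes written as single-column lines. Node and edge order is
#' deterministic (type then id).
#'
#' @param network a [multilayer_network].
#' @param format `"graphml"` or `"sif"`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_network <- function(network, format = c("graphml", "sif"), path) {
  format <- match.arg(format)
  stopifnot(inherits(network, "multilayer_network"))
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", network$edges$from,
                     network$edges$edge_type, network$edges$to)
    endpoint <- unique(c(network$edges$from, network$edges$to))
    iso <- network$nodes$id[!(network$nodes$id %in% endpoint)]
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(lines, iso), con)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

as_igraph <- function(network) {
  v <- network$nodes
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, nrow(v), name = v$id,
                            node_type = v$node_type,
                            shape = unname(NODE_SHAPES[v$node_type]),
                            isolated = as.character(v$isolated))
  if (nrow(network$edges) > 0) {
    idx <- rbind(match(network$edges$from, v$id),
                 match(network$edges$to, v$id))
    g <- igraph::add_edges(g, as.vector(idx),
                           edge_type = network$edges$edge_type)
  }
  g
}

#' Import a network written by [export_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"sif"`.
#' @return a [multilayer_network] equal to the exported one.
#' @export
import_network <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    v <- data.frame(id = igraph::vertex_attr(g, "name"),
                    node_type = igraph::vertex_attr(g, "node_type"),
                    isolated = igraph::vertex_attr(g, "isolated") == "TRUE",
                    stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g, names = TRUE)
    e <- data.frame(from = el[, 1], to = el[, 2],
                    edge_type = if (igraph::ecount(g) > 0) {
                      igraph::edge_attr(g, "edge_type")
                    } else character(0),
                    stringsAsFactors = FALSE)
    return(multilayer_network(v, e))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  is_edge <- lengths(parts) >= 3
  from <- vapply(parts[is_edge], `[[`, character(1), 1)
  rel <- vapply(parts[is_edge], `[[`, character(1), 2)
  to <- vapply(parts[is_edge], `[[`, character(1), 3)
  iso <- vapply(parts[!is_edge], `[[`, character(1), 1)
  src_type <- EDGE_SOURCE_TYPE[rel]
  if (anyNA(src_type)) stop("unknown SIF relation token", call. = FALSE)
  nodes <- unique(rbind(
    data.frame(id = from, node_type = unname(src_type),
               stringsAsFactors = FALSE),
    data.frame(id = to, node_type = "gene", stringsAsFactors = FALSE),
    # SIF does not type isolated nodes; they re-enter as isolated genes
    data.frame(id = iso, node_type = rep("gene", length(iso)),
               stringsAsFactors = FALSE)
  ))
  nodes$isolated <- !(nodes$id %in% c(from, to))
  e <- data.frame(from = from, to = to, edge_type = rel,
                  stringsAsFactors = FALSE)
  multilayer_network(nodes, e)
}

#' Write a degree summary or ranking table as TSV
#'
#' @param x a data frame (`degree_summary`, `mirna_ranking`, ...).
#' @param path output path.
#' @export
write_summary_tsv <- function(x, path) {
  write_tsv_plain(as.data.frame(x), path)
}
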