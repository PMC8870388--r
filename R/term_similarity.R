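# Wang graph-based semantic similarity between ontology terms, and
# hierarchical clustering of a term set by 1 - similarity.
#
# For an anchor term A, every term t in DAG_A (A plus its ancestors) gets an
# S-value: S_A(A) = 1 and, walking upward, S_A(t) is the best edge-weighted
# contribution through any child of t inside DAG_A. The similarity of two
# terms sums the S-values of their shared ancestors against the total
# semantic values SV(A) + SV(B).

#' S-value map of a term
#'
#' @param term a term id present in `dag`.
#' @param dag an [ontology_dag].
#' @return named numeric vector over DAG_A (the term and its ancestors):
#'   `S_A(A) = 1` and, for each ancestor t,
#'   `S_A(t) = max over children c of t within DAG_A of w(c -> t) * S_A(c)`,
#'   where w is the semantic contribution factor of the edge's relation.
#' @export
s_values <- function(term, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$terms$term_id) {
    stop("unknown term: ", term, call. = FALSE)
  }
  pidx <- parent_index(dag)
  anc <- ancestors_of(term, pidx)
  closure <- c(term, anc)
  s <- stats::setNames(rep(0, length(closure)), closure)
  s[term] <- 1
  # relax child -> parent edges in topological order of the closure
  sub <- dag$edges[dag$edges$child %in% closure &
                     dag$edges$parent %in% closure, , drop = FALSE]
  if (nrow(sub) > 0) {
    g <- igraph::graph_from_data_frame(sub[, c("child", "parent")],
                                       directed = TRUE,
                                       vertices = data.frame(name = closure))
    ord <- igraph::topo_sort(g, mode = "out")$name
    for (v in ord) {
      rows <- which(sub$child == v)
      for (i in rows) {
        p <- sub$parent[i]
        cand <- sub$weight[i] * s[v]
        if (cand > s[p]) s[p] <- cand
      }
    }
  }
  s[closure]
}

#' Wang semantic similarity of two terms
#'
#' @param a,b term ids present in `dag`.
#' @param dag an [ontology_dag].
#' @return `sim(A, B) = sum over shared t of (S_A(t) + S_B(t)) /
#'   (SV(A) + SV(B))` with `SV(X) = sum of S_X`; symmetric, in \[0, 1\],
#'   and 1 for identical terms.
#' @export
wang_similarity <- function(a, b, dag) {
  sa <- s_values(a, dag)
  sb <- s_values(b, dag)
  wang_from_svalues(sa, sb)
}

wang_from_svalues <- function(sa, sb) {
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

#' Pairwise similarity matrix over a term set
#'
#' S-value maps are computed once per term and reused for all pairs.
#'
#' @param terms character vector of distinct term ids.
#' @param dag an [ontology_dag].
#' @return symmetric numeric matrix with unit diagonal, dimnames `terms`.
#' @export
similarity_matrix <- function(terms, dag) {
  if (anyDuplicated(terms)) stop("duplicate term ids", call. = FALSE)
  maps <- lapply(terms, s_values, dag = dag)
  names(maps) <- terms
  m <- diag(1, length(terms))
  dimnames(m) <- list(terms, terms)
  if (length(terms) > 1) {
    for (i in seq_len(length(terms) - 1)) {
      for (j in seq(i + 1, length(terms))) {
        v <- wang_from_svalues(maps[[i]], maps[[j]])
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  m
}

#' Hierarchically cluster terms from a similarity matrix
#'
#' Agglomerates on the distance `1 - sim` with the chosen linkage and cuts
#' the dendrogram so that merges at height greater than `cut_height` are
#' broken. Cluster labels are deterministic: ordered by cluster size
#' descending, ties by the lexicographically smallest member term id, so
#' the labelling is invariant to the input term order.
#'
#' @param matrix square similarity matrix as from [similarity_matrix()].
#' @param linkage `"average"` (UPGMA, the default), `"complete"` or
#'   `"single"`.
#' @param cut_height dendrogram cut height in \[0, 1\]; default 0.7.
#' @return object of class `term_clusters`: list with `assignment` (named
#'   integer vector term -> label), `merges` and `heights` (the
#'   agglomeration history), `cut_height`, `linkage`.
#' @export
cluster_terms <- function(matrix, linkage = c("average", "complete", "single"),
                          cut_height = 0.7) {
  linkage <- match.arg(linkage)
  if (!is.numeric(cut_height) || cut_height < 0 || cut_height > 1) {
    stop("cut_height must lie in [0, 1]", call. = FALSE)
  }
  terms <- rownames(matrix)
  stopifnot(!is.null(terms), nrow(matrix) == ncol(matrix))
  if (length(terms) == 1) {
    assignment <- stats::setNames(1L, terms)
    return(structure(list(assignment = assignment,
                          merges = matrix(integer(0), ncol = 2),
                          heights = numeric(0), cut_height = cut_height,
                          linkage = linkage),
                     class = "term_clusters"))
  }
  ord <- order(terms, method = "radix")  # canonical input order
  m <- matrix[ord, ord, drop = FALSE]
  d <- stats::as.dist(1 - m)
  hc <- stats::hclust(d, method = linkage)
  if (is.unsorted(hc$height)) {
    # can occur for non-monotone linkages only; none offered here
    stop("non-monotone merge heights", call. = FALSE)
  }
  raw <- stats::cutree(hc, h = cut_height)
  assignment <- relabel_clusters(raw)
  structure(list(assignment = assignment, merges = hc$merge,
                 heights = hc$height, cut_height = cut_height,
                 linkage = linkage),
            class = "term_clusters")
}

# Deterministic labels: size descending, then smallest member term id.
relabel_clusters <- function(raw) {
  groups <- split(names(raw), raw)
  sizes <- lengths(groups)
  mins <- vapply(groups, min, character(1))
  ord <- order(-sizes, mins, method = "radix")
  new_label <- stats::setNames(seq_along(ord), names(groups)[ord])
  out <- stats::setNames(unname(new_label[as.character(raw)]), names(raw))
  out[order(names(out), method = "radix")]
}

#' @export
print.term_clusters <- function(x, ...) {
  cat("term_clusters:", length(x$assignment), "terms in",
      max(x$assignment), "cluster(s) at cut", x$cut_height,
      paste0("(", x$linkage, " linkage)\n"))
  invisible(x)
}

#' Tabulate clusters of at least a minimum size
#'
#' @param assignment a `term_clusters` object (or its named assignment
#'   vector).
#' @param min_size smallest cluster size to report (default 2, matching
#'   the convention of highlighting only multi-term clusters).
#' @return data frame with columns `cluster`, `size`, `members`
#'   (`"//"`-joined, sorted term ids) for clusters of size >= `min_size`;
#'   the smaller clusters are attached as attribute `"singletons"`.
#' @export
report_clusters <- function(assignment, min_size = 2) {
  stopifnot(min_size >= 1)
  if (inherits(assignment, "term_clusters")) {
    assignment <- assignment$assignment
  }
  groups <- split(names(assignment), assignment)
  sizes <- lengths(groups)
  keep <- names(groups)[sizes >= min_size]
  keep <- keep[order(as.integer(keep))]
  out <- data.frame(
    cluster = as.integer(keep),
    size = unname(sizes[keep]),
    members = vapply(groups[keep],
                     function(g) paste(sort(g), collapse = LIST_SEP),
                     character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "singletons") <- sort(unlist(groups[sizes < min_size],
                                         use.names = FALSE))
  out
}

#' Write a similarity matrix as TSV
#'
#' @param matrix similarity matrix with term-id dimnames.
#' @param path output path; term ids become the first column and the
#'   header.
#' @export
write_similarity_matrix <- function(matrix, path) {
  df <- data.frame(term_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}
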