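# Disease-ontology DAG container.
#
# Terms are identifiers with display names; edges run child -> parent and
# carry a relation label; each relation maps to a semantic contribution
# factor in (0,1) used by the Wang similarity measure. Gene annotations
# attach to terms and may be propagated to ancestors.

#' Default semantic contribution factors per relation
#'
#' The conventional Wang-method constants: `is_a` contributes 0.8 and
#' `part_of` 0.6 per edge; any other relation gets the configurable default.
#' @export
default_relation_weights <- function() c(is_a = 0.8, part_of = 0.6)

#' Construct an ontology DAG
#'
#' @param terms data frame with columns `term_id`, `term_name`.
#' @param edges data frame with columns `child`, `parent`, `relation`
#'   (child -> parent links).
#' @param annotations named list mapping `term_id` to a character vector of
#'   gene symbols.
#' @param relation_weights named numeric vector mapping relation labels to
#'   semantic contribution factors, all strictly in (0, 1).
#' @param default_weight factor for relations absent from
#'   `relation_weights`.
#' @return an object of class `ontology_dag` with elements `terms`, `edges`
#'   (with a resolved `weight` column), `annotations`, `roots`.
#' @export
ontology_dag <- function(terms, edges,
                         annotations = list(),
                         relation_weights = default_relation_weights(),
                         default_weight = 0.7) {
  stopifnot(all(c("term_id", "term_name") %in% names(terms)))
  if (anyDuplicated(terms$term_id)) {
    stop("duplicate term identifiers", call. = FALSE)
  }
  if (nrow(edges) == 0) {
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  if (any(!c(relation_weights, default_weight) > 0) ||
      any(!c(relation_weights, default_weight) < 1)) {
    stop("relation weights must be strictly between 0 and 1", call. = FALSE)
  }
  dangling <- setdiff(c(edges$child, edges$parent), terms$term_id)
  if (length(dangling) > 0) {
    stop("structural error: edge references unknown term(s): ",
         paste(utils::head(dangling, 5), collapse = ", "), call. = FALSE)
  }
  cyc <- find_cycle(terms$term_id, edges)
  if (!is.null(cyc)) {
    stop("structural error: ontology contains a cycle: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  unknown_ann <- setdiff(names(annotations), terms$term_id)
  if (length(unknown_ann) > 0) {
    stop("annotations reference unknown term(s): ",
         paste(utils::head(unknown_ann, 5), collapse = ", "), call. = FALSE)
  }
  w <- unname(relation_weights[edges$relation])
  w[is.na(w)] <- default_weight
  edges$weight <- w
  roots <- setdiff(terms$term_id, edges$child)
  structure(
    list(terms = terms, edges = edges,
         annotations = lapply(annotations, function(g) sort(unique(g))),
         relation_weights = relation_weights,
         default_weight = default_weight, roots = roots),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", nrow(x$terms), "terms,", nrow(x$edges), "edges,",
      length(x$roots), "root(s),", length(x$annotations),
      "annotated term(s)\n")
  invisible(x)
}

# Returns one directed cycle (as a vector of term ids, closed) or NULL.
# igraph::is_dag does the fast check; a DFS recovers a witness cycle for
# the error message.
find_cycle <- function(term_ids, edges) {
  if (nrow(edges) == 0) return(NULL)
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = term_ids))
  if (igraph::is_dag(g)) return(NULL)
  adj <- split(edges$parent, edges$child)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  dfs <- function(v) {
    st <- get0(v, envir = state, ifnotfound = 0L)
    if (st == 1L) {  # back edge: close the cycle
      i <- match(v, path)
      return(c(path[i:length(path)], v))
    }
    if (st == 2L) return(NULL)
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (p in adj[[v]]) {
      res <- dfs(p)
      if (!is.null(res)) return(res)
    }
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
    NULL
  }
  for (v in unique(edges$child)) {
    res <- dfs(v)
    if (!is.null(res)) return(res)
  }
  NULL  # unreachable when is_dag() was FALSE
}

#' Read an ontology from OBO or edge-list TSV
#'
#' @param path input file.
#' @param dialect `"obo"` for an OBO stanza file, `"edgelist"` for a TSV
#'   with columns `child_id`, `parent_id`, `relation` (optional
#'   `child_name`, `parent_name`), or `"auto"` to pick by extension.
#' @inheritParams ontology_dag
#' @return an [ontology_dag]. Acyclicity is verified on load; a cycle or a
#'   dangling parent raises a structural error.
#' @export
read_ontology <- function(path, dialect = c("auto", "obo", "edgelist"),
                          relation_weights = default_relation_weights(),
                          default_weight = 0.7) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.obo$", path, ignore.case = TRUE)) "obo" else "edgelist"
  }
  parsed <- if (dialect == "obo") parse_obo(path) else parse_edgelist(path)
  ontology_dag(parsed$terms, parsed$edges,
               relation_weights = relation_weights,
               default_weight = default_weight)
}

parse_edgelist <- function(path) {
  df <- read_tsv_strict(path, required = c("child_id", "parent_id", "relation"))
  if (is.null(df) || nrow(df) == 0) {
    return(list(terms = data.frame(term_id = character(0),
                                   term_name = character(0)),
                edges = data.frame(child = character(0),
                                   parent = character(0),
                                   relation = character(0))))
  }
  ids <- unique(c(df$child_id, df$parent_id))
  names_map <- stats::setNames(ids, ids)
  if ("child_name" %in% names(df)) {
    names_map[df$child_id] <- df$child_name
  }
  if ("parent_name" %in% names(df)) {
    names_map[df$parent_id] <- df$parent_name
  }
  list(
    terms = data.frame(term_id = ids, term_name = unname(names_map[ids]),
                       stringsAsFactors = FALSE),
    edges = data.frame(child = df$child_id, parent = df$parent_id,
                       relation = df$relation, stringsAsFactors = FALSE)
  )
}

# Minimal OBO parser: [Term] stanzas with id, name, is_a and
# relationship tag-values. Obsolete terms are skipped.
parse_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  ids <- character(0); nms <- character(0)
  e_child <- character(0); e_parent <- character(0); e_rel <- character(0)
  cur <- NULL; cur_name <- NA_character_; in_term <- FALSE; obsolete <- FALSE
  flush <- function() {
    if (in_term && !is.null(cur) && !obsolete) {
      ids <<- c(ids, cur)
      nms <<- c(nms, if (is.na(cur_name)) cur else cur_name)
    }
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE; cur <- NULL; cur_name <- NA_character_; obsolete <- FALSE
      next
    }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur_name <- trimws(sub("^name:", "", ln))
    else if (grepl("^is_obsolete:\\s*true", ln)) obsolete <- TRUE
    else if (grepl("^is_a:", ln)) {
      e_child <- c(e_child, cur)
      e_parent <- c(e_parent, trimws(sub("^is_a:", "", ln)))
      e_rel <- c(e_rel, "is_a")
    } else if (grepl("^relationship:", ln)) {
      parts <- strsplit(trimws(sub("^relationship:", "", ln)), "\\s+")[[1]]
      if (length(parts) >= 2) {
        e_child <- c(e_child, cur)
        e_parent <- c(e_parent, parts[2])
        e_rel <- c(e_rel, parts[1])
      }
    }
  }
  flush()
  list(
    terms = data.frame(term_id = ids, term_name = nms,
                       stringsAsFactors = FALSE),
    edges = data.frame(child = e_child, parent = e_parent, relation = e_rel,
                       stringsAsFactors = FALSE)
  )
}

#' Read term-to-gene annotations
#'
#' @param path TSV with columns `term_id`, `gene`.
#' @return named list mapping term id to unique upper-cased gene symbols.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_strict(path, required = c("term_id", "gene"))
  if (is.null(df) || nrow(df) == 0) return(list())
  lapply(split(toupper(trimws(df$gene)), df$term_id),
         function(g) sort(unique(g)))
}

#' Attach annotations to an ontology
#'
#' @param dag an [ontology_dag].
#' @param annotations named list mapping term id to gene symbols.
#' @return the DAG with annotations replaced (validated against the term
#'   set).
#' @export
set_annotations <- function(dag, annotations) {
  stopifnot(inherits(dag, "ontology_dag"))
  ontology_dag(dag$terms, dag$edges[, c("child", "parent", "relation")],
               annotations = annotations,
               relation_weights = dag$relation_weights,
               default_weight = dag$default_weight)
}

#' Write an ontology as an edge-list TSV
#'
#' @param dag an [ontology_dag].
#' @param path output path.
#' @export
write_ontology_edgelist <- function(dag, path) {
  nm <- stats::setNames(dag$terms$term_name, dag$terms$term_id)
  out <- data.frame(child_id = dag$edges$child,
                    parent_id = dag$edges$parent,
                    relation = dag$edges$relation,
                    child_name = unname(nm[dag$edges$child]),
                    parent_name = unname(nm[dag$edges$parent]),
                    stringsAsFactors = FALSE)
  write_tsv_plain(out, path)
}

# Named list of parents (with edge weights) per child term.
parent_index <- function(dag) {
  if (nrow(dag$edges) == 0) return(list())
  split(
    data.frame(parent = dag$edges$parent, weight = dag$edges$weight,
               stringsAsFactors = FALSE),
    dag$edges$child
  )
}

#' Propagate annotations to ancestors
#'
#' A gene annotated to a term also counts for every ancestor of that term
#' (the true-path rule used by ontology-aware enrichment).
#'
#' @param dag an [ontology_dag] with annotations.
#' @return named list mapping every term with >= 1 (inherited) gene to its
#'   propagated gene set.
#' @export
propagate_annotations <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (length(dag$annotations) == 0) return(list())
  pidx <- parent_index(dag)
  acc <- new.env(parent = emptyenv())
  for (term in names(dag$annotations)) {
    genes <- dag$annotations[[term]]
    for (t in c(term, ancestors_of(term, pidx))) {
      assign(t, c(get0(t, envir = acc, ifnotfound = character(0)), genes),
             envir = acc)
    }
  }
  out <- as.list(acc)
  out <- lapply(out, function(g) sort(unique(g)))
  out[order(names(out))]
}

# All strict ancestors of `term` (BFS over child -> parent edges).
ancestors_of <- function(term, pidx) {
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    parents <- unique(unlist(lapply(frontier, function(t) pidx[[t]]$parent),
                             use.names = FALSE))
    new <- setdiff(parents, seen)
    seen <- c(seen, new)
    frontier <- new
  }
  seen
}
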