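# Over-representation analysis (ORA) of a gene set against ontology term
# annotations.
#
# For a universe of N genes, a term annotated with M of them and a query of
# n genes overlapping the term in k, the enrichment p-value is the
# hypergeometric upper tail P(X >= k). Family-wise error is controlled by
# Bonferroni over the tested terms.

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) where X counts query genes falling in a term of size `M`
#' drawn from a universe of `N` genes with a query of size `n`. Delegates
#' to [stats::phyper()], which evaluates the tail in log space.
#'
#' @param k observed overlap, `0 <= k <= min(M, n)`.
#' @param N universe size.
#' @param M genes annotated to the term within the universe.
#' @param n query genes within the universe.
#' @return the upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, N, M, n) {
  if (any(c(k, N, M, n) != floor(c(k, N, M, n))) || any(c(k, N, M, n) < 0)) {
    stop("k, N, M, n must be non-negative integers", call. = FALSE)
  }
  if (M > N || n > N || k > min(M, n)) {
    stop("parameter bounds violated: need M <= N, n <= N, k <= min(M, n)",
         call. = FALSE)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests and caps at 1; input
#' order is preserved.
#'
#' @param p_values numeric vector with entries in (0, 1].
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Over-representation analysis of a gene set
#'
#' @param query character vector of gene symbols (the validated target
#'   set).
#' @param dag an [ontology_dag] with annotations. A flat single-root
#'   collection (pathway-style gene sets) works identically.
#' @param term_filter numeric length-2 vector `c(min, max)` bounding the
#'   annotated size `M` of tested terms; default `c(5, 500)`. Use
#'   `c(1, Inf)` to disable.
#' @param universe `"annotated"` (all genes annotated to >= 1 term, the
#'   default ORA convention) or `"custom"` with `custom_universe` supplied.
#' @param custom_universe character vector of gene symbols when
#'   `universe = "custom"`.
#' @param propagate propagate annotations to ancestor terms before testing
#'   (default `TRUE`).
#' @param adjust_over `"tested"` (Bonferroni multiplier = number of terms
#'   actually tested, i.e. with `k >= 1` and `M` within bounds) or
#'   `"all"` (all terms with annotations).
#' @return data frame of class `enrichment_result`, one row per tested
#'   term, sorted by `p` ascending then `term_id`, with columns `term_id`,
#'   `term_name`, `k`, `n`, `M`, `N`, `gene_ratio`, `bg_ratio`, `p`,
#'   `p_adj` and list-column `hits`. Query genes outside the universe are
#'   dropped with a message. Zero overlap everywhere yields a zero-row
#'   result; an empty effective query is an error.
#' @export
run_ora <- function(query, dag, term_filter = c(5, 500),
                    universe = c("annotated", "custom"),
                    custom_universe = NULL, propagate = TRUE,
                    adjust_over = c("tested", "all")) {
  stopifnot(inherits(dag, "ontology_dag"))
  universe <- match.arg(universe)
  adjust_over <- match.arg(adjust_over)
  stopifnot(length(term_filter) == 2, term_filter[1] >= 1)

  ann <- if (propagate) propagate_annotations(dag) else dag$annotations
  ann <- ann[lengths(ann) > 0]
  uni <- if (universe == "custom") {
    if (is.null(custom_universe)) {
      stop("custom universe requested but not supplied", call. = FALSE)
    }
    sort(unique(toupper(custom_universe)))
  } else {
    sort(unique(unlist(ann, use.names = FALSE)))
  }
  query <- unique(toupper(query))
  dropped <- setdiff(query, uni)
  if (length(dropped) > 0) {
    message(length(dropped), " query gene(s) outside the universe dropped")
  }
  q <- intersect(query, uni)
  if (length(q) == 0) stop("no testable genes", call. = FALSE)

  N <- length(uni)
  n <- length(q)
  term_ids <- sort(names(ann))
  rows <- lapply(term_ids, function(t) {
    genes_t <- intersect(ann[[t]], uni)
    M <- length(genes_t)
    hits <- intersect(q, genes_t)
    k <- length(hits)
    if (k < 1 || M < term_filter[1] || M > term_filter[2]) return(NULL)
    list(term_id = t, k = k, M = M, hits = sort(hits))
  })
  rows <- Filter(Negate(is.null), rows)
  n_all <- sum(vapply(term_ids, function(t) {
    length(intersect(ann[[t]], uni)) > 0
  }, logical(1)))
  if (length(rows) == 0) {
    return(empty_enrichment_result())
  }
  res <- data.frame(
    term_id = vapply(rows, `[[`, character(1), "term_id"),
    k = vapply(rows, `[[`, integer(1), "k"),
    M = vapply(rows, `[[`, integer(1), "M"),
    stringsAsFactors = FALSE
  )
  nm <- stats::setNames(dag$terms$term_name, dag$terms$term_id)
  res$term_name <- unname(nm[res$term_id])
  res$n <- n
  res$N <- N
  res$gene_ratio <- res$k / n
  res$bg_ratio <- res$M / N
  res$p <- mapply(hypergeom_upper_tail, res$k, N, res$M, n)
  m <- if (adjust_over == "tested") nrow(res) else n_all
  res$p_adj <- pmin(res$p * m, 1)
  res$hits <- lapply(rows, `[[`, "hits")
  res <- res[order(res$p, res$term_id, method = "radix"),
             c("term_id", "term_name", "k", "n", "M", "N",
               "gene_ratio", "bg_ratio", "p", "p_adj", "hits")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

empty_enrichment_result <- function() {
  res <- data.frame(term_id = character(0), term_name = character(0),
                    k = integer(0), n = integer(0), M = integer(0),
                    N = integer(0), gene_ratio = numeric(0),
                    bg_ratio = numeric(0), p = numeric(0),
                    p_adj = numeric(0), stringsAsFactors = FALSE)
  res$hits <- list()
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Dot-plot data table for significant terms
#'
#' Tabular backing of the enrichment dot plot: significant terms with their
#' gene ratio, ready for plotting.
#'
#' @param results an `enrichment_result` from [run_ora()].
#' @param alpha significance threshold on the adjusted p-value (default
#'   0.05).
#' @return data frame with columns `term_id`, `term_name`, `gene_ratio`,
#'   `k`, `p_adj`, restricted to `p_adj < alpha` and sorted by `gene_ratio`
#'   descending (ties by `p_adj` then `term_id`).
#' @export
dotplot_table <- function(results, alpha = 0.05) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha <= 1)
  sel <- results[results$p_adj < alpha, , drop = FALSE]
  sel <- sel[order(-sel$gene_ratio, sel$p_adj, sel$term_id,
                   method = "radix"), , drop = FALSE]
  out <- data.frame(term_id = sel$term_id, term_name = sel$term_name,
                    gene_ratio = sel$gene_ratio, k = sel$k,
                    p_adj = sel$p_adj, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write an enrichment result table as TSV
#'
#' @param results an `enrichment_result`.
#' @param path output path. The `hits` list-column is `"//"`-joined.
#' @export
write_enrichment <- function(results, path) {
  out <- as.data.frame(results)
  out$hits <- join_list_cell(results$hits)
  write_tsv_plain(out, path)
}
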