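# Shared fixtures and independent oracles.

# --- tiny ontologies used across similarity tests -------------------------

# chain D -> A -> C (is_a edges, weight 0.8)
chain_dag <- function() {
  ontology_dag(
    terms = data.frame(term_id = c("D", "A", "C"),
                       term_name = c("D", "A", "C")),
    edges = data.frame(child = c("D", "A"), parent = c("A", "C"),
                       relation = "is_a")
  )
}

# siblings A, B under root C
sibling_dag <- function() {
  ontology_dag(
    terms = data.frame(term_id = c("A", "B", "C"),
                       term_name = c("A", "B", "C")),
    edges = data.frame(child = c("A", "B"), parent = c("C", "C"),
                       relation = "is_a")
  )
}

# diamond: A -> B, A -> C, B -> R, C -> R
diamond_dag <- function() {
  ontology_dag(
    terms = data.frame(term_id = c("A", "B", "C", "R"),
                       term_name = c("A", "B", "C", "R")),
    edges = data.frame(child = c("A", "A", "B", "C"),
                       parent = c("B", "C", "R", "R"),
                       relation = "is_a")
  )
}

# random rooted DAG: levels of terms, every non-root term gets >= 1 parent
# from the level above (guaranteed acyclic by construction)
random_dag <- function(n_levels = 4, per_level = 4) {
  ids <- paste0("L", rep(seq_len(n_levels), each = per_level), "N",
                rep(seq_len(per_level), n_levels))
  ids <- c("ROOT", ids)
  level <- c(0, rep(seq_len(n_levels), each = per_level))
  child <- character(0); parent <- character(0); rel <- character(0)
  for (i in seq_along(ids)[-1]) {
    above <- ids[level == level[i] - 1]
    n_par <- sample(seq_len(min(2, length(above))), 1)
    for (p in sample(above, n_par)) {
      child <- c(child, ids[i]); parent <- c(parent, p)
      rel <- c(rel, sample(c("is_a", "part_of", "regulates"), 1))
    }
  }
  ontology_dag(
    data.frame(term_id = ids, term_name = ids),
    data.frame(child = child, parent = parent, relation = rel)
  )
}

# --- independent oracles --------------------------------------------------

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws:
# the universe is 1..N, the "annotated" genes are 1..M, and every draw of
# size n is generated with utils::combn. Returns P(overlap >= k).
enum_hyper_tail <- function(k, N, M, n) {
  if (k == 0) return(1)
  if (n == 0 || M == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= M)
  mean(overlaps >= k)
}

# Overlap distribution for one (N, M, n): table over k of P(overlap == k).
enum_overlap_counts <- function(N, M, n) {
  if (n == 0) return(c(`0` = 1))
  draws <- utils::combn(N, n)
  tab <- tabulate(colSums(draws <= M) + 1L, nbins = min(M, n) + 1L)
  tab / ncol(draws)
}

# brute-force recount of per-miRNA distinct target genes from a raw pair list
recount_targets <- function(pairs) {
  out <- integer(0)
  for (m in unique(pairs$mirna)) {
    out[m] <- length(unique(pairs$gene[pairs$mirna == m]))
  }
  out
}

# write a small interactions TSV and return its path
write_interactions_fixture <- function(rows) {
  path <- tempfile("interactions", fileext = ".tsv")
  writeLines(c("mirna\tgene\tevidence", rows), path)
  path
}

extdata <- function(name) {
  system.file("extdata", name, package = "mirmultinet", mustWork = TRUE)
}
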