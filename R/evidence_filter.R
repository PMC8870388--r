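# Strong-evidence filtering of miRNA-target interactions.
#
# Records pass when at least one of their free-text evidence strings
# mentions a strong functional assay (reporter/luciferase, immunoblot,
# RT-qPCR). Matching is a case-insensitive substring test after stripping
# non-alphanumeric separators from both sides, so "qRT-PCR", "qRT PCR" and
# "RT-qPCR" all hit the same keywords.

#' Default strong-assay keyword set
#'
#' Covers the reporter-gene, immunoblot and real-time qPCR assay families.
#' @param keywords character vector of keywords, matched case-insensitively
#'   as substrings after stripping non-alphanumeric separators.
#' @param mode `"any"` (a record passes when any evidence string matches
#'   any keyword) or `"all"` (every keyword must be matched by some
#'   evidence string of the record).
#' @return an `evidence_keywords` object.
#' @export
evidence_keywords <- function(keywords = c("luciferase", "reporter",
                                           "western", "immunoblot",
                                           "qpcr", "qrt-pcr", "real-time"),
                              mode = c("any", "all")) {
  mode <- match.arg(mode)
  keywords <- tolower(trimws(keywords))
  keywords <- keywords[nzchar(keywords)]
  if (length(keywords) == 0) stop("keyword set must be non-empty", call. = FALSE)
  structure(list(keywords = keywords, mode = mode),
            class = "evidence_keywords")
}

strip_separators <- function(x) gsub("[^a-z0-9]+", "", tolower(x))

#' Does an evidence list satisfy the keyword filter?
#'
#' @param evidence character vector of free-text evidence strings (possibly
#'   empty; an empty list never passes).
#' @param keywords an [evidence_keywords] object.
#' @return logical scalar.
#' @examples
#' classify_evidence(c("Luciferase reporter assay", "Microarray"),
#'                   evidence_keywords())  # TRUE
#' @export
classify_evidence <- function(evidence, keywords = evidence_keywords()) {
  stopifnot(inherits(keywords, "evidence_keywords"))
  if (length(evidence) == 0) return(FALSE)
  ev <- strip_separators(evidence)
  kw <- strip_separators(keywords$keywords)
  hit <- vapply(kw, function(k) any(grepl(k, ev, fixed = TRUE)), logical(1))
  if (keywords$mode == "any") any(hit) else all(hit)
}

#' Filter interactions down to the strong-evidence pair set
#'
#' Keeps records whose evidence passes [classify_evidence()], then
#' deduplicates to unique (miRNA, gene) pairs. The result is the validated
#' target set used by enrichment and network assembly.
#'
#' @param records an `interaction_records` data frame from
#'   [read_interactions()].
#' @param keywords an [evidence_keywords] object.
#' @return data frame of class `interaction_set` with columns `mirna`,
#'   `gene`, `n_evidence` (distinct evidence strings across passing records
#'   of the pair), `sources` (`"//"`-joined provenance labels), sorted by
#'   miRNA then gene.
#' @export
filter_interactions <- function(records, keywords = evidence_keywords()) {
  pass <- vapply(records$evidence, classify_evidence, logical(1),
                 keywords = keywords)
  kept <- records[pass, , drop = FALSE]
  if (nrow(kept) == 0) {
    out <- data.frame(mirna = character(0), gene = character(0),
                      n_evidence = integer(0), sources = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("interaction_set", "data.frame")
    return(out)
  }
  key <- paste(kept$mirna, kept$gene, sep = "\r")
  groups <- split(seq_len(nrow(kept)), key)
  rows <- lapply(groups, function(idx) {
    data.frame(
      mirna = kept$mirna[idx[1]], gene = kept$gene[idx[1]],
      n_evidence = length(unique(unlist(kept$evidence[idx]))),
      sources = paste(sort(unique(kept$source[idx])), collapse = LIST_SEP),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' Build an interaction set directly from pairs
#'
#' Convenience constructor for fixtures and for re-loading a written pair
#' table.
#'
#' @param mirna,gene character vectors of equal length.
#' @return an `interaction_set` with the same ordering and deduplication
#'   contract as [filter_interactions()].
#' @export
interaction_set <- function(mirna, gene) {
  stopifnot(length(mirna) == length(gene))
  df <- data.frame(mirna = normalize_mirna_name(mirna),
                   gene = toupper(trimws(gene)), stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  df$n_evidence <- NA_integer_
  df$sources <- NA_character_
  df <- df[order(df$mirna, df$gene, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interaction_set", "data.frame")
  df
}

#' Write / read the filtered pair table
#'
#' @param pairs an `interaction_set`.
#' @param path TSV path.
#' @export
write_interaction_set <- function(pairs, path) {
  write_tsv_plain(as.data.frame(pairs), path)
}

#' @rdname write_interaction_set
#' @export
read_interaction_set <- function(path) {
  df <- read_tsv_strict(path, required = c("mirna", "gene"))
  if (is.null(df)) {
    df <- data.frame(mirna = character(0), gene = character(0))
  }
  out <- interaction_set(df$mirna, df$gene)
  if ("n_evidence" %in% names(df)) {
    out$n_evidence <- as.integer(df$n_evidence)[order(df$mirna, df$gene,
                                                      method = "radix")]
  }
  if ("sources" %in% names(df)) {
    out$sources <- df$sources[order(df$mirna, df$gene, method = "radix")]
  }
  out
}
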