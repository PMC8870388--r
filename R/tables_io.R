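# Readers and writers for the five input table shapes.
#
# All tables are tab-separated UTF-8 with a header row; list-valued cells
# (evidence strings) are "//"-joined. Gene symbols are upper-cased and miRNA
# names canonicalized at read time; all downstream comparisons are
# case-sensitive.

#' Canonicalize a mature miRNA name
#'
#' Strips a leading three-letter species prefix (e.g. `"hsa-"`), fixes the
#' capitalization of the family token (`"miR-"`, `"let-"`), and lower-cases
#' the remainder while preserving the arm suffix, so that `"hsa-miR-138-5p"`
#' and `"miR-138-5p"` map to the same name.
#'
#' @param raw character vector of miRNA names.
#' @return character vector of canonical names.
#' @examples
#' normalize_mirna_name("hsa-miR-138-5p")  # "miR-138-5p"
#' normalize_mirna_name("HSA-LET-7A-5P")   # "let-7a-5p"
#' @export
normalize_mirna_name <- function(raw) {
  if (length(raw) == 0) return(character(0))
  if (!is.character(raw) || anyNA(raw) || any(!nzchar(trimws(raw)))) {
    stop("miRNA name must be a non-empty string", call. = FALSE)
  }
  x <- trimws(raw)
  # species prefix only when followed by a miR/let family token
  x <- sub("^[A-Za-z]{3}-(?=(mir|let))", "", x, perl = TRUE, ignore.case = TRUE)
  fam <- regexpr("^(mir|let)", x, ignore.case = TRUE)
  canon <- function(name) {
    m <- regmatches(name, regexpr("^(mir|let)", name, ignore.case = TRUE))
    if (length(m) == 0) return(name)  # non-standard name kept as-is
    rest <- tolower(substr(name, nchar(m) + 1L, nchar(name)))
    head <- if (tolower(m) == "mir") "miR" else "let"
    paste0(head, rest)
  }
  vapply(x, canon, character(1), USE.NAMES = FALSE)
}

#' Read a miRNA-target interaction table
#'
#' @param path TSV file with mandatory columns `mirna`, `gene`, `evidence`
#'   (the evidence cell is a `"//"`-joined list; it may be empty). Extra
#'   columns are ignored.
#' @param source provenance label attached to every record.
#' @return data frame of class `interaction_records` with columns `mirna`
#'   (canonical name), `gene` (upper-case symbol), `evidence` (list column
#'   of character vectors) and `source`, in file order. Duplicated rows are
#'   kept; deduplication is the filter stage's job.
#' @export
read_interactions <- function(path, source = "unknown") {
  df <- read_tsv_strict(path, required = c("mirna", "gene", "evidence"))
  if (is.null(df) || nrow(df) == 0) {
    return(new_interaction_records(character(0), character(0), list(),
                                   character(0)))
  }
  new_interaction_records(
    mirna = normalize_mirna_name(df$mirna),
    gene = toupper(trimws(df$gene)),
    evidence = split_list_cell(df$evidence),
    source = rep(source, nrow(df))
  )
}

new_interaction_records <- function(mirna, gene, evidence, source) {
  stopifnot(length(mirna) == length(gene),
            length(mirna) == length(evidence),
            length(mirna) == length(source))
  if (any(!nzchar(mirna)) || any(!nzchar(gene))) {
    stop("interaction records require non-empty mirna and gene", call. = FALSE)
  }
  df <- data.frame(mirna = mirna, gene = gene, stringsAsFactors = FALSE)
  df$evidence <- evidence
  df$source <- source
  class(df) <- c("interaction_records", "data.frame")
  df
}

#' Write interaction records back to TSV
#'
#' Inverse of [read_interactions()]: re-reading the written file yields an
#' identical record sequence.
#'
#' @param records an `interaction_records` data frame.
#' @param path output path.
#' @export
write_interactions <- function(records, path) {
  out <- data.frame(mirna = records$mirna, gene = records$gene,
                    evidence = join_list_cell(records$evidence),
                    source = records$source, stringsAsFactors = FALSE)
  write_tsv_plain(out, path)
}

#' Read a miRNA-disease association table
#'
#' @param path TSV with columns `mirna`, `term_id`, `term_name`.
#' @param dag optional [ontology_dag]; when supplied, associations whose
#'   `term_id` is absent from the ontology are flagged in an `orphan` column.
#' @return data frame with columns `mirna`, `term_id`, `term_name` and
#'   logical `orphan`.
#' @export
read_disease_associations <- function(path, dag = NULL) {
  df <- read_tsv_strict(path, required = c("mirna", "term_id", "term_name"))
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(mirna = character(0), term_id = character(0),
                      term_name = character(0), orphan = logical(0)))
  }
  out <- data.frame(mirna = normalize_mirna_name(df$mirna),
                    term_id = df$term_id, term_name = df$term_name,
                    stringsAsFactors = FALSE)
  out$orphan <- if (is.null(dag)) FALSE else !(out$term_id %in% dag$terms$term_id)
  out
}

#' Read a drug-target table
#'
#' @param path TSV with columns `drug`, `gene`.
#' @return data frame with columns `drug`, `gene` (upper-cased),
#'   deduplicated at the pair level, in first-occurrence order.
#' @export
read_drug_targets <- function(path) {
  df <- read_tsv_strict(path, required = c("drug", "gene"))
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(drug = character(0), gene = character(0)))
  }
  out <- data.frame(drug = trimws(df$drug), gene = toupper(trimws(df$gene)),
                    stringsAsFactors = FALSE)
  out[!duplicated(out[c("drug", "gene")]), , drop = FALSE]
}

#' Read a SNP annotation table
#'
#' @param path TSV with columns `rsid`, `gene`, `chromosome`, `position`.
#'   Positions are 1-based coordinates as printed by dbSNP; they are stored
#'   for display only, never used in arithmetic.
#' @return data frame with columns `rsid`, `gene`, `chromosome`,
#'   `position` (integer).
#' @export
read_snps <- function(path) {
  df <- read_tsv_strict(path, required = c("rsid", "gene", "chromosome",
                                           "position"))
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(rsid = character(0), gene = character(0),
                      chromosome = character(0), position = integer(0)))
  }
  rsid <- trimws(df$rsid)
  bad <- !grepl("^rs[0-9]+$", rsid)
  if (any(bad)) {
    stop("invalid rsID(s): ", paste(utils::head(rsid[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(df$position))
  if (anyNA(pos) || any(pos <= 0)) {
    stop("SNP positions must be positive 1-based integers", call. = FALSE)
  }
  data.frame(rsid = rsid, gene = toupper(trimws(df$gene)),
             chromosome = trimws(df$chromosome), position = pos,
             stringsAsFactors = FALSE)
}

#' Write a plain data-frame table as TSV
#'
#' Generic writer for drug, SNP and association tables so that any loaded
#' table round-trips exactly.
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_table_tsv <- function(df, path) {
  df <- as.data.frame(df)
  df$orphan <- NULL
  write_tsv_plain(df, path)
}
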