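# Shared helpers: rounding, TSV dialect, small validators.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (10.625 -> 10.63), as opposed to base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length.
#' @export
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# The package TSV dialect: tab separated, UTF-8, header row, "//" joins
# list-valued cells.
LIST_SEP <- "//"

read_tsv_strict <- function(path, required = character()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    return(NULL)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("format error in ", path, ": missing mandatory column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

join_list_cell <- function(x) {
  vapply(x, function(v) paste(v, collapse = LIST_SEP), character(1))
}

split_list_cell <- function(x) {
  out <- strsplit(x, LIST_SEP, fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}
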