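#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rnorm runif integrate plnorm qlnorm setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet `{A,C,G,T,N}` (case
#' preserved).  Involution: `revcomp(revcomp(x)) == x`.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, NULL), function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Derive a reproducible child seed for a pipeline stage
#'
#' A single user-facing seed fans out into per-stage seeds by stable string
#' hashing of the stage name, so individual stages can be re-run in
#' isolation while remaining tied to the global seed.  Results always lie
#' in `[1, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param stage character stage label, e.g. `"make_genome"`.
#' @return a single integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647
  h <- 17
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% m
  as.integer((abs(seed) %% m * 1000003 + h) %% (m - 1) + 1)
}

hamming <- function(a, b) {
  sum(strsplit(a, NULL)[[1]] != strsplit(b, NULL)[[1]])
}

#' Write a TSV with a versioned comment header
#'
#' All tabular outputs carry comment lines recording the tool version, the
#' coordinate convention and the parameters in force, so every result file
#' is self-describing.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param params named list serialised into the header, or `NULL`.
#' @return invisibly, `path`.
#' @export
write_tsv_header <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header_lines(params), con)
  df <- flatten_list_columns(df)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

output_header_lines <- function(params = NULL) {
  lines <- c(
    sprintf("# uorfscan %s", as.character(packageVersion("uorfscan"))),
    "# coordinates: 0-based half-open internally; 1-based only in VCF/TSV position columns"
  )
  if (length(params)) {
    kv <- vapply(names(params), function(n)
      sprintf("%s=%s", n, paste(format(params[[n]]), collapse = ",")),
      character(1))
    lines <- c(lines, paste0("# config: ", paste(kv, collapse = "; ")))
  }
  lines
}

flatten_list_columns <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(x) {
        if (is.matrix(x)) blocks_to_str(x) else paste(x, collapse = ",")
      }, character(1))
    }
  }
  df
}

#' Encode / decode genomic block lists
#'
#' Blocks are two-column integer matrices of 0-based half-open
#' `[start, end)` intervals, sorted by start.  The string form
#' `"start-end;start-end"` is used in TSV catalogs and as a deduplication
#' key.
#'
#' @param blocks integer matrix with columns `start`, `end`.
#' @return `blocks_to_str`: a single string. `str_to_blocks`: a matrix.
#' @export
blocks_to_str <- function(blocks) {
  if (is.null(blocks) || nrow(blocks) == 0) return("")
  paste(sprintf("%d-%d", blocks[, 1], blocks[, 2]), collapse = ";")
}

#' @rdname blocks_to_str
#' @param s string produced by [blocks_to_str()].
#' @export
str_to_blocks <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p), integer(2)))
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

empty_df <- function(...) {
  cols <- list(...)
  as.data.frame(cols, stringsAsFactors = FALSE)
}
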