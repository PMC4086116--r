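# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
norm1 <- function(x) {
  s <- sum(x)
  if (s > 0) x / s else x
}

# L1-normalize, falling back to `fallback` when the vector has no mass
# (disconnected component hit by the walk); keeps iterations well defined.
norm1_or <- function(x, fallback) {
  s <- sum(x)
  if (s > 0) x / s else fallback
}

stop_mr <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_mr <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)

#' Write a table as tab-separated text with a deterministic row order
#'
#' Rows are ordered by `score_col` descending with ties broken by `id_col`
#' ascending, so repeated runs produce byte-identical files.
#'
#' @param table a data.frame
#' @param path output file path
#' @param score_col,id_col column names used for ordering; pass `NULL` for
#'   `score_col` to keep the incoming row order
#' @return the path, invisibly
#' @export
write_ranked_tsv <- function(table, path, score_col = "final", id_col = names(table)[1]) {
  stopifnot(is.data.frame(table))
  if (!is.null(score_col)) {
    if (!score_col %in% names(table)) stop_mr("column '%s' not in table", score_col)
    if (!id_col %in% names(table)) stop_mr("column '%s' not in table", id_col)
    table <- table[order(-xtfrm(table[[score_col]]), table[[id_col]]), , drop = FALSE]
  }
  # flatten list columns (e.g. members_hit) to ';'-joined strings
  for (nm in names(table)) {
    if (is.list(table[[nm]])) {
      table[[nm]] <- vapply(table[[nm]], function(v) paste(v, collapse = ";"), character(1))
    }
  }
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
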