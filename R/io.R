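## Delimited-text readers and writers. Everything is plain TSV/CSV: the
## pipeline's inputs are p-value lists and expression tables.

#' Read a p-value vector from a text file
#'
#' Reads either a plain list of p-values (one per line, `#` comments
#' allowed) or, when `column` is given, a named column of a delimited table
#' with a header row.
#'
#' @param path file path.
#' @param column optional column name in a delimited table.
#' @param sep field separator for the table form (default tab; use `","`
#'   for CSV).
#' @return validated numeric vector of p-values.
#' @export
read_pvalues <- function(path, column = NULL, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(column)) {
    p <- tryCatch(
      scan(path, what = double(), comment.char = "#", quiet = TRUE),
      error = function(e) stop(sprintf("cannot parse '%s' as p-values: %s",
                                       path, conditionMessage(e)),
                               call. = FALSE)
    )
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (!column %in% names(tab)) {
      stop(sprintf("column '%s' not found in '%s' (columns: %s)",
                   column, path, paste(names(tab), collapse = ", ")),
           call. = FALSE)
    }
    p <- tab[[column]]
  }
  as_pvalues(p)
}

#' Read an expression matrix with group labels
#'
#' Reads a delimited text matrix (header row of sample ids, first column
#' gene ids) and attaches a two-group sample labelling.  Validation names
#' the offending rows or labels: duplicate gene ids, non-numeric cells, or
#' groups with fewer than two samples are errors.
#'
#' @param path file path of the delimited matrix.
#' @param labels either a vector of group labels, one per sample (in column
#'   order), or the path of a label file with one label per line.
#' @param sep field separator (default tab).
#' @return a list with `values` (numeric matrix, gene ids as row names),
#'   `gene_ids` and `group_labels` (factor with two levels), ready for
#'   [row_t_tests()].
#' @export
read_expression_matrix <- function(path, labels, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 3L) {
    stop("expression table needs a gene-id column plus at least two samples",
         call. = FALSE)
  }
  ids <- as.character(tab[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  num <- tab[-1L]
  for (j in seq_along(num)) {
    if (!is.numeric(num[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(num[[j]]))))
      stop(sprintf("non-numeric expression value for gene '%s', sample '%s'",
                   ids[bad[1L]], names(num)[j]), call. = FALSE)
    }
  }
  x <- as.matrix(num)
  rownames(x) <- ids
  if (anyNA(x)) {
    bad <- which(rowSums(is.na(x)) > 0L)
    stop("missing values in genes: ",
         paste(utils::head(ids[bad], 5L), collapse = ", "), call. = FALSE)
  }
  if (length(labels) == 1L && is.character(labels) && file.exists(labels)) {
    labels <- scan(labels, what = character(), quiet = TRUE)
  }
  if (length(labels) != ncol(x)) {
    stop(sprintf("%d labels supplied for %d samples", length(labels),
                 ncol(x)), call. = FALSE)
  }
  groups <- as.factor(labels)
  if (nlevels(groups) != 2L) {
    stop(sprintf("labels must define exactly two groups, found: %s",
                 paste(levels(groups), collapse = ", ")), call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  list(values = x, gene_ids = ids, group_labels = groups)
}

#' Write a result table as delimited text
#'
#' Writes a data frame with a stable column order and full floating-point
#' precision.  The file is written to a temporary sibling first and moved
#' into place, so a failed write never leaves a partial output file.
#'
#' @param table a data frame.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return invisibly, `path`.
#' @export
write_results <- function(table, path, sep = "\t") {
  if (!is.data.frame(table)) {
    stop("'table' must be a data frame", call. = FALSE)
  }
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  ok <- tryCatch({
    utils::write.table(format(table, digits = 17, trim = TRUE,
                              scientific = NA),
                       tmp, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (ok && !file.rename(tmp, path)) {
    stop("cannot move temporary file into place at ", path, call. = FALSE)
  }
  invisible(path)
}
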