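#' Read an expression matrix from a delimited text file
#'
#' The first row must be a header of marker names. An optional leading
#' column of cell identifiers is detected when its header is empty or
#' `"cell_id"`, or when none of its values parses as a number (a column
#' that is merely partially numeric is treated as corrupt payload, not as
#' identifiers).
#'
#' @param path path to an existing CSV/TSV file.
#' @param delimiter single field-separator character (default comma).
#' @return expression matrix (see [expression_matrix()]).
#' @export
read_expression_csv <- function(path, delimiter = ",") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 1L || nrow(raw) < 1L) {
    stop("empty expression file: ", path, call. = FALSE)
  }
  hdr <- colnames(raw)
  first_as_num <- suppressWarnings(as.numeric(raw[[1L]]))
  has_ids <- ncol(raw) >= 2L &&
    (hdr[1L] %in% c("", "cell_id") || all(is.na(first_as_num)))
  cell_ids <- if (has_ids) raw[[1L]] else NULL
  payload <- raw[if (has_ids) -1L else seq_along(raw)]
  markers <- if (has_ids) hdr[-1L] else hdr # subsetting mangles duplicates
  if (anyDuplicated(markers)) {
    stop("duplicate marker names in header: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  }
  values <- matrix(NA_real_, nrow(payload), ncol(payload))
  for (j in seq_along(payload)) {
    v <- suppressWarnings(as.numeric(payload[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   payload[[j]][bad[1L]], bad[1L], markers[j]), call. = FALSE)
    }
    values[, j] <- v
  }
  expression_matrix(values, markers, cell_ids)
}

#' Write an expression matrix to a delimited text file
#'
#' @param x expression matrix.
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(x, path, delimiter = ",") {
  df <- data.frame(cell_id = rownames(x),
                   as.data.frame(x, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write annotation CSV files
#'
#' Annotation files have columns `cell_id`, `label` and (optionally)
#' `provenance`, one row per cell.
#'
#' @param path file path.
#' @return `read_annotation_csv` returns a data frame with columns
#'   `cell_id`, `label` and `provenance`.
#' @export
read_annotation_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!all(c("cell_id", "label") %in% colnames(df))) {
    stop("annotation file must have 'cell_id' and 'label' columns",
         call. = FALSE)
  }
  if (is.null(df$provenance)) df$provenance <- "unknown"
  df[, c("cell_id", "label", "provenance")]
}

#' @param annotation data frame as returned by [annotate_cells()].
#' @rdname read_annotation_csv
#' @export
write_annotation_csv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
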