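#' Construct and validate a cytometry expression matrix
#'
#' An expression matrix holds continuous (already compensated/transformed)
#' marker intensities, cells in rows and markers in columns. The package
#' represents it as a plain numeric matrix whose column names are the marker
#' identifiers and whose row names are the cell identifiers, the same
#' convention as the `exprs` slot of classic cytometry containers.
#'
#' @param values numeric matrix (cells x markers); coerced to double.
#' @param marker_names character vector of unique, non-empty marker names;
#'   defaults to `colnames(values)`.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   `rownames(values)`, or to `"1".."n"` when absent.
#' @return a validated numeric matrix with marker column names and cell-id
#'   row names.
#' @examples
#' m <- expression_matrix(matrix(rnorm(6), 3, 2), c("CD3", "CD19"))
#' @export
expression_matrix <- function(values,
                              marker_names = colnames(values),
                              cell_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) {
    stop("an expression matrix needs at least one cell", call. = FALSE)
  }
  if (is.null(marker_names)) {
    stop("marker names are required", call. = FALSE)
  }
  marker_names <- as.character(marker_names)
  if (length(marker_names) != ncol(values)) {
    stop("length of 'marker_names' does not match the number of columns",
         call. = FALSE)
  }
  if (any(!nzchar(marker_names))) {
    stop("marker names must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(marker_names)) {
    stop("duplicate marker names: ",
         paste(unique(marker_names[duplicated(marker_names)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at cell %d, marker '%s'",
                 bad[1L], marker_names[bad[2L]]), call. = FALSE)
  }
  if (is.null(cell_ids)) {
    cell_ids <- as.character(seq_len(nrow(values)))
  }
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(values)) {
    stop("length of 'cell_ids' does not match the number of rows",
         call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids", call. = FALSE)
  }
  dimnames(values) <- list(cell_ids, marker_names)
  values
}

#' Arcsinh variance-stabilising transform
#'
#' Applies `asinh(x / cofactor)` element-wise, the standard cytometry
#' preprocessing transform (cofactor 5 is the mass-cytometry convention,
#' 150 is typical for fluorescence). The package otherwise assumes its
#' inputs are already transformed; this is an explicit opt-in.
#'
#' @param x numeric vector or expression matrix.
#' @param cofactor positive scaling constant.
#' @return object of the same shape with transformed values.
#' @examples
#' arcsinh_transform(c(0, 5), cofactor = 5) # 0, asinh(1)
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || !is.finite(cofactor) ||
      cofactor <= 0) {
    stop("'cofactor' must be a single positive number", call. = FALSE)
  }
  asinh(x / cofactor)
}
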