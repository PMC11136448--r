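# Signature dictionary: matching cell signatures against marker-table
# entries. Expansion of an entry into concrete signatures is combinatorial
# (product of per-marker level counts over the free markers), so entries are
# represented by their membership predicate and only materialised on demand.

#' Evaluate an entry's membership predicate over a signature matrix
#'
#' @param groups token groups of one cell-type entry.
#' @param levels_matrix character matrix of level symbols (cells x markers)
#'   whose columns cover every marker the entry references.
#' @return logical vector, `TRUE` for cells whose signature satisfies the
#'   entry (AND tokens fix their marker's symbol, `*` is unconstrained, an
#'   OR group needs at least one token to hold, an XOR group exactly one).
#' @export
entry_satisfies <- function(groups, levels_matrix) {
  n <- nrow(levels_matrix)
  ok <- rep(TRUE, n)
  for (g in groups) {
    missing <- setdiff(g$markers, colnames(levels_matrix))
    if (length(missing)) {
      stop("signature matrix lacks marker(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (g$operator == "AND") {
      if (g$levels != "*") {
        ok <- ok & levels_matrix[, g$markers] == g$levels
      }
    } else {
      hits <- rep(0L, n)
      for (t in seq_along(g$markers)) {
        hits <- hits + (levels_matrix[, g$markers[t]] == g$levels[t])
      }
      ok <- ok & if (g$operator == "OR") hits >= 1L else hits == 1L
    }
  }
  ok
}

# Levels fixed by AND tokens (excluding "*"); errors on contradictions.
entry_fixed_levels <- function(groups) {
  fixed <- character()
  for (g in groups) {
    if (g$operator != "AND" || g$levels == "*") next
    mk <- g$markers
    if (mk %in% names(fixed) && fixed[[mk]] != g$levels) {
      stop("contradictory definitions for marker '", mk, "' (",
           fixed[[mk]], " vs ", g$levels, ")", call. = FALSE)
    }
    fixed[[mk]] <- g$levels
  }
  fixed
}

#' Expand a cell-type entry into its concrete signatures
#'
#' A concrete signature assigns one level symbol to every marker of the
#' universe. Markers absent from the entry (or defined `*`) range over all
#' levels their mixture model allows; OR/XOR groups are resolved by
#' enumeration and filtering with the entry predicate.
#'
#' @param groups token groups of the entry.
#' @param marker_universe character vector of all markers a signature spans.
#' @param levels_per_marker named vector mapping each universe marker to 2
#'   or 3 (see [required_levels()]).
#' @param max_free materialisation guard: enumeration is refused when more
#'   than this many markers are unconstrained (the set grows as the product
#'   of level counts); matching never needs materialisation.
#' @return character matrix, one row per concrete signature, columns
#'   `marker_universe`.
#' @examples
#' lpm <- c(A = 2, B = 2)
#' expand_cell_type(parse_signature_string("A+,B-"), c("A", "B"), lpm)
#' expand_cell_type(parse_signature_string("A+|B+|"), c("A", "B"), lpm)
#' @export
expand_cell_type <- function(groups, marker_universe, levels_per_marker,
                             max_free = 12L) {
  fixed <- entry_fixed_levels(groups)
  free <- setdiff(marker_universe, names(fixed))
  if (length(free) > max_free) {
    stop(length(free), " unconstrained markers: expansion too large to ",
         "materialise (raise 'max_free' or match with the predicate)",
         call. = FALSE)
  }
  level_sets <- lapply(marker_universe, function(mk) {
    if (mk %in% names(fixed)) fixed[[mk]]
    else symbol_levels(levels_per_marker[[mk]])
  })
  names(level_sets) <- marker_universe
  grid <- as.matrix(expand.grid(level_sets, KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE))
  if (is.null(dim(grid))) grid <- matrix(grid, ncol = length(marker_universe))
  colnames(grid) <- marker_universe
  grid[entry_satisfies(groups, grid), , drop = FALSE]
}

# Priority key of an entry: number of referenced markers carrying + or m in
# some token, then number of referenced (non-wildcard) markers. Table order
# is the final tie-break, applied at sort time.
entry_priority_key <- function(groups) {
  mk_all <- character()
  mk_pm <- character()
  for (g in groups) {
    keep <- g$levels != "*"
    mk_all <- c(mk_all, g$markers[keep])
    mk_pm <- c(mk_pm, g$markers[keep & g$levels %in% c("+", "m")])
  }
  c(pm = length(unique(mk_pm)), nw = length(unique(mk_all)))
}

#' Build the ordered signature dictionary of a marker table
#'
#' Records are ordered so that lookup resolves ties the way an analyst
#' resolves overlapping gates: entries with more markers at high or medium
#' expression come first, then entries constraining more markers overall,
#' then table order. A cell signature may satisfy several entries; matching
#' returns the first record it satisfies.
#'
#' @param table marker table.
#' @param levels_per_marker named vector of component counts per marker;
#'   defaults to [required_levels()] of the table.
#' @return object of class `signature_dictionary`.
#' @export
build_dictionary <- function(table,
                             levels_per_marker = required_levels(table)) {
  stopifnot(inherits(table, "marker_table"))
  if (!length(table$entries)) stop("empty marker table", call. = FALSE)
  missing <- setdiff(table$marker_universe, names(levels_per_marker))
  if (length(missing)) {
    stop("'levels_per_marker' lacks marker(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keys <- t(vapply(table$entries, entry_priority_key, numeric(2L)))
  ord <- order(-keys[, "pm"], -keys[, "nw"], seq_len(nrow(keys)))
  # emptiness report, only where enumeration is cheap
  for (ct in names(table$entries)) {
    groups <- table$entries[[ct]]
    fixed <- entry_fixed_levels(groups)
    free <- setdiff(table$marker_universe, names(fixed))
    if (prod(vapply(free, function(mk) as.numeric(levels_per_marker[[mk]]),
                    numeric(1L))) <= 6561) {
      ex <- expand_cell_type(groups, table$marker_universe, levels_per_marker)
      if (nrow(ex) == 0L) {
        warning("entry '", ct, "' has an empty expansion and can never match",
                call. = FALSE)
      }
    }
  }
  structure(list(cell_types = names(table$entries)[ord],
                 entries = table$entries[ord],
                 keys = keys[ord, , drop = FALSE],
                 table_order = ord,
                 marker_universe = table$marker_universe,
                 levels_per_marker = levels_per_marker),
            class = "signature_dictionary")
}

#' @export
print.signature_dictionary <- function(x, ...) {
  cat(sprintf("signature_dictionary: %d record(s) over %d marker(s)\n",
              length(x$cell_types), length(x$marker_universe)))
  for (i in seq_along(x$cell_types)) {
    cat(sprintf("  [pm=%d nw=%d] %s\n", x$keys[i, "pm"], x$keys[i, "nw"],
                x$cell_types[i]))
  }
  invisible(x)
}

#' Match cell signatures against a dictionary
#'
#' Each cell receives the cell type of the highest-priority dictionary
#' record its signature satisfies, or `"unclassified"` when none does.
#'
#' @param levels_matrix character matrix of level symbols (cells x markers)
#'   covering the dictionary's marker universe. The `levels` element of
#'   [build_signature_matrix()] output is also accepted.
#' @param dictionary a [build_dictionary()] result.
#' @return character vector of labels, one per cell.
#' @export
match_signatures <- function(levels_matrix, dictionary) {
  stopifnot(inherits(dictionary, "signature_dictionary"))
  if (is.list(levels_matrix) && !is.null(levels_matrix$levels)) {
    levels_matrix <- levels_matrix$levels
  }
  missing <- setdiff(dictionary$marker_universe, colnames(levels_matrix))
  if (length(missing)) {
    stop("signature matrix lacks marker(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(levels_matrix)
  labels <- rep("unclassified", n)
  open <- rep(TRUE, n)
  for (i in seq_along(dictionary$entries)) {
    if (!any(open)) break
    sat <- entry_satisfies(dictionary$entries[[i]], levels_matrix)
    hit <- open & sat
    labels[hit] <- dictionary$cell_types[i]
    open <- open & !sat
  }
  labels
}
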