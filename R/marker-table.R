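# Marker tables: per cell type, a pseudo-gating strategy over markers.
# An entry is a list of token groups; a group is either a single AND token
# (fixing one marker at one level, or leaving it free with "*") or a run of
# two or more tokens combined with OR ("|", at least one must hold) or XOR
# ("^", exactly one must hold).

#' Parse one marker token
#'
#' A token is a marker name followed by a level symbol (`+`, `-`, `m`, `*`,
#' or the word suffixes `hi`, `mid`, `lo`, which normalise to `+`, `m`, `-`)
#' and an optional trailing operator `|` or `^`.
#'
#' @param token token text, e.g. `"CD14+"`, `"CD11bmid"`, `"CD11c+|"`.
#' @return list with elements `marker`, `level`, `op` (`""`, `"|"` or `"^"`).
#' @keywords internal
parse_marker_token <- function(token) {
  tok <- normalize_minus(trimws(token))
  if (!nzchar(tok)) stop("syntax error: empty marker token", call. = FALSE)
  op <- ""
  last <- substring(tok, nchar(tok))
  if (last %in% c("|", "^")) {
    op <- last
    tok <- substring(tok, 1L, nchar(tok) - 1L)
  }
  if (grepl("mid$", tok)) {
    level <- "m"; marker <- sub("mid$", "", tok)
  } else if (grepl("hi$", tok)) {
    level <- "+"; marker <- sub("hi$", "", tok)
  } else if (grepl("lo$", tok)) {
    level <- "-"; marker <- sub("lo$", "", tok)
  } else {
    sym <- substring(tok, nchar(tok))
    if (!sym %in% c("+", "-", "m", "*")) {
      stop(sprintf("syntax error in token '%s': missing level symbol (+, -, m, *)",
                   token), call. = FALSE)
    }
    level <- sym
    marker <- substring(tok, 1L, nchar(tok) - 1L)
  }
  if (!nzchar(marker)) {
    stop(sprintf("syntax error in token '%s': empty marker name", token),
         call. = FALSE)
  }
  list(marker = marker, level = level, op = op)
}

#' Parse a compact signature string into token groups
#'
#' Top-level tokens are comma-separated. A chunk whose tokens are joined by
#' a trailing `|` on each token (e.g. `"CD11b+|CD11c+|"`) is one OR group;
#' likewise `^` forms an XOR group. An operator group must contain at least
#' two tokens, must not mix the two operators, and `*` is not allowed
#' inside it. Chunks without operators are singleton AND groups.
#'
#' @param text signature string, e.g. `"CD14+,CD11b+|CD11c+|"`.
#' @return list of groups; each group is a list with elements
#'   `operator` (`"AND"`, `"OR"` or `"XOR"`), `markers` and `levels`.
#' @examples
#' parse_signature_string("CD14+,CD3-")          # two AND groups
#' parse_signature_string("CD11b+|CD11c+|")      # one OR group
#' parse_signature_string("CD11b+^CD11c+^")      # one XOR group
#' @export
parse_signature_string <- function(text) {
  text <- trimws(text)
  if (is.na(text) || !nzchar(text)) return(list())
  chunks <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
  groups <- list()
  for (chunk in chunks) {
    has_or <- grepl("|", chunk, fixed = TRUE)
    has_xor <- grepl("^", chunk, fixed = TRUE)
    if (has_or && has_xor) {
      stop(sprintf("syntax error near '%s': OR and XOR operators cannot be mixed in one group",
                   chunk), call. = FALSE)
    }
    if (!has_or && !has_xor) {
      tok <- parse_marker_token(chunk)
      groups[[length(groups) + 1L]] <- list(operator = "AND",
                                            markers = tok$marker,
                                            levels = tok$level)
      next
    }
    op <- if (has_or) "|" else "^"
    if (substring(chunk, nchar(chunk)) != op) {
      stop(sprintf("syntax error near '%s': every token of an operator group carries a trailing '%s'",
                   chunk, op), call. = FALSE)
    }
    parts <- strsplit(chunk, op, fixed = TRUE)[[1L]]
    parts <- parts[nzchar(trimws(parts))]
    if (length(parts) < 2L) {
      stop(sprintf("syntax error near '%s': an operator group needs at least two tokens",
                   chunk), call. = FALSE)
    }
    toks <- lapply(parts, parse_marker_token)
    lv <- vapply(toks, `[[`, "", "level")
    if (any(lv == "*")) {
      stop("syntax error: '*' is not allowed inside an OR/XOR group",
           call. = FALSE)
    }
    groups[[length(groups) + 1L]] <- list(
      operator = if (has_or) "OR" else "XOR",
      markers = vapply(toks, `[[`, "", "marker"),
      levels = lv)
  }
  groups
}

#' Serialise token groups back to the compact signature dialect
#'
#' @param groups list of token groups (see [parse_signature_string()]).
#' @return single signature string; parsing it again yields identical groups.
#' @export
serialize_signature <- function(groups) {
  if (!length(groups)) return("")
  pieces <- vapply(groups, function(g) {
    op <- switch(g$operator, AND = "", OR = "|", XOR = "^")
    paste(paste0(g$markers, g$levels, op), collapse = "")
  }, character(1L))
  paste(pieces, collapse = ",")
}

#' Construct a marker table
#'
#' @param entries named list, one element per cell type. Each element is
#'   either a list of token groups (see [parse_signature_string()]) or a
#'   named character vector of levels (convenience for AND-only entries,
#'   e.g. `c(CD3 = "+", CD19 = "-")`). An empty element is an all-wildcard
#'   entry.
#' @param marker_universe optional character vector of markers the table
#'   ranges over; defaults to (and always includes) every referenced marker.
#' @param medium_markers markers known to need a three-component model even
#'   where no entry spells out an `m` level (populated by the training
#'   module from suffixed reference labels).
#' @return object of class `marker_table` with fields `entries`,
#'   `marker_universe` and `medium_markers`.
#' @export
marker_table <- function(entries, marker_universe = NULL,
                         medium_markers = character()) {
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("every marker-table entry needs a cell-type name", call. = FALSE)
  }
  if (anyDuplicated(names(entries))) {
    stop("duplicate cell type: ",
         paste(unique(names(entries)[duplicated(names(entries))]),
               collapse = ", "), call. = FALSE)
  }
  entries <- lapply(entries, function(e) {
    if (is.character(e)) {
      lapply(seq_along(e), function(i) {
        list(operator = "AND", markers = names(e)[i],
             levels = normalize_minus(unname(e[i])))
      })
    } else {
      e
    }
  })
  for (ct in names(entries)) {
    for (g in entries[[ct]]) {
      if (!g$operator %in% c("AND", "OR", "XOR")) {
        stop("invalid operator in entry '", ct, "'", call. = FALSE)
      }
      if (!all(g$levels %in% c("-", "m", "+", "*"))) {
        stop("invalid level symbol in entry '", ct, "'", call. = FALSE)
      }
      if (g$operator != "AND" && (length(g$markers) < 2L ||
                                  any(g$levels == "*"))) {
        stop("OR/XOR groups need >= 2 tokens and no '*' (entry '", ct, "')",
             call. = FALSE)
      }
    }
  }
  referenced <- unique(unlist(lapply(entries, function(e) {
    unlist(lapply(e, `[[`, "markers"))
  })))
  universe <- unique(c(as.character(marker_universe %||% character()),
                       referenced))
  if (!length(universe)) {
    stop("a marker table must reference at least one marker", call. = FALSE)
  }
  structure(list(entries = entries,
                 marker_universe = universe,
                 medium_markers = unique(as.character(medium_markers))),
            class = "marker_table")
}

#' @export
print.marker_table <- function(x, ...) {
  cat(sprintf("marker_table: %d cell type(s) over %d marker(s)\n",
              length(x$entries), length(x$marker_universe)))
  for (ct in names(x$entries)) {
    s <- serialize_signature(x$entries[[ct]])
    cat(sprintf("  %s: %s\n", ct, if (nzchar(s)) s else "(all wildcard)"))
  }
  invisible(x)
}

#' Component counts required per marker
#'
#' A marker needs a three-component mixture (`G = 3`) when any table entry
#' uses the medium level `m` for it, or when the training module registered
#' it from `-`/`mid`/`hi` suffixed reference labels; all other markers use
#' a two-component (`G = 2`) model.
#'
#' @param table marker table.
#' @return named integer vector over the table's marker universe (plus any
#'   registered medium markers), values 2 or 3.
#' @export
required_levels <- function(table) {
  stopifnot(inherits(table, "marker_table"))
  markers <- unique(c(table$marker_universe, table$medium_markers))
  lv <- stats::setNames(rep(2L, length(markers)), markers)
  for (e in table$entries) {
    for (g in e) {
      med <- g$markers[g$levels == "m"]
      if (length(med)) lv[med] <- 3L
    }
  }
  lv[table$medium_markers] <- 3L
  lv
}

#' Read a marker table from CSV
#'
#' Two dialects are supported. The *wide* dialect has one row per cell type
#' (first column) and one column per marker, cells holding `+`, `-`, `m`,
#' `*` or blank (blank means the marker is uninformative for that type,
#' i.e. wildcard); `hi`/`mid`/`lo` spellings are accepted and normalised.
#' The *compact* dialect has columns `cell_type` and `signature`, the latter
#' a token string in the grammar of [parse_signature_string()] (the only
#' dialect that can express OR/XOR conditions).
#'
#' @param path CSV file path.
#' @param dialect `"wide"` or `"compact"`.
#' @return a [marker_table()].
#' @export
read_marker_table <- function(path, dialect = c("wide", "compact")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (nrow(df) < 1L) stop("empty marker table: ", path, call. = FALSE)
  types <- df[[1L]]
  if (anyDuplicated(types)) {
    stop("duplicate cell type: ",
         paste(unique(types[duplicated(types)]), collapse = ", "),
         call. = FALSE)
  }
  if (dialect == "compact") {
    if (!"signature" %in% colnames(df)) {
      stop("compact dialect needs a 'signature' column", call. = FALSE)
    }
    entries <- lapply(df$signature, parse_signature_string)
    names(entries) <- types
    return(marker_table(entries))
  }
  markers <- colnames(df)[-1L]
  if (!length(markers)) {
    stop("wide dialect needs at least one marker column", call. = FALSE)
  }
  entries <- vector("list", length(types))
  names(entries) <- types
  for (i in seq_along(types)) {
    groups <- list()
    for (j in seq_along(markers)) {
      cell <- normalize_minus(trimws(df[i, j + 1L]))
      if (is.na(cell) || !nzchar(cell)) next
      cell <- switch(cell, hi = "+", mid = "m", lo = "-", cell)
      if (!cell %in% c("+", "-", "m", "*")) {
        stop(sprintf("format error at cell type '%s', marker '%s': unknown symbol '%s'",
                     types[i], markers[j], df[i, j + 1L]), call. = FALSE)
      }
      groups[[length(groups) + 1L]] <- list(operator = "AND",
                                            markers = markers[j],
                                            levels = cell)
    }
    entries[[i]] <- groups
  }
  marker_table(entries, marker_universe = markers)
}

#' Write a marker table to CSV
#'
#' @param table marker table.
#' @param path output path.
#' @param dialect `"wide"` (AND-only tables) or `"compact"`.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(table, path, dialect = c("wide", "compact")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "marker_table"))
  if (dialect == "compact") {
    df <- data.frame(cell_type = names(table$entries),
                     signature = vapply(table$entries, serialize_signature,
                                        character(1L)),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = 2L)
    return(invisible(path))
  }
  has_ops <- any(vapply(table$entries, function(e) {
    any(vapply(e, function(g) g$operator != "AND", logical(1L)))
  }, logical(1L)))
  if (has_ops) {
    stop("the wide dialect cannot express OR/XOR groups; use dialect = 'compact'",
         call. = FALSE)
  }
  universe <- table$marker_universe
  m <- matrix("", length(table$entries), length(universe),
              dimnames = list(NULL, universe))
  for (i in seq_along(table$entries)) {
    for (g in table$entries[[i]]) m[i, g$markers] <- g$levels
  }
  df <- data.frame(cell_type = names(table$entries),
                   as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
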