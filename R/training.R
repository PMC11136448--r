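# Marker-table mining from an annotated reference dataset. For every pair
# of cell types a binary classification tree is fitted on the ordinally
# encoded signature symbols (- < m < +); the marker with the largest total
# impurity decrease over the tree's primary splits is the pair's top
# discriminant and is written into each type's entry (modal symbol over the
# type's cells) unless that entry already constrains it. The greedy guard
# keeps entries minimal: a marker only ever enters a table as some pair's
# top discriminant.

#' Detect markers that need a medium expression level from reference labels
#'
#' Medium expression is guided by labelling convention: a base cell type
#' split into `<base>_<marker>-`, `<base>_<marker>mid` and
#' `<base>_<marker>hi` variants (all three must be present) registers the
#' marker for a three-component mixture.
#'
#' @param labels character vector of reference cell-type labels.
#' @param markers marker names of the expression matrix.
#' @return character vector of markers requiring `G = 3`.
#' @examples
#' detect_medium_markers(
#'   c("monocytes_CD11b-", "monocytes_CD11bmid", "monocytes_CD11bhi"),
#'   c("CD11b", "CD3"))
#' @export
detect_medium_markers <- function(labels, markers) {
  labs <- unique(normalize_minus(as.character(labels)))
  out <- character()
  for (mk in markers) {
    esc <- gsub("([][{}()+*^$\\\\.|?-])", "\\\\\\1", mk)
    pat <- paste0("^(.+)_", esc, "(-|mid|hi)$")
    hit <- grepl(pat, labs)
    if (!any(hit)) next
    base <- sub(pat, "\\1", labs[hit])
    suffix <- sub(pat, "\\2", labs[hit])
    for (b in unique(base)) {
      if (all(c("-", "mid", "hi") %in% suffix[base == b])) {
        out <- c(out, mk)
        break
      }
    }
  }
  unique(out)
}

#' Top discriminant marker between two cell types
#'
#' Fits a binary classification tree (rpart, Gini impurity, depth capped at
#' 3, minimum leaf size 5) on the ordinally encoded signature symbols of the
#' two types' cells and scores each marker by the total goodness-of-split of
#' the primary splits it owns. Ties resolve to the first marker in matrix
#' column order; a pair whose signatures are identical on every marker
#' yields a null record (`top_marker = NA`).
#'
#' @param levels_matrix character signature matrix restricted to the cells
#'   of the two types.
#' @param labels two-class label vector aligned with the rows.
#' @return object of class `pairwise_importance`: `importance` (named
#'   numeric over all markers) and `top_marker` (or `NA_character_`).
#' @export
pairwise_top_marker <- function(levels_matrix, labels) {
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L || any(tabulate(labels) == 0L)) {
    stop("exactly two non-empty classes are required", call. = FALSE)
  }
  markers <- colnames(levels_matrix)
  ord <- matrix(match(levels_matrix, .LEVELS3), nrow = nrow(levels_matrix))
  df <- as.data.frame(ord)
  safe <- paste0("V", seq_along(markers))
  colnames(df) <- safe
  df$.y <- labels
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(maxdepth = 3L,
                                                     minsplit = 10L,
                                                     minbucket = 5L,
                                                     cp = 0, maxcompete = 0L,
                                                     maxsurrogate = 0L,
                                                     xval = 0L))
  importance <- stats::setNames(numeric(length(markers)), markers)
  if (!is.null(fit$splits) && nrow(fit$splits) > 0L) {
    frame <- fit$frame
    idx <- 1L
    for (i in seq_len(nrow(frame))) {
      if (as.character(frame$var[i]) == "<leaf>") next
      v <- rownames(fit$splits)[idx]
      mk <- markers[match(v, safe)]
      importance[mk] <- importance[mk] + fit$splits[idx, "improve"]
      idx <- idx + 1L + frame$ncompete[i] + frame$nsurrogate[i]
    }
  }
  top <- if (all(importance <= 0)) NA_character_ else
    markers[which.max(importance)]
  structure(list(importance = importance, top_marker = top),
            class = "pairwise_importance")
}

#' Modal expression symbol of a marker over a cell subset
#'
#' Returns the most frequent symbol of the marker's signature column over
#' the subset; ties resolve towards the symbol of higher expression
#' (`+` over `m` over `-`).
#'
#' @param marker marker name.
#' @param levels_matrix character signature matrix.
#' @param cells row indices of the subset (non-empty).
#' @return single symbol in `{-, m, +}`.
#' @export
set_marker_expression <- function(marker, levels_matrix, cells) {
  if (!length(cells)) stop("empty cell subset", call. = FALSE)
  col <- levels_matrix[cells, marker]
  counts <- c("+" = sum(col == "+"), "m" = sum(col == "m"),
              "-" = sum(col == "-"))
  names(counts)[which.max(counts)]
}

#' Mine a marker table from an annotated reference dataset
#'
#' Builds the signature matrix of the reference (component counts per marker
#' from [detect_medium_markers()], default 2), then iterates over all
#' unordered pairs of cell types in lexicographic (C-locale) name order.
#' For each pair the top discriminant marker is computed with
#' [pairwise_top_marker()] and written into each of the two entries via
#' [set_marker_expression()] — but only into entries that do not yet
#' constrain that marker; an existing symbol is never overwritten. Markers
#' never selected stay wildcard (absent from the entry).
#'
#' @param x expression matrix of the reference dataset.
#' @param labels reference cell-type label per cell.
#' @param variance_mode `"E"` or `"V"` mixture parameterisation.
#' @param use_rss precondition mixture fits by ranked-set tail selection;
#'   defaults to on under `"V"` and off under `"E"`.
#' @param seed integer seed (drives the RSS draws).
#' @param min_cells smallest admissible class size; pairs of very small
#'   classes cannot support the tree's leaf-size floor.
#' @param exclude_labels labels excluded from training (reference datasets
#'   commonly merge rare populations into an unknown bucket).
#' @return mined [marker_table()] with `medium_markers` registered from the
#'   label suffixes.
#' @export
extract_marker_table <- function(x, labels,
                                 variance_mode = c("E", "V"),
                                 use_rss = NULL,
                                 seed = 42L, min_cells = 20L,
                                 exclude_labels = c("unknown",
                                                    "unclassified")) {
  variance_mode <- match.arg(variance_mode)
  use_rss <- use_rss %||% identical(variance_mode, "V")
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) {
    stop("'labels' must have one entry per cell", call. = FALSE)
  }
  keep <- !(labels %in% exclude_labels)
  sub <- x[keep, , drop = FALSE]
  sublab <- labels[keep]
  types <- sort(unique(sublab), method = "radix")
  if (length(types) < 2L) {
    stop("training needs at least two cell types", call. = FALSE)
  }
  counts <- table(sublab)
  small <- names(counts)[counts < min_cells]
  if (length(small)) {
    stop("cell type(s) below the ", min_cells, "-cell floor: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  medium <- detect_medium_markers(sublab, colnames(x))
  lpm <- stats::setNames(ifelse(colnames(x) %in% medium, 3L, 2L),
                         colnames(x))
  sig <- build_signature_matrix(sub, lpm, variance_mode = variance_mode,
                                use_rss = use_rss, seed = seed)
  entries <- stats::setNames(
    replicate(length(types), character(), simplify = FALSE), types)
  cells_of <- lapply(types, function(t) which(sublab == t))
  names(cells_of) <- types
  for (ai in seq_len(length(types) - 1L)) {
    for (bi in (ai + 1L):length(types)) {
      a <- types[ai]
      b <- types[bi]
      rows <- c(cells_of[[a]], cells_of[[b]])
      pim <- pairwise_top_marker(
        sig$levels[rows, , drop = FALSE],
        rep(c("a", "b"), c(length(cells_of[[a]]), length(cells_of[[b]]))))
      if (is.na(pim$top_marker)) {
        warning("cell types '", a, "' and '", b,
                "' are indistinguishable: no discriminating marker",
                call. = FALSE)
        next
      }
      mk <- pim$top_marker
      if (!(mk %in% names(entries[[a]]))) {
        entries[[a]][[mk]] <- set_marker_expression(mk, sig$levels,
                                                    cells_of[[a]])
      }
      if (!(mk %in% names(entries[[b]]))) {
        entries[[b]][[mk]] <- set_marker_expression(mk, sig$levels,
                                                    cells_of[[b]])
      }
    }
  }
  marker_table(entries, medium_markers = medium)
}
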