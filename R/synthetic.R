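# Seeded synthetic cytometry data. Each marker's expression level maps to a
# Gaussian component; a ground-truth marker table defines which levels each
# cell type may take, and cells draw their intensities from the component of
# their (uniformly instantiated) concrete signature. This emulates the data
# model the level-calling procedure assumes — per-marker mixtures of 2-3
# well-separated components — and deliberately omits spillover, doublets,
# debris and acquisition drift.

#' Specify a synthetic dataset generator
#'
#' @param table ground-truth [marker_table()].
#' @param proportions named numeric vector of cell-type fractions (must sum
#'   to 1 and cover exactly the table's cell types).
#' @param component_params data frame with columns `marker`, `level`
#'   (`-`/`m`/`+`), `mean`, `sd`: the Gaussian component of each expression
#'   level, per marker. Level means must increase with the level and sds be
#'   positive.
#' @param n_cells number of cells to draw.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param skew optional named numeric vector of scales `s`; flagged markers
#'   are passed through the monotone convex map `x -> s * (exp(x/s) - 1)`
#'   (identity near 0) to induce positive skew, for exercising the
#'   ranked-set tail selection.
#' @param unknown optional planted population absent from the table: a list
#'   with `n_cells`, `means` (named, one per universe marker), optional
#'   `sd` (default 0.3) and optional `label` (default `"unknown"`). Its
#'   mean must lie at least 8 pooled sds away from every table-defined
#'   level mean on at least one marker.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(table, proportions, component_params, n_cells,
                           seed = 1L, skew = NULL, unknown = NULL) {
  stopifnot(inherits(table, "marker_table"))
  if (is.null(names(proportions)) ||
      !setequal(names(proportions), names(table$entries))) {
    stop("'proportions' must be named by exactly the table's cell types",
         call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("'proportions' must sum to 1", call. = FALSE)
  }
  cp <- as.data.frame(component_params, stringsAsFactors = FALSE)
  need <- c("marker", "level", "mean", "sd")
  if (!all(need %in% colnames(cp))) {
    stop("'component_params' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(cp$sd <= 0)) stop("component sds must be positive", call. = FALSE)
  for (mk in unique(cp$marker)) {
    sub <- cp[cp$marker == mk, ]
    mu <- sub$mean[match(.LEVELS3, sub$level)]
    mu <- mu[!is.na(mu)]
    if (is.unsorted(mu, strictly = TRUE)) {
      stop("level means of marker '", mk,
           "' must be strictly increasing (- < m < +)", call. = FALSE)
    }
  }
  missing <- setdiff(table$marker_universe, unique(cp$marker))
  if (length(missing)) {
    stop("no component parameters for marker(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(table = table, proportions = proportions,
                 component_params = cp, n_cells = as.integer(n_cells),
                 seed = as.integer(seed), skew = skew, unknown = unknown),
            class = "generator_spec")
}

#' Generate a synthetic dataset from a ground-truth marker table
#'
#' Per cell: a type is drawn from the proportions, a concrete signature is
#' drawn uniformly from the type's expansion (so wildcards are instantiated
#' uniformly over their allowed levels), and each marker value is drawn
#' from the Gaussian component of its level symbol. A planted unknown
#' population, if specified, is appended afterwards.
#'
#' @param spec a [generator_spec()].
#' @return list with `matrix` (expression matrix), `labels` (character,
#'   per cell) and `signatures` (the generating symbols; `NA` rows for
#'   planted unknown cells).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  table <- spec$table
  universe <- table$marker_universe
  lpm <- required_levels(table)
  expansions <- lapply(table$entries, expand_cell_type, universe, lpm)
  empty <- names(expansions)[vapply(expansions, nrow, 0L) == 0L]
  if (length(empty)) {
    stop("cell type(s) with an empty expansion: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  n <- spec$n_cells
  types <- names(table$entries)
  ty <- sample(types, n, replace = TRUE, prob = spec$proportions[types])
  sig <- matrix(NA_character_, n, length(universe),
                dimnames = list(NULL, universe))
  for (t in types) {
    idx <- which(ty == t)
    if (!length(idx)) next
    rows <- sample.int(nrow(expansions[[t]]), length(idx), replace = TRUE)
    sig[idx, ] <- expansions[[t]][rows, , drop = FALSE]
  }
  cp <- spec$component_params
  mu_of <- stats::setNames(cp$mean, paste(cp$marker, cp$level))
  sd_of <- stats::setNames(cp$sd, paste(cp$marker, cp$level))
  values <- matrix(NA_real_, n, length(universe))
  for (j in seq_along(universe)) {
    key <- paste(universe[j], sig[, j])
    if (anyNA(mu_of[key])) {
      stop("no component parameters for some level of marker '",
           universe[j], "'", call. = FALSE)
    }
    values[, j] <- stats::rnorm(n, mu_of[key], sd_of[key])
  }
  if (!is.null(spec$skew)) {
    for (mk in names(spec$skew)) {
      j <- match(mk, universe)
      if (is.na(j)) next
      s <- spec$skew[[mk]]
      values[, j] <- s * expm1(values[, j] / s)
    }
  }
  out <- list(matrix = expression_matrix(values, universe),
              labels = ty, signatures = sig)
  if (!is.null(spec$unknown) && (spec$unknown$n_cells %||% 0L) > 0L) {
    out <- plant_unknown_population(out$matrix, out$labels, spec,
                                    signatures = out$signatures)
  }
  out
}

#' Plant a population absent from the marker table
#'
#' Appends cells drawn around means of their own, labelled `"unknown"`
#' (or the label in `spec$unknown$label`), after verifying that the planted
#' component is at least 8 pooled standard deviations away from every
#' table-defined level mean on at least one marker — the geometric
#' precondition for the reject option to isolate it.
#'
#' @param x expression matrix of the table-defined cells.
#' @param labels their labels.
#' @param spec the [generator_spec()] carrying `unknown` and the component
#'   parameters.
#' @param signatures optional generating-signature matrix to extend with
#'   `NA` rows.
#' @return list with the extended `matrix`, `labels`, `signatures`, and
#'   `separation_margin` (the achieved margin, in sd units).
#' @export
plant_unknown_population <- function(x, labels, spec, signatures = NULL) {
  us <- spec$unknown
  if (is.null(us) || (us$n_cells %||% 0L) < 1L) {
    return(list(matrix = x, labels = labels, signatures = signatures,
                separation_margin = NA_real_))
  }
  universe <- colnames(x)
  if (!all(universe %in% names(us$means))) {
    stop("unknown-population means must cover every marker", call. = FALSE)
  }
  u_sd <- us$sd %||% 0.3
  cp <- spec$component_params
  margins <- vapply(universe, function(mk) {
    sub <- cp[cp$marker == mk, ]
    pooled <- max(sub$sd, u_sd)
    min(abs(us$means[[mk]] - sub$mean)) / pooled
  }, numeric(1L))
  if (max(margins) < 8) {
    stop(sprintf(
      "planted population too close to table-defined levels (best margin %.1f sd < 8 sd)",
      max(margins)), call. = FALSE)
  }
  n_u <- as.integer(us$n_cells)
  extra <- vapply(universe,
                  function(mk) stats::rnorm(n_u, us$means[[mk]], u_sd),
                  numeric(n_u))
  if (is.null(dim(extra))) extra <- matrix(extra, nrow = n_u)
  combined <- rbind(unclass(x), extra)
  mat <- expression_matrix(combined, universe,
                           cell_ids = as.character(seq_len(nrow(combined))))
  if (!is.null(signatures)) {
    signatures <- rbind(signatures,
                        matrix(NA_character_, n_u, ncol(signatures)))
  }
  list(matrix = mat,
       labels = c(labels, rep(us$label %||% "unknown", n_u)),
       signatures = signatures,
       separation_margin = max(margins))
}

#' Standard four-type immune-panel generator
#'
#' A compact benchmark design used throughout the package's tests and
#' examples: four populations (CD4 and CD8 T cells, B cells, monocytes)
#' over six markers, negative/positive component means 0 and 1.8 with sd
#' 0.3 (six-sd separation, so level calls are essentially noise-free), and
#' an uninformative wildcard marker (CD56). Optionally plants an
#' NK-cell-like population, bright on CD56 only, that no table entry
#' describes.
#'
#' @param n_cells table-defined cells to draw.
#' @param seed integer seed.
#' @param unknown_cells planted unknown cells (0 disables).
#' @return a [generator_spec()].
#' @export
example_generator_spec <- function(n_cells = 20000L, seed = 1L,
                                   unknown_cells = 0L) {
  table <- marker_table(
    list(Tcell_CD4 = c(CD3 = "+", CD4 = "+", CD8 = "-"),
         Tcell_CD8 = c(CD3 = "+", CD4 = "-", CD8 = "+"),
         Bcell     = c(CD3 = "-", CD19 = "+", CD14 = "-"),
         Monocyte  = c(CD3 = "-", CD14 = "+", CD19 = "-")),
    marker_universe = c("CD3", "CD4", "CD8", "CD19", "CD14", "CD56"))
  markers <- table$marker_universe
  cp <- data.frame(marker = rep(markers, each = 2L),
                   level = rep(c("-", "+"), length(markers)),
                   mean = rep(c(0, 1.8), length(markers)),
                   sd = 0.3, stringsAsFactors = FALSE)
  unknown <- NULL
  if (unknown_cells > 0L) {
    unknown <- list(n_cells = as.integer(unknown_cells),
                    means = c(CD3 = 0, CD4 = 0, CD8 = 0, CD19 = 0,
                              CD14 = 0, CD56 = 4.5),
                    sd = 0.3, label = "unknown")
  }
  generator_spec(table,
                 proportions = c(Tcell_CD4 = 0.35, Tcell_CD8 = 0.15,
                                 Bcell = 0.20, Monocyte = 0.30),
                 component_params = cp, n_cells = n_cells, seed = seed,
                 unknown = unknown)
}

#' Three-level medium-expression generator
#'
#' Companion design for the medium-expression path: one base monocyte type
#' split into CD11b negative/mid/hi variants (component means 0, 1.8, 3.6,
#' sd 0.3) plus a CD3+ T-cell population, with the suffixed label
#' convention the training module recognises.
#'
#' @inheritParams example_generator_spec
#' @return a [generator_spec()].
#' @export
example_medium_spec <- function(n_cells = 20000L, seed = 1L) {
  table <- marker_table(
    list("Tcell" = c(CD3 = "+"),
         "monocytes_CD11b-" = c(CD3 = "-", CD11b = "-"),
         "monocytes_CD11bmid" = c(CD3 = "-", CD11b = "m"),
         "monocytes_CD11bhi" = c(CD3 = "-", CD11b = "+")),
    marker_universe = c("CD3", "CD11b"))
  cp <- data.frame(
    marker = c("CD3", "CD3", "CD11b", "CD11b", "CD11b"),
    level = c("-", "+", "-", "m", "+"),
    mean = c(0, 1.8, 0, 1.8, 3.6),
    sd = 0.3, stringsAsFactors = FALSE)
  generator_spec(table,
                 proportions = c("Tcell" = 0.25, "monocytes_CD11b-" = 0.25,
                                 "monocytes_CD11bmid" = 0.25,
                                 "monocytes_CD11bhi" = 0.25),
                 component_params = cp, n_cells = n_cells, seed = seed)
}
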