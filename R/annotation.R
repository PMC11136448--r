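# Annotation pipeline: optional simple random sampling, per-marker mixture
# signatures, dictionary matching, optional MNN confident-set construction
# (the reject option), and k-NN refinement of everything not directly and
# confidently annotated. Distances are Euclidean over the raw transformed
# intensities of the table's markers, not over the symbols.

#' Simple random sample of cell indices
#'
#' Uniform sampling without replacement of `max(ceiling(fraction * n),
#' min(n, 500))` cells; the 500-cell floor protects tiny inputs from
#' undersized mixture fits. `fraction = 1` returns all indices.
#'
#' @param n_cells number of cells.
#' @param fraction sampling fraction in (0, 1].
#' @param seed optional integer seed.
#' @return sorted integer vector of sampled indices.
#' @export
simple_random_sample <- function(n_cells, fraction, seed = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  if (fraction == 1) return(seq_len(n_cells))
  if (!is.null(seed)) set.seed(seed)
  size <- min(n_cells, max(ceiling(fraction * n_cells), min(n_cells, 500L)))
  sort(sample.int(n_cells, size))
}

# squared Euclidean cross-distances, rows of a vs rows of b
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) -
    2 * tcrossprod(a, b) +
    outer(rep(1, nrow(a)), rowSums(b^2))
  pmax(d2, 0)
}

#' Mutual nearest neighbours between two point sets
#'
#' Each cell's `k`-neighbourhood is computed in the pooled set of both
#' inputs (Euclidean metric, the cell itself excluded); a pair `(a, u)` is
#' mutual iff `u` lies in `a`'s neighbourhood *and* `a` in `u`'s. Cells of
#' a tight, isolated cluster fill their neighbourhoods with each other and
#' therefore form no cross-set pairs — the property the reject option uses
#' to tell genuinely novel populations from matching errors.
#'
#' @param x_ann numeric matrix of annotated cells (rows are points).
#' @param x_unc numeric matrix of unclassified cells.
#' @param k neighbourhood size, >= 1 (clamped to the pooled size).
#' @return two-column integer matrix (`annotated`, `unclassified`) of row
#'   indices into the two inputs; zero rows when either set is empty.
#' @export
mutual_nearest_neighbors <- function(x_ann, x_unc, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be >= 1", call. = FALSE)
  x_ann <- as.matrix(x_ann)
  x_unc <- as.matrix(x_unc)
  empty <- matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("annotated", "unclassified")))
  na <- nrow(x_ann)
  nu <- nrow(x_unc)
  if (na == 0L || nu == 0L) return(empty)
  pooled <- rbind(x_ann, x_unc)
  d2 <- cross_dist2(pooled, pooled)
  diag(d2) <- Inf
  kk <- min(k, nrow(pooled) - 1L)
  in_nbhd <- matrix(FALSE, nrow(pooled), nrow(pooled))
  for (i in seq_len(nrow(pooled))) {
    in_nbhd[i, order(d2[i, ])[seq_len(kk)]] <- TRUE
  }
  cross <- in_nbhd[seq_len(na), na + seq_len(nu), drop = FALSE] &
    t(in_nbhd[na + seq_len(nu), seq_len(na), drop = FALSE])
  pairs <- which(cross, arr.ind = TRUE)
  dimnames(pairs) <- list(NULL, c("annotated", "unclassified"))
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

#' Confident annotated and unknown sets from MNN pairs
#'
#' Annotated cells with more than half of their `k` possible MNN pairs
#' landing in the unclassified set are ambiguous (likely matching errors)
#' and are moved to the refinement queries; the rest form the confident
#' annotated set. Unclassified cells with *no* MNN among the annotated
#' cells form the confident unknown set — genuinely novel populations
#' cluster together, away from every annotated type.
#'
#' @param n_annotated,n_unclassified sizes of the two sets the pairs index.
#' @param pairs matrix from [mutual_nearest_neighbors()].
#' @param k the neighbourhood size the pairs were computed with.
#' @return list of index vectors `a_conf`, `u_conf` and `ambiguous`
#'   (positions within the annotated resp. unclassified sets).
#' @export
build_confident_sets <- function(n_annotated, n_unclassified, pairs, k) {
  cnt_a <- tabulate(pairs[, 1L], nbins = n_annotated)
  ambiguous <- which(cnt_a / k > 0.5)
  cnt_u <- tabulate(pairs[, 2L], nbins = n_unclassified)
  list(a_conf = setdiff(seq_len(n_annotated), ambiguous),
       u_conf = which(cnt_u == 0L),
       ambiguous = ambiguous)
}

#' k-NN label refinement
#'
#' Majority vote among the `k` nearest training points (Euclidean); vote
#' ties resolve to the label of the single nearest neighbour. `k` larger
#' than the training set is clamped with a warning.
#'
#' @param x_train numeric matrix of training points.
#' @param train_labels label per training point.
#' @param x_query numeric matrix of query points.
#' @param k neighbourhood size.
#' @return character vector of predicted labels, one per query.
#' @export
knn_refine <- function(x_train, train_labels, x_query, k = 10L) {
  x_train <- as.matrix(x_train)
  x_query <- as.matrix(x_query)
  train_labels <- as.character(train_labels)
  if (nrow(x_train) < 1L) stop("empty training set", call. = FALSE)
  if (length(train_labels) != nrow(x_train)) {
    stop("one label per training point is required", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be >= 1", call. = FALSE)
  if (k > nrow(x_train)) {
    warning("k = ", k, " exceeds the training size; clamped to ",
            nrow(x_train))
    k <- nrow(x_train)
  }
  nq <- nrow(x_query)
  out <- character(nq)
  if (nq == 0L) return(out)
  chunk <- 1024L
  for (start in seq(1L, nq, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nq)
    d2 <- cross_dist2(x_query[idx, , drop = FALSE], x_train)
    for (r in seq_along(idx)) {
      nn <- order(d2[r, ])[seq_len(k)]
      votes <- train_labels[nn]
      tab <- table(votes)
      winners <- names(tab)[tab == max(tab)]
      out[idx[r]] <- if (length(winners) == 1L) winners else votes[1L]
    }
  }
  out
}

#' Annotate a dataset from a marker table
#'
#' Runs the full annotation pipeline: simple random sampling of the cells
#' to classify directly; per-marker mixture signatures of the sampled cells
#' (component counts from [required_levels()]); dictionary matching; then
#' refinement. Without the reject option, the directly annotated cells
#' train a k-NN classifier that labels everything else. With
#' `reject_option = TRUE`, MNN pairs between annotated and unclassified
#' sampled cells first split them into confident annotated cells, confident
#' unknowns (labelled `"unknown"`) and ambiguous cells; the k-NN training
#' set is the union of the confident sets, and ambiguous, unconfident and
#' unsampled cells are re-labelled by the vote — so novel populations can
#' keep the `"unknown"` label instead of being forced into a table type.
#'
#' @param x expression matrix (already transformed intensities).
#' @param table marker table; its markers must all be matrix columns.
#' @param variance_mode `"E"` or `"V"` mixture parameterisation.
#' @param use_rss ranked-set tail preconditioning of the mixture fits;
#'   defaults to on under `"V"`, off under `"E"`.
#' @param srs_fraction fraction of cells classified directly (default 0.1;
#'   a 500-cell floor applies to tiny datasets).
#' @param reject_option enable MNN confident-set construction.
#' @param k neighbourhood size for both MNN and k-NN (default 10).
#' @param seed integer seed driving the sampling and the RSS substreams.
#' @return data frame with one row per cell: `cell_id`, `label`,
#'   `provenance` (`direct`, `refined`, `unknown` or
#'   `unsampled->refined`), in the input row order. The annotation state
#'   partition (index sets A, U, A', U') is attached as attribute `state`.
#' @export
annotate_cells <- function(x, table,
                           variance_mode = c("E", "V"),
                           use_rss = NULL,
                           srs_fraction = 0.1,
                           reject_option = FALSE,
                           k = 10L,
                           seed = 42L) {
  variance_mode <- match.arg(variance_mode)
  use_rss <- use_rss %||% identical(variance_mode, "V")
  stopifnot(inherits(table, "marker_table"))
  missing <- setdiff(table$marker_universe, colnames(x))
  if (length(missing)) {
    stop("marker(s) in the table but not in the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(x)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be >= 1", call. = FALSE)
  sampled <- simple_random_sample(n, srs_fraction, seed = seed)
  unsampled <- setdiff(seq_len(n), sampled)
  lpm <- required_levels(table)
  lpm <- lpm[names(lpm) %in% table$marker_universe]
  xs <- x[sampled, table$marker_universe, drop = FALSE]
  sig <- build_signature_matrix(xs, lpm, variance_mode = variance_mode,
                                use_rss = use_rss, seed = seed + 1L)
  dict <- build_dictionary(table, lpm)
  matched <- match_signatures(sig$levels, dict)
  a_rel <- which(matched != "unclassified")
  u_rel <- which(matched == "unclassified")
  coords <- x[, table$marker_universe, drop = FALSE]
  labels <- rep(NA_character_, n)
  provenance <- rep(NA_character_, n)
  labels[sampled] <- matched
  provenance[sampled[a_rel]] <- "direct"
  provenance[sampled[u_rel]] <- "refined"
  provenance[unsampled] <- "unsampled->refined"
  state <- list(A = sampled[a_rel], U = c(sampled[u_rel], unsampled),
                A_conf = sampled[a_rel], U_conf = integer())
  if (!reject_option) {
    train_idx <- sampled[a_rel]
    train_lab <- matched[a_rel]
    query_idx <- c(sampled[u_rel], unsampled)
  } else {
    pairs <- mutual_nearest_neighbors(coords[sampled[a_rel], , drop = FALSE],
                                      coords[sampled[u_rel], , drop = FALSE],
                                      k)
    cs <- build_confident_sets(length(a_rel), length(u_rel), pairs, k)
    a_conf <- sampled[a_rel][cs$a_conf]
    u_conf <- sampled[u_rel][cs$u_conf]
    ambiguous <- sampled[a_rel][cs$ambiguous]
    labels[u_conf] <- "unknown"
    provenance[u_conf] <- "unknown"
    provenance[ambiguous] <- "refined"
    state$A_conf <- a_conf
    state$U_conf <- u_conf
    train_idx <- c(a_conf, u_conf)
    train_lab <- c(labels[a_conf], rep("unknown", length(u_conf)))
    query_idx <- c(setdiff(sampled[u_rel], u_conf), ambiguous, unsampled)
  }
  if (length(query_idx)) {
    if (!length(train_idx)) {
      warning("no directly annotated cells: refinement impossible; ",
              "unmatched cells stay 'unclassified'")
      labels[query_idx] <- "unclassified"
    } else {
      labels[query_idx] <- knn_refine(coords[train_idx, , drop = FALSE],
                                      train_lab,
                                      coords[query_idx, , drop = FALSE],
                                      k)
    }
  }
  out <- data.frame(cell_id = rownames(x), label = labels,
                    provenance = provenance, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "state") <- state
  attr(out, "fits") <- sig$fits
  out
}
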