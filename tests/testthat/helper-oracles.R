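# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written in the most literal way possible (scalar
# loops, no shared code with the package internals beyond the public data
# structures).

# does a single concrete signature (named character vector) satisfy an
# entry's token groups?
bf_satisfies <- function(groups, sig_row) {
  for (g in groups) {
    holds <- mapply(function(mk, lv) {
      if (lv == "*") TRUE else identical(unname(sig_row[[mk]]), lv)
    }, g$markers, g$levels)
    ok <- switch(g$operator,
                 AND = all(holds),
                 OR = sum(holds) >= 1L,
                 XOR = sum(holds) == 1L)
    if (!ok) return(FALSE)
  }
  TRUE
}

# all concrete signatures over the universe, as a character matrix
bf_signature_grid <- function(marker_universe, levels_per_marker) {
  sets <- lapply(marker_universe, function(mk) {
    if (levels_per_marker[[mk]] >= 3) c("-", "m", "+") else c("-", "+")
  })
  names(sets) <- marker_universe
  grid <- as.matrix(expand.grid(sets, KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE))
  colnames(grid) <- marker_universe
  grid
}

# enumerate an entry's expansion by filtering the full grid
bf_expand <- function(groups, marker_universe, levels_per_marker) {
  grid <- bf_signature_grid(marker_universe, levels_per_marker)
  keep <- vapply(seq_len(nrow(grid)),
                 function(i) bf_satisfies(groups, as.list(grid[i, ])),
                 logical(1L))
  grid[keep, , drop = FALSE]
}

# priority evaluator: the label a signature should get from a table
bf_lookup <- function(sig_row, table) {
  best <- "unclassified"
  best_key <- c(-Inf, -Inf, Inf)
  for (i in seq_along(table$entries)) {
    groups <- table$entries[[i]]
    if (!bf_satisfies(groups, sig_row)) next
    mks <- character()
    pm <- character()
    for (g in groups) {
      for (t in seq_along(g$markers)) {
        if (g$levels[t] == "*") next
        mks <- c(mks, g$markers[t])
        if (g$levels[t] %in% c("+", "m")) pm <- c(pm, g$markers[t])
      }
    }
    key <- c(length(unique(pm)), length(unique(mks)), i)
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2]) ||
        (key[1] == best_key[1] && key[2] == best_key[2] &&
         key[3] < best_key[3])) {
      best <- names(table$entries)[i]
      best_key <- key
    }
  }
  best
}

# random marker table over a small universe, with valid OR/XOR groups
bf_random_table <- function(seed) {
  set.seed(seed)
  universe <- paste0("M", seq_len(sample(2:4, 1L)))
  lpm <- stats::setNames(sample(2:3, length(universe), replace = TRUE),
                         universe)
  n_types <- sample(2:4, 1L)
  entries <- list()
  for (t in seq_len(n_types)) {
    groups <- list()
    pool <- sample(universe)
    if (length(pool) >= 2 && stats::runif(1) < 0.4) {
      mks <- pool[1:2]
      pool <- pool[-(1:2)]
      lv <- vapply(mks, function(mk) {
        sample(if (lpm[[mk]] >= 3) c("-", "m", "+") else c("-", "+"), 1L)
      }, character(1L))
      groups[[length(groups) + 1L]] <-
        list(operator = sample(c("OR", "XOR"), 1L), markers = mks,
             levels = unname(lv))
    }
    for (mk in pool) {
      if (stats::runif(1) < 0.6) {
        lv <- sample(c(if (lpm[[mk]] >= 3) c("-", "m", "+") else c("-", "+"),
                       "*"), 1L)
        groups[[length(groups) + 1L]] <-
          list(operator = "AND", markers = mk, levels = lv)
      }
    }
    entries[[paste0("T", t)]] <- groups
  }
  list(table = marker_table(entries, marker_universe = universe), lpm = lpm)
}

# all-pairs mutual nearest neighbours (neighbourhoods in the pooled set),
# literal double loop
bf_mnn <- function(x_ann, x_unc, k) {
  na <- nrow(x_ann)
  nu <- nrow(x_unc)
  pooled <- rbind(x_ann, x_unc)
  n <- nrow(pooled)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) d[i, j] <- sqrt(sum((pooled[i, ] - pooled[j, ])^2))
  }
  nbhd <- function(i) {
    others <- setdiff(seq_len(n), i)
    others[order(d[i, others])][seq_len(min(k, n - 1L))]
  }
  pairs <- NULL
  for (i in seq_len(na)) {
    for (j in seq_len(nu)) {
      if ((na + j) %in% nbhd(i) && i %in% nbhd(na + j)) {
        pairs <- rbind(pairs, c(i, j))
      }
    }
  }
  if (is.null(pairs)) {
    pairs <- matrix(integer(), ncol = 2L)
  }
  colnames(pairs) <- c("annotated", "unclassified")
  pairs
}

# exhaustive single-split Gini importance over ordinal-encoded symbols
bf_gini_importance <- function(levels_matrix, labels) {
  y <- as.integer(factor(labels))
  n <- length(y)
  gini <- function(idx) {
    if (!length(idx)) return(0)
    p <- tabulate(y[idx], 2L) / length(idx)
    1 - sum(p^2)
  }
  root <- gini(seq_len(n))
  out <- stats::setNames(numeric(ncol(levels_matrix)),
                         colnames(levels_matrix))
  for (mk in colnames(levels_matrix)) {
    x <- match(levels_matrix[, mk], c("-", "m", "+"))
    for (thr in c(1.5, 2.5)) {
      left <- which(x <= thr)
      right <- which(x > thr)
      if (!length(left) || !length(right)) next
      dec <- root - length(left) / n * gini(left) -
        length(right) / n * gini(right)
      out[mk] <- max(out[mk], dec)
    }
  }
  out
}
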