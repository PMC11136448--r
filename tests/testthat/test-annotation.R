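test_that("simple random sampling honours size contracts", {
  idx <- simple_random_sample(1000, 0.1, seed = 1)
  expect_length(idx, 500L) # the 500-cell floor engages over 100
  expect_false(anyDuplicated(idx) > 0)

  idx2 <- simple_random_sample(10000, 0.1, seed = 1)
  expect_length(idx2, 1000L)

  expect_identical(simple_random_sample(42, 1.0), seq_len(42L))
  expect_length(simple_random_sample(2000, 0.05, seed = 2), 500L)
  expect_error(simple_random_sample(10, 0), "\\(0, 1\\]")
  expect_error(simple_random_sample(10, 1.2), "\\(0, 1\\]")
})

test_that("mutual nearest neighbours match brute force on random sets", {
  # 1-D worked case: only the mutual pair survives
  pairs <- mutual_nearest_neighbors(matrix(c(0, 1)), matrix(0.4), k = 1)
  expect_equal(nrow(pairs), 1L)
  expect_equal(unname(pairs[1, ]), c(1L, 1L))

  expect_equal(nrow(mutual_nearest_neighbors(matrix(numeric(), 0, 2),
                                             matrix(rnorm(10), 5), 3)), 0L)

  for (seed in 1:5) {
    set.seed(seed)
    na <- sample(5:200, 1)
    nu <- sample(5:200, 1)
    k <- sample(1:10, 1)
    xa <- matrix(rnorm(na * 3), na)
    xu <- matrix(rnorm(nu * 3), nu)
    got <- mutual_nearest_neighbors(xa, xu, k)
    want <- bf_mnn(xa, xu, k)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE],
                 ignore_attr = TRUE, info = paste("seed", seed))
    # monotone in k: doubling k never removes pairs
    bigger <- mutual_nearest_neighbors(xa, xu, 2 * k)
    keys <- function(p) paste(p[, 1], p[, 2])
    expect_true(all(keys(got) %in% keys(bigger)))
    # symmetric: swapping the sets flips pair orientation only
    flipped <- mutual_nearest_neighbors(xu, xa, k)
    expect_setequal(keys(got), paste(flipped[, 2], flipped[, 1]))
  }
})

test_that("confident sets follow the MNN proportion rules", {
  # annotated cell 1 has 6/10 pairs -> ambiguous; cell 2 none -> confident
  pairs <- cbind(annotated = rep(1L, 6), unclassified = 1:6)
  cs <- build_confident_sets(2, 8, pairs, k = 10)
  expect_identical(cs$ambiguous, 1L)
  expect_identical(cs$a_conf, 2L)
  # unclassified cells 7, 8 have no pairs -> confident unknowns
  expect_identical(cs$u_conf, c(7L, 8L))

  # exactly half of k is not ambiguous (strict majority rule)
  pairs5 <- cbind(annotated = rep(1L, 5), unclassified = 1:5)
  expect_identical(build_confident_sets(1, 5, pairs5, k = 10)$a_conf, 1L)
})

test_that("a far-away planted cluster is entirely confidently unknown", {
  set.seed(91)
  xa <- matrix(rnorm(400, 0, 0.5), 200)
  xu <- matrix(rnorm(60, 50, 0.5), 30) # min cross distance >> within-A
  pairs <- mutual_nearest_neighbors(xa, xu, k = 10)
  cs <- build_confident_sets(200, 30, pairs, k = 10)
  expect_identical(cs$u_conf, 1:30)
})

test_that("k-NN refinement votes with deterministic tie-breaks", {
  expect_identical(knn_refine(matrix(0), "L", matrix(c(-5, 9)), k = 1),
                   c("L", "L"))
  # query equidistant between two size-1 classes: nearest-neighbour order
  # breaks the 1-1 vote
  tr <- matrix(c(-1, 1))
  expect_identical(knn_refine(tr, c("a", "b"), matrix(0), k = 2), "a")
  expect_warning(out <- knn_refine(matrix(c(0, 1)), c("a", "b"),
                                   matrix(0.1), k = 5),
                 "clamped")
  expect_identical(out, "a")

  set.seed(92)
  train <- rbind(matrix(rnorm(200, -5, 0.3), 100),
                 matrix(rnorm(200, 5, 0.3), 100))
  lab <- rep(c("lo", "hi"), each = 100)
  query <- rbind(matrix(rnorm(200, -5, 0.3), 100),
                 matrix(rnorm(200, 5, 0.3), 100))
  got <- knn_refine(train, lab, query, k = 10)
  expect_identical(got, rep(c("lo", "hi"), each = 100))
})

test_that("annotation partitions every cell exactly once", {
  ds <- generate_dataset(example_generator_spec(n_cells = 4000, seed = 8))
  ann <- annotate_cells(ds$matrix, example_generator_spec()$table,
                        srs_fraction = 0.1, seed = 2)
  expect_equal(nrow(ann), 4000L)
  expect_false(anyNA(ann$label))
  expect_false(anyNA(ann$provenance))
  expect_true(all(ann$provenance %in%
                    c("direct", "refined", "unknown", "unsampled->refined")))
  counts <- table(ann$provenance)
  expect_equal(sum(counts), 4000L)
  state <- attr(ann, "state")
  expect_length(intersect(state$A, state$U), 0L)
  expect_true(all(state$A_conf %in% state$A))
  expect_true(all(state$U_conf %in% state$U))

  # determinism
  ann2 <- annotate_cells(ds$matrix, example_generator_spec()$table,
                         srs_fraction = 0.1, seed = 2)
  expect_identical(ann$label, ann2$label)
})

test_that("full sampling with total matching reduces to dictionary matching", {
  set.seed(93)
  n <- 1200
  comp <- rbinom(n, 1, 0.5)
  x <- expression_matrix(cbind(A = rnorm(n, comp * 4, 0.4)), "A")
  tab <- marker_table(list(neg = c(A = "-"), pos = c(A = "+")))
  ann <- annotate_cells(x, tab, srs_fraction = 1.0, reject_option = FALSE,
                        seed = 1)
  sig <- build_signature_matrix(x[, "A", drop = FALSE], c(A = 2L))
  direct <- match_signatures(sig$levels, build_dictionary(tab))
  expect_identical(ann$label, direct)
  expect_true(all(ann$provenance == "direct"))
})

test_that("annotation validates the marker-table contract", {
  x <- expression_matrix(cbind(A = rnorm(600)), "A")
  tab <- marker_table(list(T1 = c(A = "+", MISSING = "-")))
  expect_error(annotate_cells(x, tab), "MISSING")
})

test_that("reject option leaves a planted novel population unknown", {
  spec <- example_generator_spec(n_cells = 6000, seed = 9,
                                 unknown_cells = 300)
  ds <- generate_dataset(spec)
  ann <- annotate_cells(ds$matrix, spec$table, srs_fraction = 0.1,
                        reject_option = TRUE, seed = 4)
  planted <- ds$labels == "unknown"
  expect_gt(mean(ann$label[planted] == "unknown"), 0.8)
  expect_lt(mean(ann$label[!planted] == "unknown"), 0.02)
})
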