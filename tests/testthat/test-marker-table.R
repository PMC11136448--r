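test_that("signature strings parse into the expected token groups", {
  g <- parse_signature_string("CD14+,CD3-")
  expect_length(g, 2L)
  expect_identical(vapply(g, `[[`, "", "operator"), c("AND", "AND"))
  expect_identical(g[[1]]$markers, "CD14")
  expect_identical(g[[2]]$levels, "-")

  g_or <- parse_signature_string("CD11b+|CD11c+|")
  expect_length(g_or, 1L)
  expect_identical(g_or[[1]]$operator, "OR")
  expect_identical(g_or[[1]]$markers, c("CD11b", "CD11c"))

  g_xor <- parse_signature_string("CD11b+^CD11c+^")
  expect_identical(g_xor[[1]]$operator, "XOR")

  # suffix spellings normalise to symbols; medium parses before a
  # trailing-m marker name would
  g_sfx <- parse_signature_string("CD11bhi,CD11clo,CD33mid,CD20m")
  expect_identical(vapply(g_sfx, `[[`, "", "levels"), c("+", "-", "m", "m"))
  expect_identical(vapply(g_sfx, `[[`, "", "markers"),
                   c("CD11b", "CD11c", "CD33", "CD20"))
})

test_that("malformed signature strings raise syntax errors", {
  expect_error(parse_signature_string("CD14"), "missing level")
  expect_error(parse_signature_string("+"), "empty marker")
  expect_error(parse_signature_string("A+|B+^"), "mixed")
  expect_error(parse_signature_string("A+|B+"), "trailing")
  expect_error(parse_signature_string("A+|"), "at least two tokens")
  expect_error(parse_signature_string("A+|B*|"), "not allowed inside")
})

test_that("serialisation is idempotent after one parse", {
  for (s in c("CD14+,CD3-", "CD11b+|CD11c+|,CD3-", "A+^B+^",
              "CD19*,CD33m")) {
    once <- serialize_signature(parse_signature_string(s))
    expect_identical(serialize_signature(parse_signature_string(once)), once)
  }
})

test_that("entry expansion matches brute-force enumeration", {
  lpm <- c(A = 2L, B = 2L)
  uni <- c("A", "B")

  ex <- expand_cell_type(parse_signature_string("A+,B-"), uni, lpm)
  expect_equal(nrow(ex), 1L)
  expect_identical(unname(ex[1, ]), c("+", "-"))

  ex <- expand_cell_type(parse_signature_string("A*"), "A", c(A = 2L))
  expect_equal(nrow(ex), 2L)

  ex_or <- expand_cell_type(parse_signature_string("A+|B+|"), uni, lpm)
  expect_equal(nrow(ex_or), 3L)
  expect_false(any(ex_or[, "A"] == "-" & ex_or[, "B"] == "-"))

  ex_xor <- expand_cell_type(parse_signature_string("A+^B+^"), uni, lpm)
  expect_equal(nrow(ex_xor), 2L)
  expect_true(all(rowSums(ex_xor == "+") == 1L))

  # cross-check every case against the literal enumerator
  for (s in c("A+,B-", "A+|B+|", "A+^B+^", "A*", "B-")) {
    groups <- parse_signature_string(s)
    got <- expand_cell_type(groups, uni, lpm)
    want <- bf_expand(groups, uni, lpm)
    expect_identical(got[order(apply(got, 1, paste, collapse = "")), ,
                         drop = FALSE],
                     want[order(apply(want, 1, paste, collapse = "")), ,
                          drop = FALSE],
                     info = s)
  }
})

test_that("fully wildcard expansion has product cardinality", {
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(1:4, 1)
    uni <- paste0("M", seq_len(k))
    lpm <- stats::setNames(sample(2:3, k, replace = TRUE), uni)
    ex <- expand_cell_type(list(), uni, lpm)
    expect_equal(nrow(ex), prod(lpm))
    expect_equal(nrow(ex), nrow(bf_expand(list(), uni, lpm)))
  }
})

test_that("expansion of every concrete signature re-satisfies its entry", {
  for (seed in 1:10) {
    rt <- bf_random_table(seed)
    for (ct in names(rt$table$entries)) {
      groups <- rt$table$entries[[ct]]
      ex <- expand_cell_type(groups, rt$table$marker_universe, rt$lpm)
      for (i in seq_len(nrow(ex))) {
        expect_true(bf_satisfies(groups, as.list(ex[i, ])))
      }
    }
  }
})

test_that("contradictory AND tokens are a specification error", {
  groups <- parse_signature_string("A+,A-")
  expect_error(expand_cell_type(groups, "A", c(A = 2L)), "contradictory")
})

test_that("required component counts follow medium-level usage", {
  tab <- marker_table(list(T1 = c(A = "+", B = "-"),
                           T2 = c(A = "*", C = "m")))
  lv <- required_levels(tab)
  expect_identical(lv[["A"]], 2L)
  expect_identical(lv[["B"]], 2L)
  expect_identical(lv[["C"]], 3L)

  tab2 <- marker_table(list(T1 = c(CD11b = "m"), T2 = c(CD11b = "-")))
  expect_identical(required_levels(tab2)[["CD11b"]], 3L)

  tab3 <- marker_table(list(T1 = c(A = "+"), T2 = c(A = "-")),
                       medium_markers = "B")
  expect_identical(required_levels(tab3)[["B"]], 3L)
})

test_that("dictionary priority prefers specific, high-expressing entries", {
  lpm <- c(A = 2L, B = 2L)
  tab <- marker_table(list(T1 = c(A = "+"), T2 = c(A = "+", B = "-")),
                      marker_universe = c("A", "B"))
  dict <- build_dictionary(tab, lpm)
  sig <- matrix(c("+", "-"), 1, dimnames = list(NULL, c("A", "B")))
  # both entries match; equal +/m counts, T2 constrains more markers
  expect_identical(match_signatures(sig, dict), "T2")

  tab_tie <- marker_table(list(First = c(A = "+"), Second = c(A = "+")))
  dict_tie <- build_dictionary(tab_tie, c(A = 2L))
  sig_a <- matrix("+", 1, dimnames = list(NULL, "A"))
  expect_identical(match_signatures(sig_a, dict_tie), "First")

  one <- marker_table(list(Only = c(A = "+", B = "-")))
  expect_length(build_dictionary(one, lpm)$entries, 1L)
})

test_that("unmatched signatures stay unclassified", {
  tab <- marker_table(list(T1 = c(A = "+", B = "+")))
  dict <- build_dictionary(tab, c(A = 2L, B = 2L))
  sig <- matrix(c("-", "+"), 1, dimnames = list(NULL, c("A", "B")))
  expect_identical(match_signatures(sig, dict), "unclassified")
})

test_that("dictionary lookup agrees with the brute-force priority evaluator", {
  for (seed in 1:100) {
    rt <- bf_random_table(seed)
    dict <- suppressWarnings(build_dictionary(rt$table, rt$lpm))
    grid <- bf_signature_grid(rt$table$marker_universe, rt$lpm)
    got <- match_signatures(grid, dict)
    want <- vapply(seq_len(nrow(grid)),
                   function(i) bf_lookup(as.list(grid[i, ]), rt$table),
                   character(1L))
    expect_identical(got, want, info = paste("table seed", seed))
  }
})
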