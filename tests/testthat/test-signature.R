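test_that("sample skewness follows the moment definition", {
  expect_equal(compute_skewness(c(-1, 0, 1)), 0)
  # frozen from g1 = m3/m2^1.5 evaluated directly: equals (1-2p)/sqrt(p(1-p))
  # for a Bernoulli(0.25) sample
  expect_equal(compute_skewness(c(0, 0, 0, 10)), 1.154701, tolerance = 1e-6)
  x <- rnorm(100)^3
  expect_equal(compute_skewness(-x), -compute_skewness(x))
  expect_equal(compute_skewness(rep(2, 5)), 0)
  expect_error(compute_skewness(c(1, 2)), "at least 3")
})

test_that("ranked set sampling honours its size and ordering contracts", {
  rss <- ranked_set_sample(rnorm(100), n_cycles = 5, seed = 1)
  expect_length(rss$leftmost, 5L)
  expect_length(rss$rightmost, 5L)
  expect_false(rss$fallback)

  cst <- ranked_set_sample(rep(3.5, 10), n_cycles = 7, seed = 1)
  expect_identical(cst$leftmost, rep(3.5, 7))
  expect_identical(cst$rightmost, rep(3.5, 7))

  expect_warning(small <- ranked_set_sample(c(1, 2, 3), 5), "fewer than 4")
  expect_true(small$fallback)
  expect_identical(small$leftmost, c(1, 2, 3))

  # strata are ordered order statistics: E[min pair] < E[max pair]
  big <- ranked_set_sample(runif(2000), n_cycles = 20000, seed = 2)
  expect_lt(mean(big$leftmost), mean(big$rightmost))
})

test_that("tail selection follows the sign of the skewness", {
  set.seed(3)
  right_skewed <- exp(rnorm(5000))
  sel <- select_tail_sample(right_skewed, n_cycles = 20000, seed = 4)
  expect_gt(mean(sel), mean(right_skewed))

  left_skewed <- -right_skewed
  sel_l <- select_tail_sample(left_skewed, n_cycles = 20000, seed = 4)
  expect_lt(mean(sel_l), mean(left_skewed))

  # symmetric finite sample: skewness 0 selects the leftmost stratum
  sym <- c(-2, -1, 0, 1, 2)
  expect_identical(select_tail_sample(sym, 100, seed = 5),
                   ranked_set_sample(sym, 100, seed = 5)$leftmost)
})

test_that("EM recovers well-separated two-component mixtures", {
  set.seed(11)
  x <- c(rnorm(1000, 0, 0.25), rnorm(1000, 5, 0.25))
  fit_v <- fit_marker_gmm(x, G = 2, variance_mode = "V")
  expect_true(fit_v$converged)
  expect_equal(fit_v$means, c(0, 5), tolerance = 0.1)
  expect_equal(fit_v$weights, c(0.5, 0.5), tolerance = 0.05)
  expect_false(is.unsorted(fit_v$means, strictly = TRUE))
  expect_equal(sum(fit_v$weights), 1, tolerance = 1e-9)

  fit_e <- fit_marker_gmm(x, G = 2, variance_mode = "E")
  expect_equal(fit_e$sds[1], fit_e$sds[2])
  expect_equal(fit_e$sds[1], 0.25, tolerance = 0.05)

  expect_error(fit_marker_gmm(rep(1, 100), 2), "degenerate")
  expect_error(fit_marker_gmm(rnorm(15), 2), "at least 20")
})

test_that("EM agrees with the mclust reference on a shared fixture", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC # Mclust resolves this in the caller frame
  set.seed(21)
  x <- c(rnorm(800, 0, 0.5), rnorm(1200, 4, 0.8))
  ours_v <- fit_marker_gmm(x, G = 2, variance_mode = "V")
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(ours_v$means, sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
  expect_equal(sort(ours_v$sds),
               sort(sqrt(as.numeric(ref$parameters$variance$sigmasq))),
               tolerance = 0.02)
  ours_e <- fit_marker_gmm(x, G = 2, variance_mode = "E")
  ref_e <- mclust::Mclust(x, G = 2, modelNames = "E", verbose = FALSE)
  expect_equal(ours_e$sds[1],
               sqrt(as.numeric(ref_e$parameters$variance$sigmasq))[1],
               tolerance = 0.02)
})

test_that("MAP level assignment respects closed-form decision boundaries", {
  eq <- structure(list(means = c(0, 5), sds = c(1, 1), weights = c(0.5, 0.5),
                       G = 2L, variance_mode = "V", loglik = 0,
                       converged = TRUE, iterations = 1L),
                  class = "gmm_fit")
  # equal weights and sds: the boundary is the midpoint of the means
  expect_identical(assign_expression_levels(c(2.4, 2.6), eq), c("-", "+"))
  expect_identical(assign_expression_levels(2.5, eq), "-") # tie -> lower mean

  # weights (0.9, 0.1): boundary shifts to 2.5 + log(9)/5 = 2.9394
  wt <- eq
  wt$weights <- c(0.9, 0.1)
  expect_identical(assign_expression_levels(c(2.5, 2.9, 3.0), wt),
                   c("-", "-", "+"))

  three <- structure(list(means = c(0, 3, 6), sds = rep(1, 3),
                          weights = rep(1 / 3, 3), G = 3L,
                          variance_mode = "E", loglik = 0, converged = TRUE,
                          iterations = 1L),
                     class = "gmm_fit")
  expect_identical(assign_expression_levels(4.4, three), "m")
  expect_identical(assign_expression_levels(c(-1, 2.9, 7), three),
                   c("-", "m", "+"))
})

test_that("signature matrices recover generating components", {
  set.seed(31)
  n <- 4000
  comp_a <- rbinom(n, 1, 0.5)
  comp_b <- rbinom(n, 1, 0.3)
  x <- expression_matrix(cbind(rnorm(n, comp_a * 3, 0.3),
                               rnorm(n, comp_b * 3, 0.3)),
                         c("A", "B"))
  sig <- build_signature_matrix(x, c(A = 2L, B = 2L))
  expect_identical(colnames(sig$levels), c("A", "B"))
  expect_gt(mean(sig$levels[, "A"] == c("-", "+")[comp_a + 1]), 0.99)
  expect_gt(mean(sig$levels[, "B"] == c("-", "+")[comp_b + 1]), 0.99)

  # G = 3 marker: all three symbols appear
  comp_c <- sample(0:2, n, replace = TRUE)
  x3 <- expression_matrix(cbind(rnorm(n, comp_c * 3, 0.3)), "C")
  sig3 <- build_signature_matrix(x3, c(C = 3L))
  expect_setequal(unique(sig3$levels[, "C"]), c("-", "m", "+"))
  expect_gt(mean(sig3$levels[, "C"] == c("-", "m", "+")[comp_c + 1]), 0.99)

  # markers not requested are skipped
  sig_a <- build_signature_matrix(x, c(A = 2L))
  expect_identical(colnames(sig_a$levels), "A")
})

test_that("RSS preconditioning leaves balanced symmetric mixtures alone", {
  set.seed(41)
  n <- 6000
  comp <- rbinom(n, 1, 0.5)
  x <- expression_matrix(cbind(rnorm(n, comp * 4, 0.4)), "A")
  plain <- build_signature_matrix(x, c(A = 2L), use_rss = FALSE)
  rss <- build_signature_matrix(x, c(A = 2L), use_rss = TRUE, seed = 42)
  expect_gt(mean(plain$levels == rss$levels), 0.98)
})

test_that("signature generation is deterministic given the seed", {
  set.seed(51)
  x <- expression_matrix(cbind(rnorm(2000, rbinom(2000, 1, 0.4) * 3, 0.4)),
                         "A")
  s1 <- build_signature_matrix(x, c(A = 2L), use_rss = TRUE, seed = 9)
  s2 <- build_signature_matrix(x, c(A = 2L), use_rss = TRUE, seed = 9)
  expect_identical(s1$levels, s2$levels)
  expect_identical(s1$fits, s2$fits)
})

test_that("per-marker failures are collected with marker names", {
  x <- expression_matrix(cbind(rnorm(100), rep(1, 100)), c("OK", "FLAT"))
  expect_error(build_signature_matrix(x, c(OK = 2L, FLAT = 2L)),
               "FLAT: degenerate")
  expect_error(build_signature_matrix(x, c(OK = 2L, GONE = 2L)),
               "GONE")
})

test_that("parameter recovery over repeated seeded simulations is tight", {
  # two components separated by 6 sigma; RMSE of recovered means <= 0.1 sigma
  sigma <- 0.5
  errs <- c()
  for (seed in 1:20) {
    set.seed(seed)
    x <- c(rnorm(1000, 0, sigma), rnorm(1000, 6 * sigma, sigma))
    fit <- fit_marker_gmm(x, G = 2, variance_mode = "V")
    errs <- c(errs, (fit$means - c(0, 6 * sigma))^2)
  }
  expect_lt(sqrt(mean(errs)), 0.1 * sigma)
})
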