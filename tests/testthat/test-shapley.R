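toy_background <- function(m, n = 30, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n * m), ncol = m,
         dimnames = list(NULL, paste0("f", seq_len(m))))
}

test_that("an ignored feature gets zero attribution (dummy axiom)", {
  f <- function(X) 4 * X[, 1] - X[, 2]
  bg <- toy_background(3)
  at <- exact_shapley(f, bg, c(f1 = 1, f2 = 2, f3 = 99))
  expect_equal(at$phi[["f3"]], 0)
})

test_that("linear models recover the closed-form attribution", {
  f <- function(X) 3 * X[, 1] - 2 * X[, 2]
  bg <- toy_background(2)
  x <- c(f1 = 1.5, f2 = -0.5)
  at <- exact_shapley(f, bg, x)
  expect_equal(at$phi[["f1"]], 3 * (x[["f1"]] - mean(bg[, 1])))
  expect_equal(at$phi[["f2"]], -2 * (x[["f2"]] - mean(bg[, 2])))
})

test_that("additive efficiency holds to numerical precision", {
  g <- function(X) X[, 1] * X[, 2] + sin(X[, 3]) - X[, 4]^2
  bg <- toy_background(4)
  for (i in 1:5) {
    x <- stats::setNames(stats::rnorm(4), colnames(bg))
    at <- exact_shapley(g, bg, x)
    expect_lt(abs(at$base_value + sum(at$phi) - at$prediction), 1e-9)
    expect_equal(at$base_value, mean(g(bg)))
  }
})

test_that("coalition enumeration equals the full m!-permutation brute-force oracle", {
  g <- function(X) X[, 1] * X[, 2] + sin(X[, 3]) + X[, 4]^2 - X[, 5] * X[, 3]
  for (m in c(5L, 6L)) {
    bg <- toy_background(m, n = 25, seed = m)
    set.seed(m + 100)
    x <- stats::setNames(stats::rnorm(m), colnames(bg))
    gm <- function(X) rowSums(X[, 1:2, drop = FALSE]^2) +
      X[, 3] * X[, m] - X[, 4]
    exact <- exact_shapley(gm, bg, x)
    brute <- brute_force_shapley(gm, bg, x)
    expect_lt(max(abs(exact$phi - brute)), 1e-12)
  }
})

test_that("functionally interchangeable features receive equal attributions (symmetry)", {
  f <- function(X) X[, 1] + X[, 2] + 0.5 * X[, 1] * X[, 2]
  bg <- toy_background(2)
  bg[, 2] <- bg[, 1]                       # identical background marginals
  at <- exact_shapley(f, bg, c(f1 = 2, f2 = 2))
  expect_equal(at$phi[["f1"]], at$phi[["f2"]])
})

test_that("attributions are linear in the model (linearity axiom)", {
  f1 <- function(X) X[, 1]^2 - X[, 2]
  f2 <- function(X) exp(X[, 2] / 2) + X[, 3]
  fs <- function(X) f1(X) + f2(X)
  bg <- toy_background(3)
  x <- c(f1 = 1, f2 = -1, f3 = 0.5)
  expect_equal(exact_shapley(fs, bg, x)$phi,
               exact_shapley(f1, bg, x)$phi + exact_shapley(f2, bg, x)$phi)
})

test_that("sampled attributions converge to exact values and are deterministic per seed", {
  g <- function(X) X[, 1] * X[, 2] + sin(X[, 3]) + X[, 4]^2 - X[, 5] * X[, 6]
  bg <- toy_background(6, n = 25)
  set.seed(3)
  x <- stats::setNames(stats::rnorm(6), colnames(bg))
  exact <- exact_shapley(g, bg, x)
  samp <- sampled_shapley(g, bg, x, n_permutations = 20000, seed = 2)
  expect_true(all(abs(samp$phi - exact$phi) <= 3 * samp$se + 1e-9))
  expect_lt(abs(samp$base_value + sum(samp$phi) - samp$prediction), 1e-9)
  expect_identical(samp, sampled_shapley(g, bg, x, n_permutations = 20000, seed = 2))
})

test_that("standard errors shrink as 1/sqrt(n_permutations)", {
  g <- function(X) X[, 1] * X[, 2] + X[, 3]^2
  bg <- toy_background(3, n = 25)
  x <- c(f1 = 1, f2 = -2, f3 = 0.5)
  ratios <- vapply(1:8, function(s) {
    a <- sampled_shapley(g, bg, x, 2000, seed = s)
    b <- sampled_shapley(g, bg, x, 8000, seed = s + 50)
    mean(a$se / b$se)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2), 0.25)   # 4x permutations -> ~half the SE
})

test_that("exact mode redirects to sampling above the feature limit", {
  bg <- toy_background(16)
  x <- stats::setNames(rep(0, 16), colnames(bg))
  expect_error(exact_shapley(function(X) X[, 1], bg, x),
               "sampled_shapley", class = "ohppfwa_limit_error")
})

test_that("summary ranking orders by mean |phi| with alphabetical tie-break", {
  a1 <- structure(list(base_value = 0, phi = c(b = 1, a = -1, c = 2),
                       prediction = 2), class = "ohppfwa_attribution")
  a2 <- structure(list(base_value = 0, phi = c(b = -1, a = 1, c = 2),
                       prediction = 2), class = "ohppfwa_attribution")
  sd1 <- summary_data(list(a1, a2))
  expect_equal(sd1$ranking$feature, c("c", "a", "b"))   # a and b tie at 1
  expect_equal(sd1$ranking$rank, 1:3)
  zero <- structure(list(base_value = 0, phi = c(b = 0, a = 0), prediction = 0),
                    class = "ohppfwa_attribution")
  expect_equal(summary_data(list(zero))$ranking$feature, c("a", "b"))
  expect_error(summary_data(list()), class = "ohppfwa_data_error")
})

test_that("decision paths telescope from base value to prediction", {
  at <- structure(list(base_value = 10, phi = c(a = 2, b = -1, c = 0.5),
                       prediction = 11.5), class = "ohppfwa_attribution")
  dp <- decision_path(at, c("a", "b", "c"))
  expect_equal(dp$cumulative[1], 10)
  expect_equal(dp$cumulative[4], 11.5)
  expect_equal(diff(dp$cumulative), unname(at$phi[c("a", "b", "c")]))
  rev_dp <- decision_path(at, c("c", "b", "a"))
  expect_equal(rev_dp$cumulative[1], 10)
  expect_equal(rev_dp$cumulative[4], 11.5)
  expect_equal(diff(rev_dp$cumulative), unname(at$phi[c("c", "b", "a")]))
  flat <- structure(list(base_value = 3, phi = c(a = 0, b = 0), prediction = 3),
                    class = "ohppfwa_attribution")
  expect_true(all(decision_path(flat, c("a", "b"))$cumulative == 3))
  expect_error(decision_path(at, c("a", "b")), class = "ohppfwa_data_error")
  expect_error(decision_path(at, c("a", "b", "b")), class = "ohppfwa_data_error")
})
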