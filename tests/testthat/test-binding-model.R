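# Closed-form equilibrium solutions checked against independent bracketed
# root-finding, plus the limiting behaviors of the predicted slope and the
# tandem-tag pool model.

root_oracle_c <- function(a, b, kd) {
  # unique root of (A - C)(B - C) = KD * C in [0, min(A, B)], bracketed in
  # log space so the bisection tolerance is relative, not absolute
  if (a == 0 || b == 0) return(0)
  if (kd == 0) return(min(a, b))
  g <- function(u) {
    cc <- 10^u
    (a - cc) * (b - cc) - kd * cc
  }
  u_hi <- log10(min(a, b))
  10^stats::uniroot(g, c(u_hi - 40, u_hi), tol = 1e-13)$root
}

root_oracle_free <- function(n, a_total, b_tags, kd) {
  # positive root of a + n*b*a/(a+kd) = a_total
  if (a_total == 0) return(0)
  f <- function(a) a + n * b_tags * a / (a + kd) - a_total
  stats::uniroot(f, c(0, a_total), tol = a_total * 1e-13)$root
}

test_that("complemented concentration matches bracketed root-finding over a log grid", {
  grid <- expand.grid(a = 10^seq(-3, 3, length.out = 7),
                      b = 10^seq(-3, 3, length.out = 7),
                      kd = 10^seq(-6, 6, length.out = 7))
  cc <- complemented_concentration(grid$a, grid$b, grid$kd)
  oracle <- mapply(root_oracle_c, grid$a, grid$b, grid$kd)
  expect_lt(max(abs(cc - oracle) / oracle), 1e-9)
  expect_true(all(cc <= pmin(grid$a, grid$b) + 1e-12))
})

test_that("complemented concentration limits and domain errors", {
  expect_equal(complemented_concentration(1, 1, 0), 1)
  expect_equal(complemented_concentration(0, 5, 1), 0)
  expect_equal(complemented_concentration(2, 1, 1), 2 - sqrt(2),
               tolerance = 1e-12)
  expect_error(complemented_concentration(-1, 1, 1), "non-negative")
  expect_error(complemented_concentration(1, 1, -2), "non-negative")
})

test_that("predicted slope reaches its weak- and strong-binding limits", {
  b_range <- c(1e-2, 1e2)
  expect_equal(predicted_slope(1e6 * 1e2, 2, b_range), 2, tolerance = 0.01)
  expect_equal(predicted_slope(1e-6 * 1e-2, 2, b_range), 1, tolerance = 0.01)
  expect_error(predicted_slope(1, 2, c(-1, 1)), "positive")
  expect_error(predicted_slope(1, 2, c(2, 1)), "increasing")
})

test_that("intermediate predicted slope matches a finite-difference derivative", {
  # at the grid midpoint the OLS slope over a symmetric log window agrees
  # with the local derivative of log10 C(log10 B) to within the window's
  # curvature averaging
  kd <- 1 # median of the default grid
  r <- 2
  s <- predicted_slope(kd, r, c(1e-2, 1e2))
  h <- 1e-4
  dlog <- (log10(complemented_concentration(r * 10^h, 10^h, kd)) -
           log10(complemented_concentration(r * 10^-h, 10^-h, kd))) / (2 * h)
  expect_gt(s, 1)
  expect_lt(s, 2)
  expect_equal(s, dlog, tolerance = 0.05)
})

test_that("predicted slope is monotone non-decreasing in kd and confined to [1, 2]", {
  kds <- 10^seq(-4, 6, length.out = 25)
  slopes <- vapply(kds, predicted_slope, numeric(1),
                   expression_ratio = 2, b_range = c(1e-2, 1e2))
  expect_true(all(diff(slopes) >= -1e-9))
  expect_true(all(slopes >= 1 - 1e-3 & slopes <= 2 + 1e-3))
})

test_that("tandem free-fragment solution conserves mass and matches root-finding", {
  expect_equal(tandem_free_fragment(5, 10, 1, 1), 2 + sqrt(14),
               tolerance = 1e-12)
  grid <- expand.grid(n = c(1L, 2L, 5L, 10L),
                      a = 10^seq(-2, 2, length.out = 5),
                      b = 10^seq(-2, 2, length.out = 5),
                      kd = 10^seq(-3, 3, length.out = 5))
  a_free <- mapply(tandem_free_fragment, grid$n, grid$a, grid$b, grid$kd)
  oracle <- mapply(root_oracle_free, grid$n, grid$a, grid$b, grid$kd)
  # uniroot's bracket tolerance limits the oracle's own relative precision
  # when the free pool is many orders below a_total
  expect_lt(max(abs(a_free - oracle) / pmax(oracle, 1e-300)), 1e-6)
  bound <- grid$n * grid$b * a_free / (a_free + grid$kd)
  expect_lt(max(abs(a_free + bound - grid$a) / grid$a), 1e-9)
  expect_true(all(bound <= grid$n * grid$b + 1e-12))
  expect_true(all(bound <= grid$a + 1e-12))
})

test_that("tandem model reduces to the monomeric model at n = 1", {
  a <- c(0.5, 2, 10)
  b <- c(1, 1, 3)
  kd <- c(0.1, 1, 10)
  expect_equal(tandem_free_fragment(1, a, b, kd),
               a - complemented_concentration(a, b, kd), tolerance = 1e-9)
  expect_equal(tandem_free_fragment(1, 0, 5, 1), 0)
  # kd = 0 with pool smaller than sites: everything bound
  expect_equal(tandem_free_fragment(5, 3, 1, 0), 0)
})

test_that("tandem signal saturates at n and matches the occupancy formula", {
  expect_equal(tandem_signal(5, 1e12, 1, 1), 5, tolerance = 1e-6)
  expect_equal(tandem_signal(5, 10, 1, 1), 5 * (2 + sqrt(14)) / (3 + sqrt(14)),
               tolerance = 1e-12)
  expect_equal(tandem_signal(1, 1, 1, 1e12), 0, tolerance = 1e-6)
})

test_that("amplification fold is bounded, monotone and sub-linear for finite pools", {
  expect_equal(amplification_fold(1, 3, 1, 1), 1)
  expect_equal(amplification_fold(5, 1e12, 1, 1), 5, tolerance = 1e-6)
  # strictly below n whenever the FP_1-10 pool is finite
  grid <- expand.grid(a = 10^seq(-1, 3, length.out = 9),
                      kd = 10^seq(-3, 3, length.out = 9))
  folds <- mapply(function(a, kd) amplification_fold(5, a, 1, kd),
                  grid$a, grid$kd)
  expect_true(all(folds < 5))
  expect_true(all(folds >= 1 - 1e-12))
  # monotone non-decreasing in a_total at fixed kd
  a_grid <- 10^seq(-1, 4, length.out = 30)
  f_a <- vapply(a_grid, function(a) amplification_fold(5, a, 1, 1), numeric(1))
  expect_true(all(diff(f_a) >= -1e-10))
  expect_error(amplification_fold(5, 0, 1, 1), "zero")
})
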