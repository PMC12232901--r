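test_that("noiseless three-exponential curve is recovered to 4 significant figures", {
  A <- c(0.2, 0.5, 0.3)
  k <- unname(RATES)
  h <- noiseless_crth(A, k)
  f <- fit_mixture(h, 3, n_starts = 25, seed = 1)
  # phases sorted fastest first
  expect_equal(f$rates, sort(k, decreasing = TRUE), tolerance = 1e-4)
  expect_equal(f$amplitudes, A[order(k, decreasing = TRUE)], tolerance = 1e-4)
  expect_true(f$converged)
  expect_lt(f$max_residual_fraction, 1e-6)
})

test_that("single-exponential rate agrees with the closed-form MLE", {
  for (s in c(2, 7)) {
    d <- draw_mixture(2000, 1, 0.5, seed = s)
    f <- fit_mixture(build_crth(d, normalized = TRUE), 1, n_starts = 5, seed = 1)
    expect_equal(f$rates, 1 / mean(d), tolerance = 0.02)
  }
})

test_that("fit matches a brute-force grid search on noiseless curves", {
  # independent oracle: exhaustive search over (A, k) grids
  grid_sse <- function(h, A_grid, k_grid) {
    best <- list(sse = Inf)
    for (A1 in A_grid) for (k1 in k_grid) {
      fitted <- A1 * exp(-k1 * h$t)
      sse <- sum((fitted - h$count)^2)
      if (sse < best$sse) best <- list(sse = sse, A = A1, k = k1)
    }
    best
  }
  h1 <- noiseless_crth(0.8, 0.3, m = 60)
  g <- grid_sse(h1, seq(0.5, 1.1, by = 0.01), seq(0.1, 0.6, by = 0.005))
  f1 <- fit_mixture(h1, 1, n_starts = 5, seed = 1)
  expect_equal(f1$amplitudes, g$A, tolerance = 0.011)
  expect_equal(f1$rates, g$k, tolerance = 0.006)

  # two components: grid over both phases
  A2 <- c(0.6, 0.4); k2 <- c(0.5, 0.02)
  h2 <- noiseless_crth(A2, k2, m = 80)
  f2 <- fit_mixture(h2, 2, n_starts = 10, seed = 1)
  best <- list(sse = Inf)
  for (ka in seq(0.3, 0.7, by = 0.02)) for (kb in seq(0.01, 0.04, by = 0.002)) {
    M <- cbind(exp(-ka * h2$t), exp(-kb * h2$t))
    a <- stats::coef(stats::lm.fit(M, h2$count))
    sse <- sum((drop(M %*% a) - h2$count)^2)
    if (sse < best$sse) best <- list(sse = sse, k = c(ka, kb), A = a)
  }
  expect_equal(f2$rates, best$k, tolerance = 0.02)
  expect_equal(f2$amplitudes, unname(best$A), tolerance = 0.02)
})

test_that("constrained rates pin at the 20% bound when data lie outside it", {
  k_true <- unname(RATES)
  ref <- fit_mixture(noiseless_crth(c(0.3, 0.4, 0.3), k_true), 3,
                     n_starts = 15, seed = 1)
  # data generated at 1.3x the reference rates
  h <- noiseless_crth(c(0.3, 0.4, 0.3), 1.3 * k_true)
  fc <- fit_mixture(h, 3, constraints = constraint_set(ref),
                    n_starts = 10, seed = 1)
  expect_equal(fc$rates, 1.2 * sort(k_true, decreasing = TRUE),
               tolerance = 0.02)
  expect_true(any(grepl("rate", fc$constraints_active)))
  # constraint containment invariant
  expect_true(all(fc$rates <= 1.2 * sort(k_true, TRUE) * 1.001))
  expect_true(all(fc$rates >= 0.8 * sort(k_true, TRUE) * 0.999))
})

test_that("amplitude sum stays within 20% of the event total under constraints", {
  for (s in 1:3) {
    d <- draw_mixture(800, c(0.5, 0.46, 0.04), unname(RATES), seed = s)
    ref <- fit_mixture(build_crth(draw_mixture(4000, c(0.5, 0.46, 0.04),
                                               unname(RATES), seed = s + 100),
                                  normalized = TRUE), 3, n_starts = 10, seed = 1)
    fc <- fit_mixture(build_crth(d, normalized = TRUE), 3,
                      constraints = constraint_set(ref), n_starts = 5, seed = 1)
    expect_gte(sum(fc$amplitudes), 0.8 - 1e-6)
    expect_lte(sum(fc$amplitudes), 1.2 + 1e-6)
  }
})

test_that("duplicate rates collapse to a smaller model with a warning", {
  h <- noiseless_crth(0.9, 0.2, m = 80)
  expect_warning(f <- fit_mixture(h, 2, n_starts = 8, seed = 1),
                 "duplicate rate")
  expect_equal(f$n_components, 1L)
  expect_equal(f$rates, 0.2, tolerance = 1e-3)
})

test_that("component count selection identifies the generating model", {
  # residual criteria are attainable once sampling noise sits below the
  # 0.5% bound, i.e. for tens of thousands of events
  d3 <- draw_mixture(30000, c(0.5, 0.46, 0.04), unname(RATES), seed = 11)
  expect_equal(as.integer(select_n_components(build_crth(d3, normalized = TRUE),
                                              n_starts = 8, seed = 1)), 3L)
  d1 <- draw_mixture(30000, 1, RATES[["drx"]], seed = 21)
  expect_equal(as.integer(select_n_components(build_crth(d1, normalized = TRUE),
                                              n_starts = 8, seed = 1)), 1L)
  # two well-separated phases (x20 rate ratio)
  d2 <- draw_mixture(30000, c(0.5, 0.5), c(1, 0.05), seed = 31)
  expect_equal(as.integer(select_n_components(build_crth(d2, normalized = TRUE),
                                              n_starts = 8, seed = 1)), 2L)
})

test_that("fits are deterministic given the seed", {
  d <- draw_mixture(1500, c(0.5, 0.46, 0.04), unname(RATES), seed = 3)
  h <- build_crth(d, normalized = TRUE)
  f1 <- fit_mixture(h, 3, n_starts = 10, seed = 9)
  f2 <- fit_mixture(h, 3, n_starts = 10, seed = 9)
  expect_identical(f1$rates, f2$rates)
  expect_identical(f1$amplitudes, f2$amplitudes)
})
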