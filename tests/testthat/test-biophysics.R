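test_that("compression modulus is exact on linear isotherms", {
  A <- seq(100, 40, by = -1)
  cs <- compression_modulus(A, 50 - 0.5 * A)
  expect_equal(cs$cs_inv, 0.5 * A, tolerance = 1e-10)
  expect_equal(cs$cs_inv[A == 60], 30)
  cs0 <- compression_modulus(A, rep(20, length(A)))
  expect_equal(cs0$cs_inv, rep(0, length(A)))
  expect_error(compression_modulus(c(1, 3, 2, 4, 5), 1:5), "monotone")
})

test_that("compression modulus tracks the analytic derivative within 2%", {
  tr <- synth_traces("isotherm", seed = 1)
  cs <- compression_modulus(tr$data$A, tr$data$pi)
  truth <- tr$truth$cs_inv_analytic
  interior <- 10:(length(truth) - 10)
  relerr <- abs(cs$cs_inv[interior] - truth[interior]) /
    pmax(abs(truth[interior]), 1e-8)
  expect_lt(max(relerr), 0.02)
  # physiological-pressure band average is computable
  expect_true(is.finite(mean_cs_inv(cs, c(25, 35))))
})

test_that("compression modulus is dimensionally consistent under area rescaling", {
  tr <- synth_traces("isotherm", seed = 2)
  cs1 <- compression_modulus(tr$data$A, tr$data$pi)
  cs2 <- compression_modulus(tr$data$A * 3, tr$data$pi)
  # Cs^-1 = -A dpi/dA is invariant when A is rescaled
  expect_equal(cs2$cs_inv, cs1$cs_inv, tolerance = 1e-10)
})

test_that("exponential fitting recovers noiseless and planted rates", {
  t <- seq(0, 1.5, length.out = 10)
  f <- fit_exponential_decay(t, 2 * exp(-3 * t))
  expect_equal(f$A, 2, tolerance = 1e-8)
  expect_equal(f$R, 3, tolerance = 1e-8)
  expect_warning(fc <- fit_exponential_decay(t, rep(1.7, 10)), "decay")
  expect_false(fc$decaying)
  expect_equal(fc$R, 0, tolerance = 1e-6)
  # paper-style delay grids, 1% noise: mean recovered rate within 1%
  for (grid in c("t2", "t1")) {
    R <- if (grid == "t2") 12 else 1.4
    rs <- vapply(1:60, function(s) {
      tr <- synth_traces("decay", list(grid = grid, A = 2, R = R, noise = 0.01),
                         seed = 1000 + s)
      fit_exponential_decay(tr$data$t, tr$data$h)$R
    }, 1)
    expect_lt(abs(mean(rs) - R) / R, 0.01)
  }
})

test_that("hetNOE ratios broadcast and propagate errors", {
  expect_equal(het_noe(1, 1), 1)
  expect_equal(het_noe(0.4, 0.5), 0.8)
  expect_equal(het_noe(c(1, 2, 3), c(2, 2, 2)), c(0.5, 1, 1.5))
  expect_error(het_noe(1, 0), "I0 = 0")
  out <- het_noe(0.4, 0.5, sigma_I = 0.02, sigma_I0 = 0.01)
  expect_equal(out$sigma, 0.8 * sqrt((0.02 / 0.4)^2 + (0.01 / 0.5)^2))
})

test_that("anisotropy follows the gamma-corrected formula and bounds", {
  expect_equal(anisotropy(1, 1, g = 1), 0)
  expect_equal(anisotropy(2, 0, g = 1.171), 1)
  expect_equal(anisotropy(1, 1, g = 1.171), -0.171 / 3.342, tolerance = 1e-10)
  expect_error(anisotropy(-1, 1), "negative")
  set.seed(6)
  for (i in 1:50) {
    r <- anisotropy(runif(1, 0.01, 5), runif(1, 0.01, 5), g = 1)
    expect_true(r >= -0.5 && r <= 1)
  }
  # inverse construction round-trip
  tr <- synth_traces("anisotropy", list(r = 0.23), seed = 1)
  expect_equal(anisotropy(tr$data$I_par, tr$data$I_perp, tr$data$g), 0.23,
               tolerance = 1e-12)
})

test_that("thermogram peak extraction subtracts baseline and finds peaks", {
  tr <- synth_traces("thermogram", list(centers = 11.0, offset = 0.2), seed = 1)
  pk <- thermogram_peak(tr$data$T, tr$data$cp)
  expect_equal(pk$Tm, 11.0, tolerance = 0.051)
  expect_equal(pk$baseline, 0.2, tolerance = 1e-6)
  # constant offset changes nothing after baseline correction
  pk2 <- thermogram_peak(tr$data$T, tr$data$cp + 3.3)
  expect_equal(pk2$Tm, pk$Tm)
  expect_equal(pk2$peak_height, pk$peak_height, tolerance = 1e-9)
  # two-peak trace: dominant + one secondary at planted centers
  tr2 <- synth_traces("thermogram",
                      list(centers = c(8, 12), heights = c(0.5, 1),
                           widths = c(0.7, 0.5)), seed = 2)
  pk3 <- thermogram_peak(tr2$data$T, tr2$data$cp)
  expect_equal(pk3$Tm, 12, tolerance = 0.051)
  expect_true(any(abs(pk3$secondary_peaks$T - 8) <= 0.1))
})

test_that("planted Tm shifts are resolved by the unpaired t test", {
  # two replicate sets, Delta Tm = 0.32 C, sigma = 0.04, n = 3
  tm <- function(center, seed) {
    tr <- synth_traces("thermogram",
                       list(centers = center, noise = 0.005), seed = seed)
    thermogram_peak(tr$data$T, tr$data$cp)$Tm
  }
  set.seed(123)
  g1 <- vapply(1:3, function(k) tm(rnorm(1, 10.96, 0.04), 10 + k), 1)
  g2 <- vapply(1:3, function(k) tm(rnorm(1, 11.28, 0.04), 20 + k), 1)
  r <- unpaired_t(g1, g2, welch = FALSE)
  expect_lt(r$p_value, 0.01)
})
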