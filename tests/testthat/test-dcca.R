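test_that("self- and anti-correlation give exactly +/-1", {
  set.seed(1)
  x <- cumsum(rnorm(60))
  expect_equal(rho_dcca(x, x, 8), 1, tolerance = 1e-10)
  expect_equal(rho_dcca(x, -x, 8), -1, tolerance = 1e-10)
})

test_that("rho matches the literal brute-force oracle on random pairs", {
  set.seed(2)
  for (i in 1:50) {
    x <- cumsum(rnorm(50))
    y <- cumsum(rnorm(50))
    expect_equal(rho_dcca(x, y, 8), brute_dcca(x, y, 8), tolerance = 1e-12)
  }
})

test_that("rho is invariant to affine rescaling of either series", {
  set.seed(3)
  x <- cumsum(rnorm(80))
  y <- cumsum(rnorm(80))
  base <- rho_dcca(x, y, 10)
  expect_equal(rho_dcca(3.7 * x - 12, y, 10), base, tolerance = 1e-10)
  expect_equal(rho_dcca(x, -2 * y + 5, 10), -base, tolerance = 1e-10)
})

test_that("rho input validation and degenerate cases error as declared", {
  x <- cumsum(rnorm(30))
  expect_error(rho_dcca(x, x[-1], 8), "equal length")
  expect_error(rho_dcca(x, x, 3), "at least 4")
  expect_error(rho_dcca(x, x, 20), "too short")
  const <- rep(2, 30)  # flat series: profile is identically zero
  expect_error(rho_dcca(const, rnorm(30), 8), "undefined coefficient")
})

test_that("rho recovers the true cross-correlation of i.i.d. Gaussian pairs", {
  set.seed(4)
  for (target in c(-0.5, 0, 0.5)) {
    rhos <- replicate(100, {
      z <- rnorm(2000)
      x <- sqrt(abs(target)) * z + sqrt(1 - abs(target)) * rnorm(2000)
      y <- sign(target) * sqrt(abs(target)) * z +
        sqrt(1 - abs(target)) * rnorm(2000)
      rho_dcca(x, y, default_dcca_scale(2000))
    })
    expect_lt(abs(mean(rhos) - target), 0.05)
  }
})

test_that("ensemble correlation returns one coefficient per realization", {
  g <- time_grid(50, 1)
  driver <- cumsum(rnorm(50))
  base <- driver + rnorm(50, 0, 0.5)
  m <- rate_ensemble(g, pmax(base - min(base) + 0.1, 0), rep(0.1, 50))
  ens <- emulate_posterior(m, ensemble_noise(40, 0.1, 5, seed = 5))
  rho <- correlate_ensemble(ens, driver, "speciation", 10)
  expect_length(rho, 40)
  expect_gt(mean(rho), 0)   # positive-coupling construction

  zero_noise <- emulate_posterior(m, ensemble_noise(12, 0, 5, seed = 6))
  rho0 <- correlate_ensemble(zero_noise, driver, "speciation", 10)
  expect_true(all(rho0 == rho0[1]))
})

test_that("scale-averaged mode is the mean of the single-scale coefficients", {
  set.seed(14)
  g <- time_grid(60, 1)
  driver <- cumsum(rnorm(60))
  m <- rate_ensemble(g, pmax(cumsum(rnorm(60, 0, 0.1)) + 1, 0.05), rep(0.1, 60))
  ens <- emulate_posterior(m, ensemble_noise(5, 0.1, 4, seed = 15))
  multi <- correlate_ensemble(ens, driver, "speciation", scale = c(8, 12))
  s8 <- correlate_ensemble(ens, driver, "speciation", scale = 8)
  s12 <- correlate_ensemble(ens, driver, "speciation", scale = 12)
  expect_equal(multi, (as.numeric(s8) + as.numeric(s12)) / 2,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("independent drivers give near-zero mean coefficients", {
  set.seed(7)
  g <- time_grid(200, 1)
  base <- pmax(1 + cumsum(rnorm(200, 0, 0.05)), 0.1)
  m <- rate_ensemble(g, base, rep(0.2, 200))
  ens <- emulate_posterior(m, ensemble_noise(200, 0.15, 10, seed = 8))
  driver <- as.numeric(arima.sim(list(ar = 0.9), 200))
  rho <- correlate_ensemble(ens, driver, "speciation", 20)
  expect_lt(abs(mean(rho)), 0.1)
})

test_that("summaries report the percentiles, Wilcoxon p and the magnitude rule", {
  set.seed(10)
  rho <- rnorm(200, 0.204, 0.09)
  s <- summarize_correlations(rho, "marine", "temperature", "speciation")
  expect_true(s$reported)           # |mean| > 0.1
  expect_lte(s$ci2.5, s$mean)
  expect_gte(s$ci97.5, s$mean)
  expect_lt(s$wilcoxon_p, 1e-10)

  weak <- summarize_correlations(rnorm(200, -0.003, 0.1), "marine",
                                 "sea_level", "speciation")
  expect_false(weak$reported)

  const <- summarize_correlations(rep(0.5, 20), "x", "y", "net")
  expect_equal(const$mean, 0.5)
  expect_equal(const$ci2.5, 0.5)
  expect_equal(const$ci97.5, 0.5)
  expect_equal(const$wilcoxon_p, 2 * 0.5^20)
})

test_that("exact Wilcoxon p matches full enumeration for n <= 10", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5)), 0.0625)  # 2 / 2^5
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:10, 1)
    v <- round(rnorm(n), 2)
    v <- v[v != 0]
    if (length(v) < 5) next
    expect_equal(wilcoxon_signed_rank(v), brute_wilcoxon(v), tolerance = 1e-12)
  }
  # ties included
  expect_equal(wilcoxon_signed_rank(c(1, 1, -1, 2, 2)),
               brute_wilcoxon(c(1, 1, -1, 2, 2)), tolerance = 1e-12)
})

test_that("wilcoxon agrees with the base-R exact test on tie-free samples", {
  set.seed(12)
  for (i in 1:10) {
    v <- rnorm(9)
    expect_equal(wilcoxon_signed_rank(v),
                 wilcox.test(v, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("wilcoxon has power and respects symmetry", {
  set.seed(13)
  shifted <- rnorm(50) + 1
  expect_lt(wilcoxon_signed_rank(shifted), 0.001)
  sym <- c(-3, 3, -2, 2, -1, 1)
  expect_gt(wilcoxon_signed_rank(sym), 0.9)
  expect_error(wilcoxon_signed_rank(rep(0, 10)), "zero")
})
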