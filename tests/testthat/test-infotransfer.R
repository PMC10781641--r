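test_that("equal-width discretization honours the request and the sparse-bin rule", {
  s <- discretize_series(1:100, 4)
  expect_identical(attr(s, "n_states"), 4L)
  expect_equal(as.vector(table(s)), rep(25L, 4), ignore_attr = TRUE)

  # a heavy-tailed series cannot support 20 dense bins
  set.seed(1)
  skew <- c(rexp(200), 50)
  s2 <- discretize_series(skew, 20)
  expect_lt(attr(s2, "n_states"), 20L)
  expect_true(all(tabulate(s2, attr(s2, "n_states")) > 1) ||
                attr(s2, "n_states") == 2L)

  s3 <- discretize_series(rep(c(0, 1), 50), 17)
  expect_identical(attr(s3, "n_states"), 2L)

  expect_error(discretize_series(rep(1, 50), 4), "constant")
})

test_that("transfer entropy hits the closed form for a deterministic copy", {
  set.seed(2)
  x <- sample(1:2, 10000, TRUE)
  y <- c(1L, x[-10000])     # y(t) = x(t-1): H(Y+|Y) = 1 bit, H(Y+|Y,X) = 0
  expect_gt(shannon_te(x, y), 0.98)
  expect_lte(shannon_te(x, y), 1)
  expect_lt(shannon_te(y, x), 0.02)
  # independent sequences carry nothing beyond plug-in bias
  z <- sample(1:2, 10000, TRUE)
  expect_lt(shannon_te(z, y), 0.02)
})

test_that("transfer entropy equals the literal-summation oracle", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    n <- 300
    sx <- sample(seq_len(k), n, TRUE)
    sy <- pmin(k, pmax(1, sx + sample(-1:1, n, TRUE)))
    sy <- c(sy[1], sy[-n])
    te_val <- suppressWarnings(shannon_te(sx, sy))  # short-series bias warning
    expect_equal(te_val, brute_te(sx, sy), tolerance = 1e-12)
    expect_gte(te_val, -1e-12)  # plug-in TE is non-negative
  }
})

test_that("TE rises monotonically with coupling strength", {
  med_te <- vapply(c(0, 0.5, 1, 2), function(alpha) {
    tes <- vapply(1:20, function(s) {
      set.seed(1000 + s)
      x <- rnorm(2000)
      y <- alpha * c(0, x[-2000]) + rnorm(2000)
      shannon_te(as.integer(discretize_series(x, 3)),
                 as.integer(discretize_series(y, 3)))
    }, numeric(1))
    median(tes)
  }, numeric(1))
  expect_identical(order(med_te), 1:4)
})

test_that("block bootstrap flags the copy pair and is reproducible", {
  set.seed(4)
  x <- sample(1:2, 2000, TRUE)
  y <- c(1L, x[-2000])
  cfg <- te_config(n_repeats = 3, n_bootstrap = 1000, seed = 9)
  r1 <- effective_te_and_p(x, y, cfg)
  expect_lte(r1$p_value, 0.001)
  expect_true(r1$retained)
  expect_gt(r1$effective_te_bits, 0.9)
  r2 <- effective_te_and_p(x, y, te_config(n_repeats = 3, n_bootstrap = 1000,
                                           seed = 9))
  expect_identical(r1, r2)

  expect_error(effective_te_and_p(x, y, te_config(block_length = 2000)),
               "block_length")
})

test_that("block-bootstrap p-values are calibrated on independent pairs", {
  set.seed(5)
  p_vals <- ette <- numeric(50)
  for (i in 1:50) {
    x <- as.integer(discretize_series(as.numeric(arima.sim(list(ar = 0.6), 500)), 3))
    y <- as.integer(discretize_series(as.numeric(arima.sim(list(ar = 0.6), 500)), 3))
    r <- effective_te_and_p(x, y, te_config(n_repeats = 1, n_bootstrap = 200,
                                            seed = 5000 + i))
    p_vals[i] <- r$p_value
    ette[i] <- r$effective_te_bits
  }
  expect_gte(mean(p_vals > 0.05), 0.8)
  expect_lt(abs(mean(ette)), 0.02)
})

test_that("HMM state selection recovers a well-separated 3-state chain", {
  hits <- vapply(1:10, function(s) {
    x <- gen_hmm_series(2000, c(-5, 0, 5), 0.5, 0.95, s)
    set.seed(s * 19)
    select_states(x, 2:6) == 3L
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("HMM-AIC penalizes over-parameterization on white noise", {
  ks <- vapply(1:10, function(s) {
    set.seed(s + 400)
    x <- rnorm(1500)
    set.seed(s * 23)
    as.integer(select_states(x, 2:6))
  }, integer(1))
  expect_gte(mean(ks <= 3), 0.8)
})

test_that("state selection rejects degenerate or too-short input", {
  expect_error(select_states(rep(1, 500), 2:4), "constant")
  expect_error(select_states(rnorm(50), 2:20), "too short")
})

test_that("reversing time flips the roles of source and target", {
  # for a lag-1 copy, reversal turns the X->Y flow into Y->X
  set.seed(6)
  x <- sample(1:2, 4000, TRUE)
  y <- c(1L, x[-4000])
  expect_gt(shannon_te(x, y) - shannon_te(y, x), 0.9)
  expect_gt(shannon_te(rev(y), rev(x)) - shannon_te(rev(x), rev(y)), 0.9)
})
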