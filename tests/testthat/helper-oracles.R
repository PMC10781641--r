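# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately literal (explicit loops, lm() fits, full
# enumerations) and share no code with the package internals.

# DCCA coefficient: zero-anchored cumulative profiles, overlapping boxes of
# scale+1 points, per-box least-squares detrending via lm(), box-averaged
# residual products.
brute_dcca <- function(x, y, scale) {
  X <- c(0, cumsum(x - mean(x)))
  Y <- c(0, cumsum(y - mean(y)))
  n <- length(X)
  f2xy <- f2x <- f2y <- 0
  for (i in 1:(n - scale)) {
    idx <- i:(i + scale)
    tt <- seq_along(idx)
    rx <- residuals(lm(X[idx] ~ tt))
    ry <- residuals(lm(Y[idx] ~ tt))
    f2xy <- f2xy + mean(rx * ry)
    f2x <- f2x + mean(rx^2)
    f2y <- f2y + mean(ry^2)
  }
  f2xy / sqrt(f2x * f2y)
}

# Plug-in transfer entropy by literal summation over the empirical joint
# distribution of (y_next, y_history, x_history), order-1 histories.
brute_te <- function(sx, sy) {
  n <- length(sx)
  joint <- table(yp = sy[2:n], yk = sy[1:(n - 1)], xl = sx[1:(n - 1)])
  N <- n - 1
  te <- 0
  for (yp in dimnames(joint)$yp) for (yk in dimnames(joint)$yk)
    for (xl in dimnames(joint)$xl) {
      n1 <- joint[yp, yk, xl]
      if (n1 == 0) next
      n2 <- sum(joint[, yk, xl])
      n3 <- sum(joint[yp, yk, ])
      n4 <- sum(joint[, yk, ])
      te <- te + n1 / N * log2(n1 * n4 / (n2 * n3))
    }
  te
}

# Exact two-sided Wilcoxon signed-rank p-value by full 2^n enumeration of
# sign assignments on the observed absolute ranks.
brute_wilcoxon <- function(values) {
  values <- values[values != 0]
  n <- length(values)
  r <- rank(abs(values))
  v_obs <- sum(r[values > 0])
  centre <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - centre) >= abs(v_obs - centre) - 1e-9)
}

# Sticky-transition Gaussian HMM sampler for state-count recovery tests.
gen_hmm_series <- function(n, means, sd_emit, stay, seed) {
  set.seed(seed)
  k <- length(means)
  s <- integer(n)
  s[1] <- sample.int(k, 1)
  for (t in 2:n)
    s[t] <- if (runif(1) < stay) s[t - 1] else sample(setdiff(1:k, s[t - 1]), 1)
  rnorm(n, means[s], sd_emit)
}

# Small fixed test tree: root at 10 Ma, tip X extinct at 4 Ma, tip Y extant.
two_tip_tree <- function() {
  tr <- ape::read.tree(text = "(X:6,Y:10);")
  tr
}
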