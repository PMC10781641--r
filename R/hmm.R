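#' Fit a Gaussian-emission hidden Markov model by EM
#'
#' Expectation-maximization (Baum-Welch) with scaled forward-backward
#' recursions for a univariate Gaussian-emission HMM with `k` hidden states.
#' Initial means are spread over the data quantiles (jittered across
#' restarts), initial transitions are sticky (0.9 on the diagonal), and state
#' variances are floored at `1e-6 * var(x)` to keep a state from collapsing
#' onto a single point. The best of `n_restarts` fits by log-likelihood is
#' returned.
#'
#' @param x Numeric series.
#' @param k Number of hidden states (>= 1).
#' @param n_restarts EM restarts with jittered initial means.
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood change falls below `tol` or after `max_iter` iterations.
#' @return A list with `loglik`, `aic`, `k`, `n_par`, `means`, `vars`,
#'   `trans`, `init`, `converged`. The AIC uses
#'   `n_par = k^2 + 2k - 1` free parameters (k-1 initial probabilities,
#'   k(k-1) transition rates, k means, k variances).
#' @export
fit_ghmm <- function(x, k, n_restarts = 3L, max_iter = 200L, tol = 1e-6) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be at least 1")
  vx <- var(x)
  if (!is.finite(vx) || vx <= 0) stop("degenerate input: constant series")
  var_floor <- 1e-6 * vx
  qs <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  km <- tryCatch(stats::kmeans(x, k, nstart = 5L), error = function(e) NULL)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    if (r == 1L && !is.null(km)) {
      means0 <- sort(as.numeric(km$centers))
      vars0 <- pmax(km$withinss / pmax(km$size, 1L), var_floor)[order(km$centers)]
    } else {
      means0 <- qs + if (r == 2L) 0 else rnorm(k, 0, sd(x) / 4)
      vars0 <- rep(vx, k)
    }
    trans0 <- matrix(0.1 / max(1L, k - 1L), k, k)
    diag(trans0) <- if (k == 1L) 1 else 0.9
    fit <- ghmm_em_cpp(x, rep(1 / k, k), trans0, means0, vars0,
                       as.integer(max_iter), tol, var_floor)
    if (!isTRUE(fit$ok) || !is.finite(fit$loglik)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("EM failed to produce a finite likelihood for k = ", k)
  n_par <- k^2 + 2L * k - 1L
  list(loglik = best$loglik, aic = -2 * best$loglik + 2 * n_par, k = k,
       n_par = n_par, means = best$means, vars = best$vars,
       trans = best$trans, init = best$init, converged = best$converged)
}

#' Select the number of Markov states by HMM-AIC
#'
#' Fits a Gaussian-emission HMM for every candidate state count and returns
#' the count minimizing the Akaike Information Criterion,
#' `AIC = -2 logL + 2 p` with `p = k^2 + 2k - 1`. Ties go to the smallest
#' `k`. Candidates whose EM fit fails are skipped with a warning; if every
#' candidate fails, selection fails with an error. The chosen count is used
#' downstream as the discretization alphabet for transfer entropy.
#'
#' @param x Numeric series; its length must be at least
#'   `10 * max(state_range)` so the largest model is identifiable.
#' @param state_range Integer candidates (default `2:20`).
#' @param n_restarts EM restarts per candidate.
#' @return The AIC-minimizing state count (integer), with the full AIC table
#'   attached as attribute `aic_table`.
#' @examples
#' set.seed(1)
#' x <- rnorm(400)
#' select_states(x, 2:4)
#' @export
select_states <- function(x, state_range = 2:20, n_restarts = 3L) {
  state_range <- sort(unique(as.integer(state_range)))
  if (any(state_range < 2L)) stop("'state_range' must be >= 2")
  if (length(x) < 10L * max(state_range))
    stop("series too short for the requested state range: need at least ",
         10L * max(state_range), " samples, got ", length(x))
  if (!is.finite(var(x)) || var(x) <= 0)
    stop("selection failed: constant (zero-variance) series")
  aics <- rep(NA_real_, length(state_range))
  for (i in seq_along(state_range)) {
    fit <- tryCatch(fit_ghmm(x, state_range[i], n_restarts = n_restarts),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("EM did not converge for k = ", state_range[i], "; skipped")
      next
    }
    aics[i] <- fit$aic
  }
  if (all(is.na(aics))) stop("selection failed: EM failed for every state count")
  k <- state_range[which.min(aics)]  # which.min takes the first (smallest k) tie
  attr(k, "aic_table") <- data.frame(k = state_range, aic = aics)
  k
}
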