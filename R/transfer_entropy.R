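#' Configuration for transfer-entropy testing
#'
#' @param state_range Candidate state counts for HMM-AIC selection
#'   (default `2:20`).
#' @param markov_order History length for both source and target (default 1).
#' @param n_repeats Number of repetitions of the bootstrap procedure; the
#'   median effective TE and p-value over repeats are reported (default 100).
#' @param n_bootstrap Surrogates per repetition (default 1000, minimum 100).
#' @param block_length Bootstrap block length in samples; default
#'   `ceiling(N^(1/3))`, set at run time from the series length.
#' @param seed Optional integer seed.
#' @return A list of class `te_config`.
#' @export
te_config <- function(state_range = 2:20, markov_order = 1L,
                      n_repeats = 100L, n_bootstrap = 1000L,
                      block_length = NULL, seed = NULL) {
  if (markov_order < 1L) stop("'markov_order' must be at least 1")
  if (n_bootstrap < 100L) stop("'n_bootstrap' must be at least 100")
  if (n_repeats < 1L) stop("'n_repeats' must be at least 1")
  structure(list(state_range = as.integer(state_range),
                 markov_order = as.integer(markov_order),
                 n_repeats = as.integer(n_repeats),
                 n_bootstrap = as.integer(n_bootstrap),
                 block_length = block_length, seed = seed),
            class = "te_config")
}

#' Discretize a series into equal-width bins
#'
#' Bins the series into `n_states` equal-width intervals over
#' `[min(x), max(x)]`. Sparse alphabets bias plug-in entropy estimates, so
#' if any bin holds one sample or fewer, the state count is decremented and
#' the binning redone until no bin is sparse (floor of 2 states).
#'
#' @param x Numeric, non-constant series.
#' @param n_states Requested number of bins (>= 2).
#' @return Integer vector of symbols in `1..k`, with the final state count
#'   attached as attribute `n_states`.
#' @examples
#' s <- discretize_series(1:100, 4)
#' attr(s, "n_states")   # 4 bins of 25
#' @export
discretize_series <- function(x, n_states) {
  n_states <- as.integer(n_states)
  if (n_states < 2L) stop("'n_states' must be at least 2")
  rng <- range(x)
  if (!all(is.finite(rng)) || rng[1L] == rng[2L])
    stop("degenerate input: constant series cannot be discretized")
  k <- n_states
  repeat {
    breaks <- seq(rng[1L], rng[2L], length.out = k + 1L)
    sym <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(sym, nbins = k)
    if (all(counts > 1L) || k == 2L) break
    k <- k - 1L
  }
  structure(as.integer(sym), n_states = k)
}

#' Plug-in Shannon transfer entropy (bits)
#'
#' Estimates `TE(X -> Y) = sum p(y+, y_hist, x_hist) *
#' log2[ p(y+ | y_hist, x_hist) / p(y+ | y_hist) ]` over the empirical joint
#' distribution of the embedded symbol histories, in bits. The plug-in TE of
#' an empirical distribution is a conditional mutual information and hence
#' non-negative up to floating-point tolerance; like all plug-in entropy
#' estimators it carries a positive small-sample bias, which
#' [effective_te_and_p()] corrects against a surrogate null.
#'
#' @param source,target Integer symbol vectors of equal length (values in
#'   `1..alphabet`), e.g. from [discretize_series()].
#' @param order History length for both series (default 1).
#' @return Transfer entropy source -> target in bits.
#' @examples
#' set.seed(1)
#' x <- sample(1:2, 500, TRUE)
#' y <- c(1L, x[-500])        # y copies x with lag 1
#' shannon_te(x, y)           # about 1 bit
#' shannon_te(y, x)           # about 0
#' @export
shannon_te <- function(source, target, order = 1L) {
  source <- as.integer(source); target <- as.integer(target)
  if (length(source) != length(target)) stop("series must have equal length")
  if (any(source < 1L) || any(target < 1L)) stop("symbols must be in 1..alphabet")
  ax <- max(source); ay <- max(target)
  order <- as.integer(order)
  n_rec <- 10 * ay^(order + 1) * ax^order
  if (length(source) < n_rec)
    warning("series length ", length(source), " is below the recommended ",
            n_rec, " for this alphabet and order; estimates will be biased")
  te_cpp(source, target, ax, ay, order)
}

#' Effective transfer entropy with Markov block-bootstrap significance
#'
#' Tests for information flow from a source to a target symbol series.
#' The null distribution is built by resampling the source in contiguous
#' blocks (length `block_length`, default `ceiling(N^(1/3))`) with
#' replacement and concatenating to the original length -- destroying the
#' source-target alignment while preserving the source's short-range
#' dependence. For each of `n_repeats` repetitions with fresh bootstrap
#' draws: effective TE = observed TE minus the null mean, and
#' `p = (1 + #\{null >= observed\}) / (n_bootstrap + 1)` (add-one estimator,
#' so p is never exactly 0). The medians over repetitions are reported.
#' A result is retained as evidence of information transfer when
#' `p < p_threshold` and the transfer entropy exceeds `te_threshold` bits.
#'
#' @param source,target Integer symbol vectors (see [discretize_series()]).
#' @param config A [te_config()].
#' @param chosen_states State count to report (e.g. from [select_states()]);
#'   defaults to the source/target alphabet maximum.
#' @param p_threshold,te_threshold Retention rule (defaults 0.001 and 0.1).
#' @return A list of class `te_result`: `direction`, `te_bits`,
#'   `effective_te_bits`, `p_value`, `chosen_states`, `retained`,
#'   `block_length`, `n_bootstrap`, `n_repeats`.
#' @export
effective_te_and_p <- function(source, target, config = te_config(),
                               chosen_states = NULL,
                               p_threshold = 0.001, te_threshold = 0.1) {
  stopifnot(inherits(config, "te_config"))
  source <- as.integer(source); target <- as.integer(target)
  n <- length(source)
  if (length(target) != n) stop("series must have equal length")
  block_len <- as.integer(config$block_length %||% ceiling(n^(1 / 3)))
  if (block_len >= n) stop("'block_length' must be smaller than the series length")
  if (!is.null(config$seed)) set.seed(config$seed)
  ax <- max(source); ay <- max(target)
  obs <- te_cpp(source, target, ax, ay, config$markov_order)
  n_blocks <- as.integer(ceiling(n / block_len))
  p_rep <- ette_rep <- numeric(config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    starts <- matrix(sample.int(n - block_len + 1L,
                                config$n_bootstrap * n_blocks, replace = TRUE),
                     nrow = config$n_bootstrap)
    null_te <- te_boot_cpp(source, target, ax, ay, config$markov_order,
                           starts, block_len)
    p_rep[r] <- (1 + sum(null_te >= obs)) / (config$n_bootstrap + 1)
    ette_rep[r] <- obs - mean(null_te)
  }
  p <- stats::median(p_rep)
  ette <- stats::median(ette_rep)
  structure(list(direction = "source->target",
                 te_bits = obs,
                 effective_te_bits = ette,
                 p_value = p,
                 chosen_states = chosen_states %||% max(ax, ay),
                 retained = (p < p_threshold) && (obs > te_threshold),
                 block_length = block_len,
                 n_bootstrap = config$n_bootstrap,
                 n_repeats = config$n_repeats),
            class = "te_result")
}

#' @export
print.te_result <- function(x, ...) {
  cat(sprintf("Transfer entropy %s: TE = %.4f bits (effective %.4f), p = %.4g, states = %d, %s\n",
              x$direction, x$te_bits, x$effective_te_bits, x$p_value,
              x$chosen_states, if (x$retained) "retained" else "not retained"))
  invisible(x)
}
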