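#' Running-mean (Tukey-style) smoothing of a proxy series
#'
#' Smooths a series in place on its own time stamps. The default mode is a
#' centred moving average of odd window length, with windows shrinking on one
#' side near the series ends; this is the reading of "Tukey running mean"
#' used throughout the package. Because the phrase is ambiguous, Tukey's
#' 3RS3R running-median smoother is available as an alternative mode (the
#' window argument is ignored there, as 3RS3R has its own fixed spans).
#'
#' @param series An [env_series()].
#' @param window Odd window length in samples, `>= 3` and at most the series
#'   length (mean mode only; default 11).
#' @param mode `"mean"` (centred moving average) or `"median3RS3R"`.
#' @return An [env_series()] on the same time stamps.
#' @examples
#' es <- env_series(c(2, 1, 0), c(1, 10, 1))
#' tukey_smooth(es, 3)$values   # centre becomes 4
#' @export
tukey_smooth <- function(series, window = 11L, mode = c("mean", "median3RS3R")) {
  stopifnot(inherits(series, "env_series"))
  mode <- match.arg(mode)
  v <- series$values
  n <- length(v)
  if (mode == "median3RS3R") {
    sm <- as.numeric(stats::smooth(v, kind = "3RS3R"))
    return(env_series(series$times, sm, series$name))
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("'window' must be odd")
  if (window < 3L) stop("'window' must be at least 3")
  if (window > n) stop("'window' exceeds the series length")
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  env_series(series$times, sm, series$name)
}

#' Interpolate a series onto a time grid
#'
#' Piecewise-linear interpolation of a proxy series at the bin midpoints of
#' a [time_grid()]. Extrapolation is refused: every midpoint must lie inside
#' the series' time span.
#'
#' @param series An [env_series()].
#' @param grid A [time_grid()].
#' @return Numeric vector of values at `grid$mids` (descending times).
#' @examples
#' es <- env_series(c(10, 0), c(1, 2))
#' g <- time_grid(10, 5)    # midpoints 7.5, 2.5
#' to_grid(es, g)
#' @export
to_grid <- function(series, grid) {
  stopifnot(inherits(series, "env_series"), inherits(grid, "time_grid"))
  if (max(grid$mids) > max(series$times) + 1e-12 ||
      min(grid$mids) < min(series$times) - 1e-12)
    stop("grid midpoints exceed the series' time span (",
         max(series$times), "-", min(series$times),
         " Ma); extrapolation is refused")
  approx(series$times, series$values, xout = grid$mids, rule = 1)$y
}

#' Bridge masked bins by linear interpolation
#'
#' Fills interior `NA` runs in a curve on a grid by linear interpolation
#' between the neighbouring defined values; leading/trailing `NA`s (no
#' neighbour on one side) are left in place. The number of bridged bins is
#' attached as attribute `n_bridged` so every bridge is loggable.
#'
#' @param values Numeric vector with possible `NA`s.
#' @return Numeric vector with interior `NA`s bridged.
#' @export
bridge_masked <- function(values) {
  n_na <- sum(is.na(values))
  if (n_na == 0L || sum(!is.na(values)) < 2L) {
    attr(values, "n_bridged") <- 0L
    return(values)
  }
  idx <- seq_along(values)
  out <- approx(idx[!is.na(values)], values[!is.na(values)], xout = idx,
                rule = 1)$y
  attr(out, "n_bridged") <- sum(is.na(values) & !is.na(out))
  out
}

#' Align a driver and a response curve on a common grid
#'
#' Restricts two curves, each given on its own [time_grid()] of equal
#' spacing, to the bins they share, bridges masked response bins
#' ([bridge_masked()]), and orients both past to present. All downstream
#' statistics (DCCA, transfer entropy) are computed on this orientation.
#'
#' @param driver_values,response_values Numeric vectors on the midpoints of
#'   their grids.
#' @param driver_grid,response_grid [time_grid()] objects of equal spacing.
#' @param min_overlap Minimum number of shared bins (default 10).
#' @return An object of class `aligned_pair`: list with `mids` (shared bin
#'   midpoints, descending = past to present), `x` (driver), `y` (response)
#'   and `n_bridged`.
#' @export
align <- function(driver_values, driver_grid, response_values, response_grid,
                  min_overlap = 10L) {
  stopifnot(inherits(driver_grid, "time_grid"), inherits(response_grid, "time_grid"))
  if (abs(driver_grid$spacing - response_grid$spacing) > 1e-12)
    stop("grids must share the same spacing")
  h <- driver_grid$spacing
  key_d <- round(driver_grid$mids / h * 2)   # mids are odd multiples of h/2
  key_r <- round(response_grid$mids / h * 2)
  shared <- intersect(key_d, key_r)
  if (length(shared) < min_overlap)
    stop("insufficient overlap: ", length(shared), " shared bins (need >= ",
         min_overlap, ")")
  shared <- sort(shared, decreasing = TRUE)
  x <- driver_values[match(shared, key_d)]
  y <- response_values[match(shared, key_r)]
  y <- bridge_masked(y)
  n_bridged <- attr(y, "n_bridged")
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < min_overlap)
    stop("insufficient overlap after removing undefined bins: ", sum(keep))
  structure(list(mids = shared[keep] * h / 2, x = x[keep], y = as.numeric(y)[keep],
                 n_bridged = n_bridged),
            class = "aligned_pair")
}
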