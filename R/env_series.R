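#' Environmental proxy time series
#'
#' Container for a single proxy curve (palaeotemperature, eustatic sea level,
#' ...) sampled through geological time. Times are in Ma before present and
#' run from the oldest sample down to the present; values are in the proxy's
#' native units (deg C, m, lineage counts, ...).
#'
#' @param times Numeric vector of ages in Ma, strictly decreasing.
#' @param values Numeric vector of proxy values, same length as `times`.
#' @param name Label for the proxy (e.g. `"temperature"`).
#' @return An object of class `env_series`: a list with elements `times`,
#'   `values` and `name`.
#' @examples
#' es <- env_series(c(10, 5, 0), c(18, 20, 19), "temperature")
#' print(es)
#' @export
env_series <- function(times, values, name = "proxy") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2L)
    stop("an environmental series needs at least 2 samples")
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length")
  if (any(diff(times) >= 0))
    stop("'times' must be strictly decreasing (oldest first, in Ma)")
  if (!all(is.finite(values)))
    stop("'values' must all be finite")
  structure(list(times = times, values = values, name = as.character(name)[1L]),
            class = "env_series")
}

#' @export
print.env_series <- function(x, ...) {
  cat(sprintf("Environmental series '%s': %d samples, %.4g-%.4g Ma, values in [%.4g, %.4g]\n",
              x$name, length(x$times), max(x$times), min(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Generate a synthetic environmental proxy series
#'
#' Draws an autocorrelated proxy curve on an even time grid spanning
#' `[span, 0]` Ma. Two generating models are available: a Gaussian random walk
#' and a mean-reverting Ornstein-Uhlenbeck (OU) process discretized exactly
#' over the grid step.
#'
#' For the OU model with reversion rate `theta` (per Myr), stationary mean
#' `mean` and diffusion `sigma`, the update over a step `dt` is
#' `x' = mean + (x - mean) * exp(-theta dt) + sqrt(sigma^2 (1 - exp(-2 theta dt)) / (2 theta)) * z`
#' with standard normal `z`; the stationary variance is `sigma^2 / (2 theta)`.
#' `theta = 0` degenerates to a driftless random walk with step standard
#' deviation `sigma * sqrt(dt)`.
#'
#' @param n_points Number of grid points (>= 2).
#' @param model `"random_walk"` or `"mean_reverting"`.
#' @param params Named list of model parameters. Random walk: `start`
#'   (default 0) and `step_sd` (per sqrt(Myr), default 1). Mean reverting:
#'   `mean` (default 0), `theta` (>= 0, default 0.1), `sigma` (>= 0, default 1)
#'   and `x0` (default `mean`).
#' @param span Oldest time in Ma (> 0); the grid runs evenly from `span` to 0.
#' @param seed Optional integer seed; the same seed reproduces the series
#'   exactly.
#' @param name Label for the resulting series.
#' @return An [env_series()].
#' @examples
#' te <- gen_environment(201, "mean_reverting",
#'                       list(mean = 0, theta = 0.05, sigma = 1),
#'                       span = 100, seed = 1, name = "temperature")
#' @export
gen_environment <- function(n_points,
                            model = c("random_walk", "mean_reverting"),
                            params = list(), span, seed = NULL,
                            name = "proxy") {
  model <- match.arg(model)
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("'n_points' must be at least 2")
  if (!is.numeric(span) || span <= 0) stop("'span' must be a positive time span in Ma")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(span, 0, length.out = n_points)
  dt <- span / (n_points - 1L)
  values <- switch(model,
    random_walk = {
      start <- params$start %||% 0
      step_sd <- params$step_sd %||% 1
      if (step_sd < 0) stop("'step_sd' must be non-negative")
      start + c(0, cumsum(rnorm(n_points - 1L, 0, step_sd * sqrt(dt))))
    },
    mean_reverting = {
      mu <- params$mean %||% 0
      theta <- params$theta %||% 0.1
      sigma <- params$sigma %||% 1
      x0 <- params$x0 %||% mu
      if (theta < 0) stop("'theta' must be non-negative")
      if (sigma < 0) stop("'sigma' must be non-negative")
      decay <- exp(-theta * dt)
      step_sd <- if (theta > 0) sigma * sqrt((1 - decay^2) / (2 * theta))
                 else sigma * sqrt(dt)
      x <- numeric(n_points)
      x[1L] <- x0
      z <- rnorm(n_points - 1L)
      for (i in seq_len(n_points - 1L))
        x[i + 1L] <- mu + (x[i] - mu) * decay + step_sd * z[i]
      x
    })
  env_series(times, values, name)
}

#' Read / write an environmental series as CSV
#'
#' The on-disk format is a two-column CSV with header `time_ma,value`,
#' oldest sample first.
#'
#' @param path File path.
#' @param series An [env_series()].
#' @param name Label to attach on read (defaults to the file name).
#' @return `read_series()` returns an [env_series()]; `write_series()`
#'   invisibly returns `path`.
#' @export
read_series <- function(path, name = NULL) {
  df <- read.csv(path)
  if (!all(c("time_ma", "value") %in% names(df)))
    stop("series CSV must have columns 'time_ma' and 'value': ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  o <- order(df$time_ma, decreasing = TRUE)
  env_series(df$time_ma[o], df$value[o], name)
}

#' @rdname read_series
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "env_series"))
  write.csv(data.frame(time_ma = series$times, value = series$values),
            path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
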