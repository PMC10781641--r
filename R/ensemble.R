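#' Rate-curve ensemble on a time grid
#'
#' Realizations-by-bins matrices of speciation, extinction and net
#' diversification rates (events/lineage/Myr) on the midpoints of a
#' [time_grid()]. A single-realization ensemble holds point estimates (e.g.
#' from [event_rates()]); a many-realization ensemble plays the role of a
#' posterior sample of rate curves. Net diversification is always
#' speciation - extinction, recomputed rather than stored independently.
#'
#' @param grid A [time_grid()].
#' @param speciation,extinction Numeric matrices (realizations x bins) of
#'   non-negative rates; `NA` marks masked (zero-exposure) bins.
#' @param partition Label for the ecological partition the curves belong to.
#' @return An object of class `rate_ensemble` with elements `grid`,
#'   `speciation`, `extinction`, `net`, `partition`.
#' @export
rate_ensemble <- function(grid, speciation, extinction, partition = "all") {
  stopifnot(inherits(grid, "time_grid"))
  speciation <- rbind(speciation); extinction <- rbind(extinction)
  nb <- length(grid$mids)
  if (ncol(speciation) != nb || ncol(extinction) != nb)
    stop("rate matrices must have one column per grid bin (", nb, ")")
  if (!identical(dim(speciation), dim(extinction)))
    stop("speciation and extinction matrices must have the same shape")
  if (any(speciation < 0, na.rm = TRUE) || any(extinction < 0, na.rm = TRUE))
    stop("rates must be non-negative")
  structure(list(grid = grid, speciation = speciation, extinction = extinction,
                 net = speciation - extinction, partition = partition),
            class = "rate_ensemble")
}

#' @export
print.rate_ensemble <- function(x, ...) {
  cat(sprintf("Rate ensemble [%s]: %d realization(s) x %d bins (%g Myr), %g-0 Ma\n",
              x$partition, nrow(x$speciation), length(x$grid$mids),
              x$grid$spacing, max(x$grid$edges)))
  invisible(x)
}

#' Pick one rate matrix out of an ensemble
#'
#' @param ensemble A [rate_ensemble()].
#' @param rate_type `"speciation"`, `"extinction"` or `"net"`.
#' @return The realizations x bins matrix for that rate type.
#' @export
rate_matrix <- function(ensemble, rate_type = c("speciation", "extinction", "net")) {
  stopifnot(inherits(ensemble, "rate_ensemble"))
  ensemble[[match.arg(rate_type)]]
}

#' Noise model for posterior-style rate ensembles
#'
#' @param n_realizations Number of realizations to draw (>= 1). Full-scale
#'   analyses use 9001 to mirror a posterior sample of that size; tests use
#'   a few hundred.
#' @param sd_log_rate Marginal standard deviation of the log-rate
#'   perturbation field (dimensionless).
#' @param autocorrelation_length Correlation length of the field in Myr.
#' @param seed Optional integer seed.
#' @return A list of class `ensemble_noise`.
#' @export
ensemble_noise <- function(n_realizations = 9001L, sd_log_rate = 0.2,
                           autocorrelation_length = 5, seed = NULL) {
  if (n_realizations < 1) stop("'n_realizations' must be at least 1")
  if (sd_log_rate < 0) stop("'sd_log_rate' must be non-negative")
  if (autocorrelation_length <= 0) stop("'autocorrelation_length' must be positive")
  structure(list(n_realizations = as.integer(n_realizations),
                 sd_log_rate = sd_log_rate,
                 autocorrelation_length = autocorrelation_length,
                 seed = seed),
            class = "ensemble_noise")
}

#' Emulate a posterior sample of rate curves around mean curves
#'
#' Expands a single-realization ensemble (the mean speciation and extinction
#' curves) into `n_realizations` curves by multiplying each mean curve with
#' the exponential of a smooth, zero-mean, autocorrelated Gaussian field:
#' a stationary AR(1) on the grid with correlation `exp(-spacing / length)`
#' and marginal standard deviation `sd_log_rate`. The lognormal mean
#' correction `-sd^2/2` is applied so each realization has expectation equal
#' to the input curve. Speciation and extinction receive independent fields;
#' net diversification is recomputed per realization.
#'
#' @param mean_curves A [rate_ensemble()] with exactly one realization.
#'   Masked (`NA`) bins stay masked in every realization; bridge interior
#'   gaps first with [bridge_masked()] if a gap-free ensemble is needed.
#' @param noise An [ensemble_noise()].
#' @return A [rate_ensemble()] with `n_realizations` rows.
#' @examples
#' g <- time_grid(10, 0.5)
#' m <- rate_ensemble(g, rep(0.3, 20), rep(0.1, 20))
#' e <- emulate_posterior(m, ensemble_noise(100, 0.2, 2, seed = 1))
#' @export
emulate_posterior <- function(mean_curves, noise) {
  stopifnot(inherits(mean_curves, "rate_ensemble"), inherits(noise, "ensemble_noise"))
  if (nrow(mean_curves$speciation) != 1L)
    stop("'mean_curves' must hold exactly one realization")
  if (!is.null(noise$seed)) set.seed(noise$seed)
  nb <- length(mean_curves$grid$mids)
  nr <- noise$n_realizations
  phi <- exp(-mean_curves$grid$spacing / noise$autocorrelation_length)
  draw_field <- function() {
    g <- matrix(rnorm(nr * nb), nr, nb)
    if (nb > 1L) {
      innov_sd <- sqrt(1 - phi^2)
      for (j in 2:nb) g[, j] <- phi * g[, j - 1L] + innov_sd * g[, j]
    }
    noise$sd_log_rate * g
  }
  adj <- noise$sd_log_rate^2 / 2
  spec <- sweep(exp(draw_field() - adj), 2L, mean_curves$speciation[1L, ], `*`)
  ext <- sweep(exp(draw_field() - adj), 2L, mean_curves$extinction[1L, ], `*`)
  rate_ensemble(mean_curves$grid, spec, ext, mean_curves$partition)
}

#' Read / write rate ensembles as CSV
#'
#' On disk one matrix CSV holds one rate type: the first row is the grid bin
#' midpoints in Ma (descending) and each subsequent row one realization.
#'
#' @param x A realizations x bins matrix (e.g. from [rate_matrix()]).
#' @param grid The [time_grid()] the columns live on.
#' @param path File path.
#' @return `read_rate_matrix()` returns a list with `mids` and `values`
#'   (matrix); `write_rate_matrix()` invisibly returns `path`.
#' @export
write_rate_matrix <- function(x, grid, path) {
  stopifnot(inherits(grid, "time_grid"))
  m <- rbind(grid$mids, x)
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_matrix
#' @export
read_rate_matrix <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  list(mids = m[1L, ], values = m[-1L, , drop = FALSE])
}

# AR(1) field note: the first column is drawn at the stationary marginal
# already, so the field is stationary from the first bin.
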