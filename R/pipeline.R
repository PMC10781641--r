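#' Run the full driver analysis on one tree
#'
#' End-to-end orchestration: for each ecological partition, extract the
#' subtree, build the time grid, estimate rate curves ([event_rates()]),
#' bridge masked bins and smooth the curves, expand them into a
#' posterior-style ensemble ([emulate_posterior()]), compute the partition's
#' lineages-through-time as its biotic driver, align every driver, and run
#' DCCA with Wilcoxon summaries plus transfer entropy with block-bootstrap
#' significance for each rate type. Produces two tables mirroring a
#' driver-by-rate results table, plus a structured log of every masked-bin
#' bridge, range clamp and skipped partition.
#'
#' @param tree A rooted binary time-scaled `phylo`.
#' @param habitat Named character vector assigning every tip a habitat.
#' @param drivers Named list of [env_series()] driver proxies (e.g.
#'   `temperature`, `sea_level`). The partition's own LTT is added as the
#'   `LTT` driver unless `include_ltt` is `FALSE`.
#' @param partitions Partitions to analyse.
#' @param grid_spacing Bin width in Myr (default 0.1).
#' @param smooth_window,smooth_mode Arguments to [tukey_smooth()] for driver
#'   smoothing.
#' @param smooth_drivers Names of drivers to smooth before analysis; by
#'   default only `temperature` is smoothed (noise removal on the
#'   temperature proxy), sea level and LTT pass through unsmoothed.
#' @param rate_smooth_window Running-mean window applied to the event-count
#'   rate curves before ensemble emulation (they stand in for smooth
#'   posterior-mean curves); odd, in samples.
#' @param min_lineages Rate bins where the partition has fewer lineages than
#'   this are masked before analysis: with so little exposure the event-count
#'   estimator is dominated by Poisson noise (and its equal-width
#'   discretization for transfer entropy collapses). Leading masked bins are
#'   dropped by alignment; interior ones are bridged and logged.
#' @param te_sample_interval Sampling interval in Myr for the transfer
#'   entropy stage: both series are anti-alias smoothed over the interval
#'   and then decimated to it before discretization, so consecutive TE
#'   samples carry appreciable dynamics rather than sub-resolution
#'   increments of smooth curves. Default 1 Myr.
#' @param dcca_scale DCCA box length; default [default_dcca_scale()] of the
#'   aligned length.
#' @param te A [te_config()]; its `state_range` is clamped (and logged) when
#'   an aligned series is too short for the largest candidate.
#' @param noise An [ensemble_noise()]; its `n_realizations` sets the
#'   ensemble size (200 at test scale, 9001 to mirror a full posterior).
#' @param include_ltt Add the partition LTT as a biotic driver?
#' @param metadata Named list recorded in the manifest but unused (e.g.
#'   `sampling_fraction = 0.7`).
#' @param out_dir Optional directory: writes `correlations.tsv`, `te.tsv`,
#'   `manifest.txt` and `run.log`.
#' @param seed Integer seed; every stochastic stage derives its own seed
#'   from it, so a fixed seed gives identical reports.
#' @return A list of class `driver_report`: `correlations` (data frame, one
#'   row per partition x driver x rate type), `te` (same shape), `log`
#'   (character), `seed`.
#' @export
run_pipeline <- function(tree, habitat, drivers,
                         partitions = c("marine", "terrestrial",
                                        "freshwater", "non-marine"),
                         grid_spacing = 0.1,
                         smooth_window = 11L, smooth_mode = "mean",
                         smooth_drivers = "temperature",
                         rate_smooth_window = 5L,
                         min_lineages = 10L,
                         te_sample_interval = 1,
                         dcca_scale = NULL,
                         te = te_config(),
                         noise = ensemble_noise(200L, 0.2, 5),
                         include_ltt = TRUE,
                         metadata = list(),
                         out_dir = NULL, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!length(drivers) && !include_ltt) stop("at least one driver is required")
  if (length(drivers) && is.null(names(drivers)))
    stop("'drivers' must be a named list of env_series")
  missing <- setdiff(tree$tip.label, names(habitat))
  if (length(missing))
    stop("tips without a habitat assignment: ", paste(missing, collapse = ", "))
  log_lines <- character(0)
  note <- function(...) log_lines[[length(log_lines) + 1L]] <<- paste0(...)
  seed_counter <- 0L
  next_seed <- function() {
    if (is.null(seed)) return(NULL)
    seed_counter <<- seed_counter + 1L
    (seed + 7919L * seed_counter) %% 2147483647L
  }

  cor_rows <- list(); te_rows <- list()
  for (p in partitions) {
    sub <- tryCatch(extract_partition(tree, habitat, p), error = function(e) e)
    if (inherits(sub, "error")) {
      note("partition '", p, "' skipped: ", conditionMessage(sub))
      next
    }
    grid <- grid_for_tree(sub, grid_spacing)
    er <- event_rates(sub, grid, partition = p)
    n_lin <- ltt(sub, grid)
    low <- n_lin < min_lineages
    if (any(low))
      note("partition '", p, "': masked ", sum(low),
           " bins with fewer than ", min_lineages, " lineages")
    lam_raw <- er$speciation[1L, ]; lam_raw[low] <- NA_real_
    mu_raw <- er$extinction[1L, ]; mu_raw[low] <- NA_real_
    lam <- bridge_masked(lam_raw)
    mu <- bridge_masked(mu_raw)
    nb <- attr(lam, "n_bridged") + attr(mu, "n_bridged")
    if (nb > 0L) note("partition '", p, "': bridged ", nb, " masked rate bins")
    lam <- smooth_defined(as.numeric(lam), rate_smooth_window)
    mu <- smooth_defined(as.numeric(mu), rate_smooth_window)
    mean_ens <- rate_ensemble(grid, lam, mu, p)
    ens <- emulate_posterior(mean_ens, ensemble_noise(
      noise$n_realizations, noise$sd_log_rate, noise$autocorrelation_length,
      seed = next_seed()))

    driver_vals <- list()
    for (d in names(drivers)) {
      s <- drivers[[d]]
      if (d %in% smooth_drivers) s <- tukey_smooth(s, smooth_window, smooth_mode)
      v <- rep(NA_real_, length(grid$mids))
      inside <- grid$mids <= max(s$times) & grid$mids >= min(s$times)
      v[inside] <- approx(s$times, s$values, xout = grid$mids[inside])$y
      driver_vals[[d]] <- v
    }
    if (include_ltt) driver_vals[["LTT"]] <- as.numeric(ltt(sub, grid))

    state_cache <- new.env(parent = emptyenv())
    for (d in names(driver_vals)) {
      for (rt in c("speciation", "extinction", "net")) {
        mean_curve <- if (rt == "net") lam - mu else if (rt == "speciation") lam else mu
        pair <- tryCatch(
          align(driver_vals[[d]], grid, mean_curve, grid),
          error = function(e) e)
        if (inherits(pair, "error")) {
          note("partition '", p, "', driver '", d, "', ", rt, " skipped: ",
               conditionMessage(pair))
          next
        }
        h <- grid$spacing
        cols <- match(round(pair$mids / h * 2), round(grid$mids / h * 2))
        sub_ens <- rate_ensemble(grid_stub(pair$mids, h),
                                 ens$speciation[, cols, drop = FALSE],
                                 ens$extinction[, cols, drop = FALSE], p)
        scale <- dcca_scale %||% default_dcca_scale(length(pair$x))
        rho <- correlate_ensemble(sub_ens, pair$x, rt, scale)
        if (attr(rho, "n_failed") > 0L)
          note("partition '", p, "', driver '", d, "', ", rt, ": ",
               attr(rho, "n_failed"), " realization(s) dropped from DCCA")
        cor_rows[[length(cor_rows) + 1L]] <-
          summarize_correlations(rho, p, d, rt)

        stride <- max(1L, as.integer(round(te_sample_interval / grid$spacing)))
        te_rows[[length(te_rows) + 1L]] <-
          te_cell(pair, p, d, rt, te, stride, state_cache, note, next_seed())
      }
    }
  }
  if (!length(cor_rows)) stop("no partition produced any results")
  report <- structure(list(correlations = do.call(rbind, cor_rows),
                           te = do.call(rbind, te_rows),
                           log = log_lines, seed = seed,
                           metadata = metadata),
                      class = "driver_report")
  rownames(report$correlations) <- NULL
  rownames(report$te) <- NULL
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# anti-alias running mean over one stride, then take every stride-th sample
decimate <- function(v, stride) {
  if (stride <= 1L) return(v)
  w <- stride + 1L - (stride %% 2L)  # odd window covering the stride
  n <- length(v)
  if (n <= w) return(v)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  sm[seq(1L, n, by = stride)]
}

# one transfer-entropy table row; HMM state selection is cached per series
te_cell <- function(pair, p, d, rt, te, stride, state_cache, note, run_seed) {
  px <- decimate(pair$x, stride)
  py <- decimate(pair$y, stride)
  n <- length(px)
  kmax_feasible <- max(2L, n %/% 10L)
  range_used <- te$state_range[te$state_range <= kmax_feasible]
  if (length(range_used) < length(te$state_range))
    note("partition '", p, "', driver '", d, "': HMM state range clamped to 2..",
         max(range_used), " (aligned length ", n, ")")
  select_cached <- function(key, x) {
    if (!is.null(state_cache[[key]])) return(state_cache[[key]])
    k <- tryCatch(as.integer(select_states(x, range_used)),
                  error = function(e) NA_integer_)
    state_cache[[key]] <- k
    k
  }
  kx <- select_cached(paste0("x::", d), px)
  ky <- select_cached(paste0("y::", d, "::", rt), py)
  if (is.na(kx) || is.na(ky)) {
    note("partition '", p, "', driver '", d, "', ", rt,
         ": HMM state selection failed; TE skipped")
    return(data.frame(partition = p, driver = d, rate_type = rt,
                      te = NA_real_, effective_te = NA_real_, p = NA_real_,
                      chosen_states = NA_integer_, retained = FALSE))
  }
  k <- min(kx, ky)
  sx <- discretize_series(px, k)
  sy <- discretize_series(py, k)
  cfg <- te_config(te$state_range, te$markov_order, te$n_repeats,
                   te$n_bootstrap, te$block_length, seed = run_seed)
  res <- suppressWarnings(effective_te_and_p(sx, sy, cfg, chosen_states = k))
  data.frame(partition = p, driver = d, rate_type = rt,
             te = res$te_bits, effective_te = res$effective_te_bits,
             p = res$p_value, chosen_states = k, retained = res$retained)
}

# running mean over the defined (non-NA) segment, ends left masked
smooth_defined <- function(v, window) {
  ok <- which(!is.na(v))
  if (length(ok) < window || window < 3L) return(v)
  seg <- v[min(ok):max(ok)]
  if (anyNA(seg)) return(v)  # interior gaps should have been bridged
  n <- length(seg)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, seg))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  v[min(ok):max(ok)] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  v
}

# internal: a grid-like stub over an already-aligned midpoint subset
grid_stub <- function(mids, spacing) {
  structure(list(edges = c(mids + spacing / 2, min(mids) - spacing / 2),
                 mids = mids, spacing = spacing),
            class = "time_grid")
}

#' @export
print.driver_report <- function(x, ...) {
  cat("Driver analysis report:", nrow(x$correlations), "correlation rows,",
      nrow(x$te), "transfer-entropy rows\n")
  flagged <- x$correlations[x$correlations$reported, c("partition", "driver", "rate_type", "mean")]
  if (nrow(flagged)) {
    cat("Reported correlations (|mean rho| > 0.1):\n")
    print(flagged, row.names = FALSE)
  } else cat("No correlation passed the |mean rho| > 0.1 rule\n")
  invisible(x)
}

#' Write a driver report to disk
#'
#' Writes `correlations.tsv` and `te.tsv` (tab-separated result tables),
#' `manifest.txt` (key-value run metadata) and `run.log`.
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "driver_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$correlations, file.path(out_dir, "correlations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$te, file.path(out_dir, "te.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(list(package_version = as.character(utils::packageVersion("divdrivers")),
                 seed = report$seed %||% "none"),
            report$metadata)
  writeLines(paste(names(meta), vapply(meta, function(v) paste(format(v), collapse = " "), ""),
                   sep = "\t"),
             file.path(out_dir, "manifest.txt"))
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Sensitivity mode: re-run the analysis over several trees
#'
#' Applies [run_pipeline()] to each input tree (alternative topologies or
#' posterior draws with differing node dates) without ever averaging across
#' trees, then tabulates cross-tree consistency: for each partition, driver
#' and rate type, how many trees yielded a result, how many agreed on the
#' sign of the mean coefficient, and how many passed the reporting rule.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @param habitat Habitat vector covering the tips of every tree.
#' @param drivers Named list of [env_series()].
#' @param ... Passed to [run_pipeline()].
#' @param seed Base seed; tree `i` uses `seed + i`.
#' @return A list with `per_tree` (list of reports) and `consistency`
#'   (data frame).
#' @export
run_sensitivity <- function(trees, habitat, drivers, ..., seed = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  reports <- vector("list", length(trees))
  for (i in seq_along(trees))
    reports[[i]] <- run_pipeline(trees[[i]], habitat, drivers, ...,
                                 seed = if (is.null(seed)) NULL else seed + i)
  all_cor <- do.call(rbind, lapply(seq_along(reports), function(i)
    cbind(tree = i, reports[[i]]$correlations)))
  agg <- split(all_cor, list(all_cor$partition, all_cor$driver,
                             all_cor$rate_type), drop = TRUE)
  consistency <- do.call(rbind, lapply(agg, function(g) data.frame(
    partition = g$partition[1L], driver = g$driver[1L],
    rate_type = g$rate_type[1L], n_trees = nrow(g),
    n_positive = sum(g$mean > 0), n_reported = sum(g$reported),
    sign_consistent = length(unique(sign(g$mean))) == 1L)))
  rownames(consistency) <- NULL
  list(per_tree = reports, consistency = consistency)
}
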