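#' Even time grid in Ma
#'
#' Bins of even width running from an oldest edge down to the present (0 Ma).
#' Rate curves, lineage counts and aligned driver series all live on the bin
#' midpoints of such a grid. Following the fixed tie-break used throughout the
#' package, a bin covers the half-open age interval `(younger_edge, older_edge]`:
#' an event falling exactly on an edge belongs to the younger bin.
#'
#' @param oldest Oldest edge in Ma (> 0). Rounded up to a whole number of bins
#'   so that the youngest edge is exactly 0.
#' @param spacing Bin width in Myr (default 0.1, the resolution used for all
#'   shipped analyses).
#' @return An object of class `time_grid`: list with `edges` (descending,
#'   length `n_bins + 1`, last element 0), `mids` (descending bin midpoints)
#'   and `spacing`.
#' @examples
#' g <- time_grid(25, 0.5)
#' head(g$mids)
#' @export
time_grid <- function(oldest, spacing = 0.1) {
  if (!is.numeric(spacing) || spacing <= 0) stop("'spacing' must be positive")
  if (!is.numeric(oldest) || oldest <= 0) stop("'oldest' must be positive")
  n_bins <- ceiling(oldest / spacing - 1e-9)
  edges <- spacing * (n_bins:0)
  mids <- edges[-1L] + spacing / 2
  structure(list(edges = edges, mids = mids, spacing = spacing),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("Time grid: %d bins of %g Myr, %g-0 Ma\n",
              length(x$mids), x$spacing, max(x$edges)))
  invisible(x)
}

#' Grid spanning a tree
#'
#' Convenience constructor: a [time_grid()] whose oldest edge is the smallest
#' multiple of `spacing` at or above the tree's root age, so the grid spans
#' every branch.
#'
#' @param tree A time-scaled `phylo`.
#' @param spacing Bin width in Myr.
#' @return A [time_grid()].
#' @export
grid_for_tree <- function(tree, spacing = 0.1) {
  time_grid(max(node_ages(tree)), spacing)
}
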