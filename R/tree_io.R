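#' Node ages of a time-scaled tree
#'
#' Ages in Ma before present for every tip and internal node, reconstructed
#' from branch lengths as (maximum root-to-tip path length) minus
#' (root-to-node path length). Tips within `tol` of the present are snapped to
#' exactly 0 (extant calibration); every other tip is an extinct tip with a
#' strictly positive age.
#'
#' If the tree carries a `root_age` attribute (set by [extract_partition()]
#' when a pruned subtree retains no extant tip), ages are anchored to that
#' absolute root age instead of assuming the deepest tip is extant.
#'
#' @param tree A rooted `phylo` with branch lengths in Myr.
#' @param tol Snap tolerance in Ma for extant tips.
#' @return Numeric vector of ages indexed like ape's node numbering
#'   (tips `1..Ntip`, then internal nodes).
#' @export
node_ages <- function(tree, tol = 1e-9) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)
  root_age <- attr(tree, "root_age") %||% max(depths)
  ages <- root_age - depths
  tip <- seq_len(ape::Ntip(tree))
  ages[tip][abs(ages[tip]) < tol] <- 0
  ages
}

#' Read and write time-calibrated Newick trees
#'
#' `read_newick()` parses a rooted, fully bifurcating Newick tree whose branch
#' lengths are durations in Myr, and validates it for downstream use: it must
#' be binary (polytomies are refused rather than silently resolved) and carry
#' a branch length on every edge. Node ages are recovered with [node_ages()].
#' `write_newick()` writes a tree back out; a write/read round trip preserves
#' topology, tip labels and node ages to numerical precision.
#'
#' @param path File path.
#' @param tree A `phylo`.
#' @return `read_newick()` returns a `phylo`; `write_newick()` invisibly
#'   returns `path`.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_newick(tf)
#' node_ages(tr)   # root age 2, all tips extant at 0
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree in: ", path)
  validate_timetree(tree)
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_timetree <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths; a time-scaled tree is required")
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    stop("unsupported topology: a rooted, fully bifurcating tree is required ",
         "(polytomies are not resolved automatically)")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  invisible(tree)
}

#' Read and write tip-habitat tables
#'
#' The on-disk format is a two-column TSV (`taxon`, `habitat`) with habitats
#' among `marine`, `freshwater`, `terrestrial`.
#'
#' @param path File path.
#' @param habitat Named character vector (names = taxa, values = habitats).
#' @return `read_habitat()` returns a named character vector;
#'   `write_habitat()` invisibly returns `path`.
#' @export
read_habitat <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "habitat") %in% names(df)))
    stop("habitat table must have columns 'taxon' and 'habitat': ", path)
  hab <- check_habitat(structure(df$habitat, names = df$taxon))
  hab
}

#' @rdname read_habitat
#' @export
write_habitat <- function(habitat, path) {
  check_habitat(habitat)
  write.table(data.frame(taxon = names(habitat), habitat = unname(habitat)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

HABITATS <- c("marine", "freshwater", "terrestrial")

check_habitat <- function(habitat) {
  if (is.null(names(habitat)) || any(!nzchar(names(habitat))))
    stop("habitat vector must be named by taxon")
  bad <- setdiff(unique(habitat), HABITATS)
  if (length(bad))
    stop("unknown habitat states: ", paste(bad, collapse = ", "),
         " (expected ", paste(HABITATS, collapse = "/"), ")")
  habitat
}
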