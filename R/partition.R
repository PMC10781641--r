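#' Extract the subtree of an ecological partition
#'
#' Induces the subtree spanned by the tips assigned to a habitat partition,
#' suppressing the degree-2 nodes created by pruning while preserving the
#' ages of all retained nodes. Partitioning acts on tips only: a branch
#' belongs to a partition through its descendant tips, matching the practice
#' of classifying terminal taxa and colouring branches post hoc. The
#' `non-marine` partition is the union of terrestrial and freshwater tips,
#' used when non-marine taxa cannot be confidently split between those two
#' habitats.
#'
#' The returned subtree carries a `root_age` attribute holding the absolute
#' age (Ma) of its root in the full tree, so [node_ages()] stays calibrated
#' even when the partition retains no extant tip (an entirely extinct
#' ecology).
#'
#' @param tree A rooted binary time-scaled `phylo`.
#' @param habitat Named character vector mapping every tip label to
#'   `marine`, `freshwater` or `terrestrial`.
#' @param partition One of `"marine"`, `"freshwater"`, `"terrestrial"`,
#'   `"non-marine"`.
#' @return A `phylo` on the matching tips.
#' @examples
#' sim <- simulate_bd_tree(sim_config(15, 0.25, 0.05,
#'                                    habitat_transition_rate = 0.1, seed = 2))
#' tab <- table(sim$habitat)
#' @export
extract_partition <- function(tree, habitat,
                              partition = c("marine", "freshwater",
                                            "terrestrial", "non-marine")) {
  partition <- match.arg(partition)
  check_habitat(habitat)
  missing <- setdiff(tree$tip.label, names(habitat))
  if (length(missing))
    stop("tips without a habitat assignment: ", paste(missing, collapse = ", "))
  states <- if (partition == "non-marine") c("terrestrial", "freshwater") else partition
  keep <- tree$tip.label[habitat[tree$tip.label] %in% states]
  if (length(keep) < 2L)
    stop("partition '", partition, "' has ", length(keep),
         " tip(s); at least 2 are required")
  ages <- node_ages(tree)
  if (length(keep) == ape::Ntip(tree)) {
    attr(tree, "root_age") <- max(ages)
    return(tree)
  }
  mrca <- ape::getMRCA(tree, keep)
  sub <- ape::keep.tip(tree, keep)
  # keep.tip preserves path lengths among retained nodes; anchoring the new
  # root at its absolute age in the full tree keeps all ages calibrated.
  attr(sub, "root_age") <- ages[mrca]
  sub
}
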