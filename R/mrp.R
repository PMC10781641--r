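#' Non-trivial clades of a rooted source tree
#'
#' Returns the tip-label set of every internal non-root node. Trivial groups
#' (single tips, the full tip set) are excluded, so a fully bifurcating
#' `n`-tip tree yields exactly `n - 2` clades and a star tree yields none.
#'
#' @param tree A rooted `phylo` with at least 3 tips (polytomies allowed in
#'   source trees).
#' @return A list of character vectors (clade tip labels), in increasing
#'   node-number order.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' bipartitions(tr)   # list({A, B})
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 3L)
    stop("nothing to encode: a source tree needs at least 3 tips")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  internal <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), root)
  if (!length(internal)) return(list())  # star tree: no internal structure
  if (!ape::is.rooted(tree))
    stop("unrooted source tree; rooting is taken as given, not inferred")
  desc <- phangorn::Descendants(tree, internal, type = "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

#' Baum-Ragan MRP encoding of source trees
#'
#' Encodes the clades of one or more rooted source trees as binary
#' characters over the union of their taxa: for each clade, taxa inside the
#' clade score 1, taxa sampled in that source but outside the clade score 0,
#' and taxa absent from that source score `?`. A synthetic all-zero outgroup
#' row roots the matrix. Every column carries its source tree's weight
#' (upweighting a source, e.g. a molecular backbone, multiplies the weight
#' of all its columns). Duplicate clades from different sources are kept as
#' separate columns -- replication acts as an implicit weight, so no
#' deduplication is done.
#'
#' @param source_trees A list of rooted `phylo` objects (or a `multiPhylo`).
#' @param weights Positive integer weight per source tree (default all 1).
#' @param outgroup Label for the synthetic all-zero outgroup row.
#' @return An object of class `mrp_matrix`: list with `taxa` (row labels,
#'   outgroup first), `cells` (character matrix of `"0"`, `"1"`, `"?"`),
#'   `weights` (integer per column) and `provenance` (source index per
#'   column).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' m <- mrp_encode(list(tr))
#' m$cells
#' @export
mrp_encode <- function(source_trees, weights = NULL, outgroup = "MRP_outgroup") {
  if (inherits(source_trees, "phylo")) source_trees <- list(source_trees)
  n_src <- length(source_trees)
  if (n_src < 1L) stop("at least one source tree is required")
  if (is.null(weights)) weights <- rep(1L, n_src)
  if (length(weights) != n_src) stop("'weights' must align with the source trees")
  if (any(weights < 1) || any(weights != round(weights)))
    stop("'weights' must be positive integers")
  for (i in seq_len(n_src)) {
    labs <- source_trees[[i]]$tip.label
    if (anyDuplicated(labs))
      stop("duplicate tip labels in source ", i, ": ",
           paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  taxa <- unique(unlist(lapply(source_trees, `[[`, "tip.label")))
  if (outgroup %in% taxa) stop("outgroup label '", outgroup, "' clashes with a taxon")
  all_rows <- c(outgroup, taxa)
  cols <- list(); wts <- integer(0); prov <- integer(0)
  for (i in seq_len(n_src)) {
    src_taxa <- source_trees[[i]]$tip.label
    for (clade in bipartitions(source_trees[[i]])) {
      col <- rep("?", length(all_rows))
      names(col) <- all_rows
      col[src_taxa] <- "0"
      col[clade] <- "1"
      col[outgroup] <- "0"
      cols[[length(cols) + 1L]] <- col
      wts <- c(wts, as.integer(weights[i]))
      prov <- c(prov, i)
    }
  }
  if (!length(cols)) stop("nothing to encode: no source contributed a clade")
  cells <- do.call(cbind, cols)
  dimnames(cells) <- list(all_rows, NULL)
  structure(list(taxa = all_rows, cells = cells, weights = wts,
                 provenance = prov),
            class = "mrp_matrix")
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat(sprintf("MRP matrix: %d taxa (incl. outgroup) x %d characters, weights %s\n",
              length(x$taxa), ncol(x$cells),
              paste(sort(unique(x$weights)), collapse = "/")))
  invisible(x)
}

#' Write / read an MRP matrix in TNT (xread) format
#'
#' The TNT file holds the matrix in an `xread` block followed by `ccode`
#' lines assigning each character its weight (0-based character indices, one
#' line per distinct weight). `?` cells are preserved. [read_tnt()] parses
#' exactly this subset of the TNT grammar, so a write/read round trip
#' returns an identical matrix (provenance is not stored in the file; see
#' [write_mrp_provenance()]).
#'
#' @param m An [mrp_encode()] matrix.
#' @param path File path.
#' @return `write_tnt()` invisibly returns `path`; `read_tnt()` returns an
#'   `mrp_matrix` (with `provenance` set to `NA`).
#' @export
write_tnt <- function(m, path) {
  stopifnot(inherits(m, "mrp_matrix"))
  if (ncol(m$cells) == 0L) stop("nothing to write: empty matrix")
  if (any(grepl("[[:space:]]", m$taxa)))
    stop("taxon labels must not contain whitespace for TNT output")
  rows <- apply(m$cells, 1L, paste, collapse = "")
  lines <- c("xread", "'MRP matrix'",
             paste(ncol(m$cells), length(m$taxa)),
             paste(m$taxa, rows), ";")
  for (w in sort(unique(m$weights)))
    lines <- c(lines, paste0("ccode /", w, " ",
                             paste(which(m$weights == w) - 1L, collapse = " "), ";"))
  lines <- c(lines, "proc/;")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tnt
#' @export
read_tnt <- function(path) {
  lines <- trimws(readLines(path))
  hdr <- which(lines == "xread")
  if (!length(hdr)) stop("not a TNT xread file: ", path)
  i <- hdr[1L] + 1L
  while (grepl("^'", lines[i])) i <- i + 1L   # skip title
  dims <- as.integer(strsplit(lines[i], "[[:space:]]+")[[1L]])
  nchar_m <- dims[1L]; ntax <- dims[2L]
  tax_lines <- lines[(i + 1L):(i + ntax)]
  parts <- strsplit(tax_lines, "[[:space:]]+")
  taxa <- vapply(parts, `[[`, "", 1L)
  rows <- vapply(parts, `[[`, "", 2L)
  cells <- do.call(rbind, strsplit(rows, ""))
  dimnames(cells) <- list(taxa, NULL)
  if (ncol(cells) != nchar_m) stop("matrix width disagrees with header in ", path)
  weights <- rep(1L, nchar_m)
  for (ln in grep("^ccode", lines, value = TRUE)) {
    toks <- strsplit(sub(";$", "", ln), "[[:space:]]+")[[1L]]
    w <- as.integer(sub("^/", "", toks[2L]))
    idx <- as.integer(toks[-(1:2)]) + 1L
    weights[idx] <- w
  }
  structure(list(taxa = taxa, cells = cells, weights = weights,
                 provenance = rep(NA_integer_, nchar_m)),
            class = "mrp_matrix")
}

#' Write / read an MRP matrix in NEXUS format
#'
#' Writes a `DATA` block (`SYMBOLS="01"`, `MISSING=?`) and an `ASSUMPTIONS`
#' block with a `WTSET` assigning character weights (1-based indices,
#' grouped by weight). [read_nexus_mrp()] parses this subset back; a
#' write/read round trip returns an identical matrix.
#'
#' @param m An [mrp_encode()] matrix.
#' @param path File path.
#' @return `write_nexus()` invisibly returns `path`; `read_nexus_mrp()`
#'   returns an `mrp_matrix` (with `provenance` set to `NA`).
#' @export
write_nexus <- function(m, path) {
  stopifnot(inherits(m, "mrp_matrix"))
  if (ncol(m$cells) == 0L) stop("nothing to write: empty matrix")
  if (any(grepl("[[:space:]]", m$taxa)))
    stop("taxon labels must not contain whitespace for NEXUS output")
  rows <- apply(m$cells, 1L, paste, collapse = "")
  wt_groups <- vapply(sort(unique(m$weights)), function(w)
    paste0(w, ": ", paste(which(m$weights == w), collapse = " ")), "")
  lines <- c("#NEXUS",
             "BEGIN DATA;",
             paste0("DIMENSIONS NTAX=", length(m$taxa),
                    " NCHAR=", ncol(m$cells), ";"),
             "FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
             "MATRIX",
             paste(m$taxa, rows),
             ";", "END;",
             "BEGIN ASSUMPTIONS;",
             paste0("WTSET * mrp_weights = ", paste(wt_groups, collapse = ", "), ";"),
             "END;")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_nexus
#' @export
read_nexus_mrp <- function(path) {
  lines <- trimws(readLines(path))
  if (!length(lines) || toupper(lines[1L]) != "#NEXUS")
    stop("not a NEXUS file: ", path)
  mstart <- grep("^MATRIX$", lines, ignore.case = TRUE)[1L]
  mend <- which(lines == ";" & seq_along(lines) > mstart)[1L]
  parts <- strsplit(lines[(mstart + 1L):(mend - 1L)], "[[:space:]]+")
  taxa <- vapply(parts, `[[`, "", 1L)
  cells <- do.call(rbind, strsplit(vapply(parts, `[[`, "", 2L), ""))
  dimnames(cells) <- list(taxa, NULL)
  weights <- rep(1L, ncol(cells))
  wl <- grep("^WTSET", lines, ignore.case = TRUE, value = TRUE)
  if (length(wl)) {
    spec <- sub(";$", "", sub(".*=", "", wl[1L]))
    for (grp in strsplit(spec, ",")[[1L]]) {
      kv <- strsplit(trimws(grp), ":")[[1L]]
      idx <- as.integer(strsplit(trimws(kv[2L]), "[[:space:]]+")[[1L]])
      weights[idx] <- as.integer(trimws(kv[1L]))
    }
  }
  structure(list(taxa = taxa, cells = cells, weights = weights,
                 provenance = rep(NA_integer_, ncol(cells))),
            class = "mrp_matrix")
}

#' Provenance sidecar for an MRP matrix
#'
#' Writes a CSV mapping each character column to the index of the source
#' tree that contributed it.
#'
#' @param m An [mrp_encode()] matrix.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_mrp_provenance <- function(m, path) {
  stopifnot(inherits(m, "mrp_matrix"))
  write.csv(data.frame(character = seq_along(m$provenance),
                       source = m$provenance),
            path, row.names = FALSE)
  invisible(path)
}
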