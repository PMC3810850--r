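#' Parse a rooted Newick tree with branch lengths
#'
#' Reads a Newick string into an \code{ape} \code{"phylo"} object and
#' validates it for use with the PTP model: the tree must be rooted, every
#' non-root node must carry a finite, non-negative branch length (expected
#' substitutions per site), and tip labels must be unique and non-empty.
#' Multifurcations are preserved, not resolved.  Bracketed comments
#' (\code{[...]}) are stripped and quoted labels are tolerated.  A branch
#' length on the root itself, if present, is ignored (stored as
#' \code{root.edge} and treated as 0).
#'
#' @param text A Newick string ending in \code{";"}.  If the terminal
#'   semicolon is missing it is appended, so strings copied from figure
#'   captions parse as-is.
#' @param file Alternatively, path to a file containing one Newick tree.
#' @return A validated object of class \code{"phylo"}.
#' @examples
#' tr <- read_newick("((a:1,b:1):0.5,c:2);")
#' ape::Ntip(tr)
#' @seealso [write_newick()], [path_lengths()], [prune_taxa()]
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file))
    stop("provide either `text` or `file`")
  if (is.null(text)) {
    if (!file.exists(file))
      stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^]]*\\]", "", text)       # Newick comments
  if (!grepl("'", text, fixed = TRUE))        # keep quoted labels intact
    text <- gsub("[[:space:]]", "", text)
  text <- sub("[[:space:]]+$", "", text)
  if (!nzchar(text))
    stop("parse error at offset 1: empty Newick string")
  if (!endsWith(text, ";")) text <- paste0(text, ";")
  .check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error   = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("parse error at offset 1: not a valid Newick tree")
  validate_tree(tree)
}

# Cheap structural scan so syntax errors can name a character offset.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("parse error at offset ", i, ": unmatched ')'")
    }
    if (ch == ";" && depth > 0L)
      stop("parse error at offset ", i, ": ", depth, " unclosed '('")
  }
  if (depth != 0L)
    stop("parse error at offset ", length(chars), ": ", depth, " unclosed '('")
  invisible(TRUE)
}

#' Validate a rooted tree for PTP analysis
#'
#' Checks the invariants the likelihood machinery relies on: a single root,
#' unique non-empty tip labels, and a finite branch length \eqn{\ge 0} on
#' every non-root edge.
#'
#' @param tree A \code{"phylo"} object.
#' @return The tree, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("`tree` must be a \"phylo\" object")
  if (is.null(tree$tip.label) || length(tree$tip.label) < 2L)
    stop("tree must have at least 2 tips")
  if (anyNA(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("validation error: empty tip label")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("validation error: duplicate tip label(s): ",
         paste(dup, collapse = ", "))
  # the outermost Newick node is the root by designation; a basal
  # multifurcation is legal (we never re-root)
  root_candidates <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  if (length(root_candidates) != 1L)
    stop("validation error: tree does not have a unique root")
  if (is.null(tree$edge.length))
    stop("validation error: tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("validation error: missing or non-finite branch length on a non-root edge")
  if (any(tree$edge.length < 0))
    stop("validation error: negative branch length (min = ",
         format(min(tree$edge.length)), ")")
  if (nrow(tree$edge) != tree$Nnode + length(tree$tip.label) - 1L)
    stop("validation error: edge count != node count - 1")
  invisible(tree)
}

#' Write a tree as a Newick string
#'
#' @param tree A \code{"phylo"} object.
#' @param file Optional path; when given the string is written there and
#'   returned invisibly.
#' @return The Newick string (round-trips through [read_newick()] to an
#'   isomorphic tree with identical labels and branch lengths).
#' @export
write_newick <- function(tree, file = NULL) {
  validate_tree(tree)
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Root-to-tip edge lengths
#'
#' Returns the branch lengths along the path from the root down to one tip,
#' in root-to-tip order.  Cumulative sums of this vector are the substitution
#' depths of the successive branching events on that path, the quantity the
#' Poisson-process view of the tree is built on.
#'
#' @param tree A \code{"phylo"} object.
#' @param leaf A tip label.
#' @return Numeric vector of edge lengths, ordered root to tip.
#' @examples
#' tr <- ptp_example_tree()
#' path_lengths(tr, "d1")          # 0.15 0.10 0.01
#' cumsum(path_lengths(tr, "d1"))  # branching-event depths
#' @export
path_lengths <- function(tree, leaf) {
  validate_tree(tree)
  tip <- match(leaf, tree$tip.label)
  if (is.na(tip))
    stop("unknown leaf label: ", leaf)
  parent <- .parent_vec(tree)
  elen <- .edge_len_by_child(tree)
  root <- ape::Ntip(tree) + 1L
  path <- numeric(0)
  node <- tip
  while (node != root) {
    path <- c(elen[node], path)
    node <- parent[node]
  }
  path
}

#' Remove tips from a tree
#'
#' Drops the listed tips; internal nodes left with a single child are
#' suppressed and their two incident branch lengths summed, so the
#' root-to-tip path length of every surviving tip is unchanged.  A root left
#' with one child is collapsed into that child.  Typical use is removing
#' outgroup taxa before delimitation.
#'
#' @param tree A \code{"phylo"} object.
#' @param labels Character vector of tip labels to remove (may be empty,
#'   in which case the tree is returned unchanged).  Must be a proper subset
#'   of the tips, and at least 2 tips must survive.
#' @return The pruned, validated \code{"phylo"} object.
#' @export
prune_taxa <- function(tree, labels) {
  validate_tree(tree)
  labels <- unique(as.character(labels))
  if (length(labels) == 0L)
    return(tree)
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown))
    stop("labels not in tree: ", paste(unknown, collapse = ", "))
  if (length(tree$tip.label) - length(labels) < 2L)
    stop("pruning would leave fewer than 2 tips")
  out <- ape::drop.tip(tree, labels, collapse.singles = TRUE)
  out$root.edge <- NULL
  validate_tree(out)
  out
}

#' The seven-tip worked example tree
#'
#' A small rooted tree used throughout the documentation and tests: four
#' species, one represented by a single individual (\code{C}) and three by
#' two individuals each (\code{d1,d2}, \code{e1,e2}, \code{f1,f2}).  Its
#' among-species branches are roughly an order of magnitude longer than its
#' within-species branches, so the two-rate model separates them cleanly.
#'
#' @return A \code{"phylo"} object with 7 tips, 6 internal nodes and 12 edges.
#' @examples
#' delimit(ptp_example_tree())
#' @export
ptp_example_tree <- function() {
  read_newick(paste0(
    "((C:0.14,(d1:0.01,d2:0.02)D:0.1)A:0.15,",
    "((e1:0.015,e2:0.014)E:0.1,(f1:0.03,f2:0.02)F:0.12)B:0.11)R;"
  ))
}

## ---- internal phylo helpers -------------------------------------------------

.parent_vec <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent
}

.children_list <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  kids
}

# branch length indexed by child node id
.edge_len_by_child <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  elen <- rep(NA_real_, n)
  elen[tree$edge[, 2L]] <- tree$edge.length
  elen
}

# node ids in postorder (children before parents); each non-root node appears
# exactly once in the child column of the postorder edge matrix
.postorder_nodes <- function(tree) {
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  c(eo[, 2L], ape::Ntip(tree) + 1L)
}
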