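#' Prune a tree down to a set of tips
#'
#' Keeps exactly the requested tips.  Internal nodes left with a single
#' child are suppressed and their two incident edge lengths summed; an
#' absent (`NA`) length summed with anything remains absent.
#'
#' @param tree a `"phylo"` object.
#' @param keep character vector of tip labels to retain (non-empty, all
#'   present in the tree).
#' @return the pruned `"phylo"` object.
#' @examples
#' prune_tips(parse_newick("((A:1,B:1):1,C:2);"), c("A", "C"))
#' @export
prune_tips <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- as.character(keep)
  if (length(keep) == 0L) stop("'keep' must contain at least one tip label")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0L)
    stop("tip label(s) not in tree: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keep)) keep <- unique(keep)
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) return(.prune_to_one(tree, keep))
  out <- ape::keep.tip(tree, keep)
  if (!is.null(out$edge.length)) {
    out$edge.length[is.nan(out$edge.length)] <- NA_real_
    if (all(is.na(out$edge.length))) out$edge.length <- NULL
  }
  out
}

# single-surviving-tip case: the whole root path collapses onto one edge
.prune_to_one <- function(tree, keep) {
  v <- match(keep, tree$tip.label)
  par <- .parent_vec(tree)
  el <- tree$edge.length
  len_of <- rep(NA_real_, length(tree$tip.label) + tree$Nnode)
  if (!is.null(el)) len_of[tree$edge[, 2L]] <- el
  total <- 0
  while (!is.na(par[v])) { total <- total + len_of[v]; v <- par[v] }
  out <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = keep, Nnode = 1L)
  if (!is.na(total)) out$edge.length <- total
  class(out) <- "phylo"
  attr(out, "order") <- "cladewise"
  out
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree a `"phylo"` object.
#' @param tips character vector of tip labels (non-empty).  A singleton set
#'   returns the tip's own node number.
#' @return the node number of the MRCA.
#' @export
tree_mrca <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  tips <- unique(as.character(tips))
  if (length(tips) == 0L) stop("'tips' must be non-empty")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0L)
    stop("tip label(s) not in tree: ", paste(unknown, collapse = ", "))
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

#' Total branch length of a tree
#'
#' Sum of all non-root edge lengths.  The root edge (`$root.edge`), if
#' present, is excluded.  Under fair-proportion apportionment this total
#' equals the sum of all tip ED scores, which [fair_proportion()] exploits
#' as a conservation check.
#'
#' @param tree a `"phylo"` object with every edge length present.
#' @return a non-negative number.
#' @export
total_branch_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length))
    stop("absent branch length on ", sum(is.na(tree$edge.length)), " edge(s)")
  sum(tree$edge.length)
}
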