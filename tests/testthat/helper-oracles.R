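# Independent oracles, deliberately naive: explicit per-tip root-path
# enumeration with per-edge descendant counting by exhaustive subtree
# listing.  No code shared with the package's linear-time implementation.
fp_bruteforce <- function(tree) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  el <- tree$edge.length
  children_of <- function(v) edge[edge[, 1] == v, 2]
  tips_under <- function(v) {
    if (v <= n) return(v)
    unlist(lapply(children_of(v), tips_under))
  }
  parent_of <- function(v) {
    p <- edge[edge[, 2] == v, 1]
    if (length(p) == 0) NA_integer_ else p
  }
  ed <- stats::setNames(numeric(n), tree$tip.label)
  for (tip in seq_len(n)) {
    v <- tip
    while (!is.na(parent_of(v))) {
      i <- which(edge[, 2] == v)
      ed[tip] <- ed[tip] + el[i] / length(tips_under(v))
      v <- parent_of(v)
    }
  }
  ed
}

# label-sorted bracket representation: equal iff same unordered topology
canon_topology <- function(tree) {
  n <- length(tree$tip.label)
  kids <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  rec <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    paste0("(", paste(sort(vapply(kids(v), rec, "")), collapse = ","), ")")
  }
  rec(n + 1L)
}

# hand Pearson R^2, no stats::cor
r2_byhand <- function(x, y) {
  cx <- x - mean(x); cy <- y - mean(y)
  (sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2)))^2
}

expect_same_tree <- function(a, b) {
  expect_true(isTRUE(all.equal.phylo(a, b, use.tip.label = TRUE)))
}
all.equal.phylo <- ape::all.equal.phylo
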