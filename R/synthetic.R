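#' Random rooted tree
#'
#' A uniformly distributed random labeled binary topology (via
#' [ape::rtopology()]) with i.i.d. branch lengths.  Three branch-length
#' laws are offered: `"uniform"` (U(0,1), the conventional random-tree
#' baseline), `"exponential"` (rate 1), and `"heavy_tail"` (lognormal,
#' meanlog 0, sdlog 1.5).  The heavy-tailed law concentrates much of the
#' tree's length on a few branches, which is what makes fair-proportion ED
#' initially resilient to tip loss on realistic (e.g. lexical) trees —
#' uniform-length random trees show no such resilience.
#'
#' @param n_tips number of tips (>= 3).
#' @param branch_law `"uniform"`, `"exponential"` or `"heavy_tail"`.
#' @param seed optional integer seed.
#' @return a binary `"phylo"` with tips `t1..tn` and `2 * n_tips - 2`
#'   non-root edges.
#' @export
random_tree <- function(n_tips, branch_law = c("uniform", "exponential",
                                               "heavy_tail"),
                        seed = NULL) {
  branch_law <- match.arg(branch_law)
  if (n_tips < 3L) stop("'n_tips' must be >= 3")
  .with_seed(seed, {
    tr <- ape::rtopology(n_tips, rooted = TRUE, br = NULL)
    m <- nrow(tr$edge)
    tr$edge.length <- switch(branch_law,
      uniform = stats::runif(m),
      exponential = stats::rexp(m),
      heavy_tail = stats::rlnorm(m, meanlog = 0, sdlog = 1.5))
    tr
  })
}

#' Derive a classification from a tree
#'
#' Names internal nodes of the tree as classification groups and gives
#' each tip the lineage formed by the family (root) plus its named
#' ancestors, outermost first.  Two cuts control which nodes are named:
#'
#' * `depth`: only nodes within the first `depth` internal levels below
#'   the root (a fixed-level cut);
#' * `min_size`: only nodes whose clade holds at least `min_size` tips.
#'
#' A pure level cut emulates a shallow classification; on strongly
#' unbalanced trees it leaves most taxa inside one giant terminal group.
#' Curated taxonomies instead resolve to small subgroups everywhere in the
#' tree, at varying depth — which is what the size cut (e.g.
#' `min_size = 5`, `depth = Inf`) reproduces.  By construction every group
#' is a clade of the tree, so the classification is perfectly consistent
#' with the topology — the best-case analogue of a curated taxonomy.
#'
#' @param tree a `"phylo"`.
#' @param depth number of internal levels to name (>= 1); `Inf` for no
#'   level cut.
#' @param min_size smallest clade named as a group (default 1, no size
#'   cut).
#' @param family name of the outermost group.
#' @return a `"classification"` covering all tips.
#' @export
classification_from_tree <- function(tree, depth = 1L, min_size = 1L,
                                     family = "Family") {
  stopifnot(inherits(tree, "phylo"))
  if (depth < 1L) stop("'depth' must be >= 1")
  if (min_size < 1L) stop("'min_size' must be >= 1")
  n <- length(tree$tip.label)
  par <- .parent_vec(tree)
  root <- n + 1L
  node_depth <- rep(NA_real_, n + tree$Nnode)
  node_depth[root] <- 0
  clade_size <- c(rep(1, n), rep(0, tree$Nnode))
  tr <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(tr$edge)))
    clade_size[tr$edge[i, 1L]] <- clade_size[tr$edge[i, 1L]] +
      clade_size[tr$edge[i, 2L]]
  for (i in rev(seq_len(nrow(tr$edge))))
    node_depth[tr$edge[i, 2L]] <- node_depth[tr$edge[i, 1L]] + 1
  named <- function(v) v != root && node_depth[v] <= depth &&
    clade_size[v] >= min_size
  lineages <- lapply(seq_len(n), function(tip) {
    path <- integer(0)
    v <- par[tip]
    while (!is.na(v)) { path <- c(v, path); v <- par[v] }
    grp <- path[vapply(path, named, logical(1))]
    c(family, if (length(grp) > 0L) paste0("G", grp))
  })
  classification(tree$tip.label, lineages)
}

#' Random endangerment statuses
#'
#' Draws status names from the default GE scale.  The default weights make
#' roughly 32% of taxa threatened (GE >= 2), 13% endangered (GE >= 3) and
#' 7% moribund or worse — the mix observed across a large, partly
#' endangered language family.
#'
#' @param taxa character vector of taxon ids.
#' @param weights named numeric vector of sampling weights over status
#'   names (needs not sum to 1).
#' @param seed optional integer seed.
#' @return named character vector taxon -> status.
#' @export
random_statuses <- function(taxa,
                            weights = c("nearly extinct" = 0.04,
                                        "moribund" = 0.03,
                                        "shifting" = 0.06,
                                        "threatened" = 0.19,
                                        "vigorous" = 0.30,
                                        "developing" = 0.15,
                                        "educational" = 0.08,
                                        "wider communication" = 0.05,
                                        "provincial" = 0.05,
                                        "national" = 0.05),
                            seed = NULL) {
  bad <- setdiff(names(weights), ge_scale_default()$status)
  if (length(bad) > 0L)
    stop("unknown status in 'weights': ", paste(bad, collapse = ", "))
  .with_seed(seed, stats::setNames(
    sample(names(weights), length(taxa), replace = TRUE,
           prob = weights / sum(weights)),
    taxa))
}

#' Generate a complete synthetic study scenario
#'
#' Emulates the study setting of a measured backbone tree plus an external
#' classification: a "truth" tree is simulated, a classification is derived
#' from its topology, a backbone is obtained by keeping a uniform random
#' fraction of tips, and every taxon gets a random endangerment status.
#'
#' @param n_tips tips in the truth tree.
#' @param sampling_fraction fraction of tips kept on the backbone, in
#'   `(0, 1]`; must keep at least 3 tips.
#' @param classification_depth internal levels named by the
#'   classification, see [classification_from_tree()]; the default (no
#'   level cut) defers to the size cut.
#' @param classification_min_size smallest clade named as a group; the
#'   default of 5 yields terminal subgroups of a handful of taxa, the
#'   granularity of a curated taxonomy.
#' @param branch_law passed to [random_tree()]; the heavy-tailed default
#'   mimics measured lexical trees.
#' @param status_weights passed to [random_statuses()].
#' @param seed optional integer seed making the whole scenario
#'   reproducible.
#' @return an object of class `"synthetic_scenario"`: list with
#'   `truth_tree`, `backbone`, `classification`, `statuses`, `seed`.
#' @export
make_scenario <- function(n_tips, sampling_fraction = 0.5,
                          classification_depth = Inf,
                          classification_min_size = 5L,
                          branch_law = "heavy_tail",
                          status_weights = NULL, seed = NULL) {
  if (sampling_fraction <= 0 || sampling_fraction > 1)
    stop("'sampling_fraction' must be in (0, 1]")
  n_keep <- round(sampling_fraction * n_tips)
  if (n_keep < 3L) stop("'sampling_fraction' keeps fewer than 3 tips")
  .with_seed(seed, {
    truth <- random_tree(n_tips, branch_law = branch_law)
    cl <- classification_from_tree(truth, depth = classification_depth,
                                   min_size = classification_min_size)
    backbone <- if (n_keep == n_tips) truth else
      prune_tips(truth, sample(truth$tip.label, n_keep))
    statuses <- if (is.null(status_weights)) random_statuses(truth$tip.label)
                else random_statuses(truth$tip.label, weights = status_weights)
    structure(list(truth_tree = truth, backbone = backbone,
                   classification = cl, statuses = statuses, seed = seed),
              class = "synthetic_scenario")
  })
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic scenario:", length(x$truth_tree$tip.label), "taxa,",
      length(x$backbone$tip.label), "on the backbone\n")
  invisible(x)
}
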