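#' Fair-proportion evolutionary distinctiveness
#'
#' Apportions every branch of the tree equally among the tips descending
#' from it: a tip's ED is the sum, over the edges on its root-to-tip path,
#' of the edge length divided by the number of tips below that edge.  The
#' scores therefore sum exactly to the tree's total branch length, which is
#' the natural conservation check on the computation.  The root edge, if
#' any, is excluded: the root has no ancestral lineage to apportion.
#'
#' ED is in the branch-length units of the input tree (for a lexical
#' language tree, expected cognate replacements).
#'
#' Computed in one postorder pass (descendant-tip counts) and one preorder
#' pass (accumulated per-edge shares), so the cost is linear in tree size.
#'
#' @param tree a `"phylo"` object; every non-root edge length must be
#'   present and non-negative.  Polytomies are fine.
#' @return named numeric vector of ED scores, one per tip.
#' @examples
#' fair_proportion(parse_newick("((A:1,B:1):1,C:2);"))  # A 1.5, B 1.5, C 2
#' @export
fair_proportion <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (is.null(tree$edge.length))
    stop("fair_proportion needs branch lengths, but the tree has none")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1L]
    stop("absent branch length on the edge to node ", tree$edge[bad, 2L])
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length(s)")
  if (n == 1L)
    return(stats::setNames(sum(tree$edge.length), tree$tip.label))
  tr <- ape::reorder.phylo(tree, "postorder")
  N <- n + tr$Nnode
  e1 <- tr$edge[, 1L]; e2 <- tr$edge[, 2L]; el <- tr$edge.length
  ntips_below <- c(rep(1, n), rep(0, tr$Nnode))
  for (i in seq_along(e1))
    ntips_below[e1[i]] <- ntips_below[e1[i]] + ntips_below[e2[i]]
  acc <- numeric(N)
  for (i in rev(seq_along(e1)))            # reverse postorder = preorder
    acc[e2[i]] <- acc[e1[i]] + el[i] / ntips_below[e2[i]]
  stats::setNames(acc[seq_len(n)], tr$tip.label)
}

#' Relative evolutionary distinctiveness
#'
#' Divides ED scores by the arithmetic mean ED over a normalization set, so
#' that the mean relative score over that set is exactly 1 and a taxon with
#' ED_R of 2 is twice as distinct as the average taxon.  Useful when branch
#' lengths are not in interpretable absolute units.
#'
#' @param ed named numeric vector of ED scores (e.g. [fair_proportion()]).
#' @param normalization_set character vector of taxa over which to average;
#'   defaults to all of `ed`.  Scores are returned for this set only.
#' @return named numeric vector of ED_R values with mean 1.
#' @export
relative_ed <- function(ed, normalization_set = names(ed)) {
  if (is.null(names(ed))) stop("'ed' must be a named vector")
  unknown <- setdiff(normalization_set, names(ed))
  if (length(unknown) > 0L)
    stop("taxa not in 'ed': ", paste(unknown, collapse = ", "))
  x <- ed[normalization_set]
  m <- mean(x)
  if (!is.finite(m) || m <= 0)
    stop("mean ED over the normalization set must be positive")
  x / m
}

#' EDGE score
#'
#' Combines distinctiveness and endangerment.  The `"original"` variant is
#' `ln(1 + ED) + GE * ln(2)`; with GE on a doubling scale this term equals
#' `ln(2^GE)`, so EDGE rises one `ln 2` per doubling of extinction
#' probability.  The `"modified"` variant, designed for relative ED, divides
#' the endangerment weight by 4 (the maximum GE of the default scale):
#' `ln(1 + ED_R) + GE/4 * ln(2)`, so that distinctiveness and threat
#' contribute on comparable scales and endangerment alone can add at most
#' `ln 2`.
#'
#' @param distinctiveness non-negative numeric vector: raw ED for the
#'   original variant, ED_R for the modified variant.
#' @param ge non-negative numeric vector of GE values.
#' @param variant `"modified"` (default) or `"original"`.
#' @return numeric vector of EDGE scores.
#' @examples
#' edge_score(3.36, 4)            # ~2.17
#' edge_score(0.16, 1/32)         # ~0.15
#' @export
edge_score <- function(distinctiveness, ge, variant = c("modified", "original")) {
  variant <- match.arg(variant)
  if (any(distinctiveness < 0, na.rm = TRUE))
    stop("'distinctiveness' must be non-negative")
  if (any(ge < 0, na.rm = TRUE))
    stop("'ge' must be non-negative")
  w <- if (variant == "modified") 1 / 4 else 1
  log1p(distinctiveness) + w * ge * log(2)
}

#' Per-taxon ED / GE / EDGE score table
#'
#' The end product of the prioritization: one row per reported taxon with
#' its ED (fair proportion on `tree`), ED_R (normalized over
#' `normalization_set`), GE, EDGE and ordinal rank (1 = highest EDGE; ties
#' broken by ED_R descending, then label ascending).
#'
#' ED is computed on the full tree — including any grafted tips, which is
#' how grafting corrects the scores — but rows are reported for the
#' normalization set only unless `include_all` is set; taxa outside the
#' normalization set (the grafted ones) have no measured branch lengths, so
#' their own scores are flagged `grafted` and are not normally reported.
#'
#' @param tree a `"phylo"` with branch lengths.
#' @param statuses named character vector taxon -> endangerment status.
#' @param scale GE scale, see [ge_scale_default()].
#' @param normalization_set taxa over which ED_R is normalized and which are
#'   reported; defaults to all tips.
#' @param variant EDGE variant, see [edge_score()]; the modified variant
#'   pairs with ED_R, the original with raw ED.
#' @param include_all also report taxa outside the normalization set
#'   (flagged `grafted = TRUE`).
#' @return a data frame with columns `taxon`, `ED`, `ED_R`, `GE`, `EDGE`,
#'   `rank`, `grafted`, sorted by EDGE descending.
#' @export
rank_table <- function(tree, statuses, scale = ge_scale_default(),
                       normalization_set = NULL,
                       variant = c("modified", "original"),
                       include_all = FALSE) {
  variant <- match.arg(variant)
  ed <- fair_proportion(tree)
  if (is.null(normalization_set)) normalization_set <- names(ed)
  unknown <- setdiff(normalization_set, names(ed))
  if (length(unknown) > 0L)
    stop("normalization set taxa not in tree: ",
         paste(unknown, collapse = ", "))
  report <- if (include_all) names(ed) else normalization_set
  no_status <- setdiff(report, names(statuses))
  if (length(no_status) > 0L)
    stop("no endangerment status for: ",
         paste(utils::head(no_status, 10L), collapse = ", "))
  mean_ed <- mean(ed[normalization_set])
  if (mean_ed <= 0) stop("mean ED over the normalization set must be positive")
  ed_r <- ed[report] / mean_ed
  ge <- ge_from_status(statuses[report], scale)
  dist <- if (variant == "modified") ed_r else ed[report]
  edge <- edge_score(dist, ge, variant)
  tab <- data.frame(taxon = report, ED = unname(ed[report]),
                    ED_R = unname(ed_r), GE = ge, EDGE = unname(edge),
                    grafted = !(report %in% normalization_set),
                    stringsAsFactors = FALSE)
  ord <- order(-tab$EDGE, -tab$ED_R, tab$taxon, method = "radix")
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab[, c("taxon", "ED", "ED_R", "GE", "EDGE", "rank", "grafted")]
}

#' Deduplicate tips sharing an identifier code
#'
#' Where several tips (e.g. dialects) share one code (e.g. an ISO 639-3
#' code), keeps only the tip with the greatest fair-proportion ED on the
#' input tree (ties broken by label order) and prunes the rest.
#'
#' @param tree a `"phylo"` with branch lengths.
#' @param code named character vector tip label -> code, covering all tips.
#' @return the pruned `"phylo"`; its tip count equals the number of
#'   distinct codes.
#' @export
dedupe_by_code <- function(tree, code) {
  stopifnot(inherits(tree, "phylo"))
  no_code <- setdiff(tree$tip.label, names(code))
  if (length(no_code) > 0L)
    stop("no code for tip(s): ", paste(no_code, collapse = ", "))
  ed <- fair_proportion(tree)
  keep <- vapply(split(names(ed), unname(code[names(ed)])), function(tips) {
    tips <- tips[order(tips, method = "radix")]
    tips[which.max(ed[tips])]
  }, "")
  prune_tips(tree, unname(keep))
}
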