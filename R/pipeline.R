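#' End-to-end EDGE scoring pipeline
#'
#' The full workflow from a measured tree to a ranked score table:
#' optional dialect deduplication by shared code ([dedupe_by_code()]),
#' optional grafting of classification taxa missing from the tree
#' ([graft_missing()]), fair-proportion ED on the resulting tree, ED_R
#' normalized over the measured (backbone) tips, GE from statuses, EDGE
#' and ordinal ranks ([rank_table()]).
#'
#' Grafted taxa have no measured branch lengths, so by default their rows
#' are not reported (their presence still corrects the backbone taxa's
#' scores); set `include_grafted` to expose them, flagged.
#'
#' @param tree a `"phylo"` with branch lengths (the backbone).
#' @param statuses named character vector taxon -> endangerment status,
#'   covering all reported taxa.
#' @param classification optional `"classification"`; enables grafting.
#' @param codes optional named character vector tip -> code; enables
#'   deduplication (run before grafting).
#' @param scale GE scale.
#' @param variant EDGE variant, see [edge_score()].
#' @param include_grafted report grafted taxa too.
#' @return an object of class `"edge_scores"`: list with `scores` (the
#'   table), `tree` (the scored tree), `graft_report`, `warnings`, and
#'   counts `n_backbone`, `n_grafted`, `n_threatened`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' st <- c(A = "vigorous", B = "threatened", C = "nearly extinct")
#' score_languages(tr, st)$scores
#' @export
score_languages <- function(tree, statuses, classification = NULL,
                            codes = NULL, scale = ge_scale_default(),
                            variant = c("modified", "original"),
                            include_grafted = FALSE) {
  variant <- match.arg(variant)
  if (!is.null(codes)) tree <- dedupe_by_code(tree, codes)
  backbone_tips <- tree$tip.label
  graft_report <- NULL
  warnings <- character(0)
  if (!is.null(classification)) {
    g <- graft_missing(tree, classification)
    tree <- g$tree
    graft_report <- g$report
    warnings <- g$warnings
    for (w in warnings) warning(w, call. = FALSE)
  }
  scores <- rank_table(tree, statuses, scale = scale,
                       normalization_set = backbone_tips,
                       variant = variant, include_all = include_grafted)
  structure(list(scores = scores, tree = tree, graft_report = graft_report,
                 warnings = warnings,
                 n_backbone = length(backbone_tips),
                 n_grafted = length(tree$tip.label) - length(backbone_tips),
                 n_threatened = sum(scores$GE >= 2 & !scores$grafted)),
            class = "edge_scores")
}

#' @export
print.edge_scores <- function(x, n = 6L, ...) {
  cat("EDGE scores for", x$n_backbone, "measured taxa")
  if (x$n_grafted > 0L) cat(" (", x$n_grafted, " taxa grafted in)", sep = "")
  cat("; ", x$n_threatened, " threatened (GE >= 2)\n", sep = "")
  top <- utils::head(x$scores, n)
  top$ED <- round(top$ED, 4); top$ED_R <- round(top$ED_R, 2)
  top$EDGE <- round(top$EDGE, 4)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Write a score table as CSV
#'
#' Full double precision; an audit header records package version (and
#' seed/command when given).
#'
#' @param x an `"edge_scores"` object or a score-table data frame.
#' @param file output path (UTF-8).
#' @param seed,command optional audit fields for the header.
#' @return `file`, invisibly.
#' @export
write_scores_csv <- function(x, file, seed = NULL, command = NULL) {
  df <- if (inherits(x, "edge_scores")) x$scores else x
  .write_csv_with_header(df, file, seed = seed, command = command)
}
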