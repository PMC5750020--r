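#' Per-group summaries of a score table
#'
#' Arithmetic means of GE, ED_R and EDGE plus counts, per group (e.g. per
#' country), sorted by mean EDGE descending.  Groups named in `grouping`
#' but matching no table row are skipped with a warning.
#'
#' @param table a score table from [rank_table()].
#' @param grouping named character vector taxon -> group name; taxa of the
#'   table not named here are ignored.
#' @return data frame with columns `group`, `n`, `mean_GE`, `mean_ED_R`,
#'   `mean_EDGE`.
#' @export
group_summaries <- function(table, grouping) {
  stopifnot(is.data.frame(table),
            all(c("taxon", "GE", "ED_R", "EDGE") %in% names(table)))
  g <- grouping[table$taxon]
  keep <- !is.na(g)
  empty <- setdiff(unique(grouping), g[keep])
  if (length(empty) > 0L)
    warning("group(s) with no scored taxa skipped: ",
            paste(empty, collapse = ", "))
  if (!any(keep)) stop("no table row matched by 'grouping'")
  tab <- table[keep, ]
  g <- g[keep]
  out <- do.call(rbind, lapply(split(seq_len(nrow(tab)), g), function(i)
    data.frame(n = length(i), mean_GE = mean(tab$GE[i]),
               mean_ED_R = mean(tab$ED_R[i]), mean_EDGE = mean(tab$EDGE[i]))))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out$group <- as.character(out$group)
  out[order(-out$mean_EDGE, out$group, method = "radix"), , drop = FALSE]
}

#' Significance of a group's best rank
#'
#' Probability, under uniformly random assignment of ranks `1..total` to a
#' group of `group_size` taxa, that no group member ranks better than
#' `best_rank`: `choose(total - best_rank + 1, group_size) /
#' choose(total, group_size)`, evaluated in log space.  A small value means
#' the group's best member ranks significantly *worse* than chance — the
#' pattern seen when a geographic region is uniformly low-priority.
#'
#' @param total number of ranked taxa.
#' @param group_size number of taxa in the group.
#' @param best_rank the best (smallest) rank held by a group member; must
#'   satisfy `1 <= best_rank <= total - group_size + 1`.
#' @param permutations optional: if a positive integer, also estimate the
#'   probability by Monte-Carlo rank permutation (returned as the
#'   `"mc_estimate"` attribute) as a cross-check on the closed form.
#' @param seed optional seed for the permutation estimate.
#' @return the probability, in `(0, 1]`.
#' @examples
#' group_best_rank_pvalue(5, 2, 3)          # 0.3
#' group_best_rank_pvalue(350, 53, 83)      # ~1.8e-7
#' @export
group_best_rank_pvalue <- function(total, group_size, best_rank,
                                   permutations = NULL, seed = NULL) {
  if (group_size < 1L || group_size > total)
    stop("'group_size' must be between 1 and 'total'")
  if (best_rank < 1L || best_rank > total - group_size + 1L)
    stop("'best_rank' must be between 1 and total - group_size + 1")
  p <- exp(lchoose(total - best_rank + 1, group_size) -
             lchoose(total, group_size))
  if (!is.null(permutations) && permutations > 0) {
    mc <- .with_seed(seed, mean(vapply(seq_len(permutations), function(i)
      min(sample.int(total, group_size)) >= best_rank, logical(1))))
    attr(p, "mc_estimate") <- mc
  }
  p
}

#' Correlation between distinctiveness and endangerment
#'
#' Squared Pearson correlation between the ED and GE columns of a score
#' table, with the conventional two-sided t-test p-value (n - 2 degrees of
#' freedom) for the underlying correlation.
#'
#' @param table a score table from [rank_table()] (needs `ED` and `GE`).
#' @return list with elements `r_squared` and `p_value`.
#' @export
ed_ge_correlation <- function(table) {
  stopifnot(is.data.frame(table), all(c("ED", "GE") %in% names(table)))
  if (nrow(table) < 3L) stop("need at least 3 rows")
  if (stats::sd(table$ED) == 0 || stats::sd(table$GE) == 0)
    stop("correlation undefined for a constant column")
  ct <- stats::cor.test(table$ED, table$GE, method = "pearson")
  list(r_squared = unname(ct$estimate^2), p_value = ct$p.value)
}
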