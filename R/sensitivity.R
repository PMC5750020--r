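#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y)^2
}

#' Randomly prune a fixed number of tips
#'
#' Removes a uniformly random subset of tips (without replacement within a
#' draw) via [prune_tips()].  Deterministic for a given seed.
#'
#' @param tree a `"phylo"`.
#' @param n_remove integer, `0 <= n_remove <= Ntip - 3`.
#' @param seed optional integer seed; when given, the caller's RNG stream
#'   is left untouched.
#' @return the pruned `"phylo"`.
#' @export
prune_random <- function(tree, n_remove, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n_remove < 0L || n_remove > n - 3L)
    stop("'n_remove' must be between 0 and Ntip - 3 (= ", n - 3L, ")")
  if (n_remove == 0L) return(tree)
  .with_seed(seed, {
    drop <- sample(tree$tip.label, n_remove)
    prune_tips(tree, setdiff(tree$tip.label, drop))
  })
}

#' Pruning robustness experiment at one missingness fraction
#'
#' Measures how well fair-proportion ED survives incomplete tip sampling.
#' Per replicate: remove `floor(fraction * Ntip)` uniformly random tips;
#' optionally graft the removed taxa back from a classification (the
#' "reconstructed" arm, mimicking taxonomy-based repair of an incomplete
#' tree); recompute ED; and take the squared Pearson correlation with the
#' full tree's ED over the surviving tips only.  Replicates draw tip sets
#' independently.
#'
#' @param tree a `"phylo"` with branch lengths.
#' @param fraction fraction of tips removed, in `[0, 1)`; must leave at
#'   least 3 tips.
#' @param reps number of replicates (>= 1).
#' @param classification optional `"classification"` covering all tips of
#'   `tree`; when given, removed taxa are grafted back before scoring
#'   (the reconstructed arm).
#' @param seed optional integer seed.
#' @return an object of class `"prune_experiment"`: list with
#'   `fraction_removed`, `replicates` (R-squared values), `mean_r2`, `band`
#'   (central 99% interval of the replicates, 0.5 and 99.5 percentiles),
#'   `arm` (`"reduced"` or `"reconstructed"`), `n_removed`.
#' @export
pruning_experiment <- function(tree, fraction, reps, classification = NULL,
                               seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (fraction < 0 || fraction >= 1) stop("'fraction' must be in [0, 1)")
  if (reps < 1L) stop("'reps' must be >= 1")
  n <- length(tree$tip.label)
  k <- floor(fraction * n)
  if (n - k < 3L) stop("'fraction' leaves fewer than 3 tips")
  ed_full <- fair_proportion(tree)
  r2 <- .with_seed(seed, vapply(seq_len(reps), function(i) {
    if (k == 0L) return(1)
    drop <- sample(tree$tip.label, k)
    surv <- setdiff(tree$tip.label, drop)
    red <- prune_tips(tree, surv)
    if (!is.null(classification)) {
      red <- graft_missing(red, classification)$tree
    }
    r_squared(ed_full[surv], fair_proportion(red)[surv])
  }, 0))
  structure(list(fraction_removed = fraction, replicates = r2,
                 mean_r2 = mean(r2),
                 band = unname(stats::quantile(r2, c(0.005, 0.995))),
                 arm = if (is.null(classification)) "reduced" else "reconstructed",
                 n_removed = k),
            class = "prune_experiment")
}

#' @export
print.prune_experiment <- function(x, ...) {
  cat(sprintf(
    "Pruning experiment (%s arm): fraction %.3f (%d tips), %d replicates\n",
    x$arm, x$fraction_removed, x$n_removed, length(x$replicates)))
  cat(sprintf("mean R^2 = %.4f, central 99%% band [%.4f, %.4f]\n",
              x$mean_r2, x$band[1L], x$band[2L]))
  invisible(x)
}

#' Pruning robustness curve over several missingness fractions
#'
#' Runs [pruning_experiment()] at each fraction.  The replicate draws of
#' successive fractions share one seeded RNG stream, so the whole curve is
#' reproducible from a single seed.
#'
#' @inheritParams pruning_experiment
#' @param fractions numeric vector of fractions in `[0, 1)`.
#' @param reps_per_fraction replicates per fraction.
#' @return an object of class `"prune_curve"`: list of
#'   `"prune_experiment"` results, one per fraction.
#' @export
pruning_curve <- function(tree, fractions, reps_per_fraction,
                          classification = NULL, seed = NULL) {
  if (any(fractions < 0 | fractions >= 1))
    stop("all fractions must be in [0, 1)")
  out <- .with_seed(seed, lapply(fractions, function(f)
    pruning_experiment(tree, f, reps_per_fraction,
                       classification = classification)))
  class(out) <- "prune_curve"
  out
}

#' Summarize a pruning curve as a data frame
#'
#' @param object a `"prune_curve"`.
#' @param ... unused.
#' @return data frame with one row per fraction: `fraction_removed`,
#'   `retained`, `mean_r2`, `band_low`, `band_high`, `arm`.
#' @export
summary.prune_curve <- function(object, ...) {
  do.call(rbind, lapply(object, function(e)
    data.frame(fraction_removed = e$fraction_removed,
               retained = 1 - e$fraction_removed,
               mean_r2 = e$mean_r2,
               band_low = e$band[1L], band_high = e$band[2L],
               arm = e$arm, stringsAsFactors = FALSE)))
}

#' Plot a pruning curve
#'
#' Scatter of replicate R-squared values against the fraction of tips
#' removed, with the per-fraction mean overlaid.
#'
#' @param x a `"prune_curve"`.
#' @param ... passed to [plot()].
#' @export
plot.prune_curve <- function(x, ...) {
  f <- unlist(lapply(x, function(e)
    rep(e$fraction_removed, length(e$replicates))))
  r2 <- unlist(lapply(x, function(e) e$replicates))
  graphics::plot(f, r2, pch = ".", col = "grey40",
                 xlab = "fraction of tips removed",
                 ylab = expression(R^2 ~ "with full-tree ED"),
                 ylim = c(0, 1), ...)
  s <- summary.prune_curve(x)
  graphics::lines(s$fraction_removed, s$mean_r2, type = "b", pch = 19)
  invisible(x)
}

#' Endangerment summary for included versus excluded taxa
#'
#' Quantifies sampling bias in which taxa made it onto a tree: mean GE and
#' the percentage of taxa at or above GE thresholds 2 (threatened),
#' 3 (endangered) and 3.5 (moribund), separately for the included and
#' excluded sets.
#'
#' @param statuses named character vector taxon -> status, covering both
#'   sets.
#' @param included character vector of included taxa; the excluded set is
#'   the remaining names of `statuses`.
#' @param scale GE scale.
#' @return data frame with rows `included` and `excluded` and columns `n`,
#'   `mean_ge`, `pct_ge_2`, `pct_ge_3`, `pct_ge_3.5`.
#' @export
inclusion_bias_summary <- function(statuses, included,
                                   scale = ge_scale_default()) {
  if (length(statuses) == 0L) stop("'statuses' is empty")
  unknown <- setdiff(included, names(statuses))
  if (length(unknown) > 0L)
    stop("included taxa without status: ", paste(unknown, collapse = ", "))
  ge <- ge_from_status(statuses, scale)
  names(ge) <- names(statuses)
  inc <- names(statuses) %in% included
  if (!any(inc) || all(inc))
    stop("both the included and excluded sets must be non-empty")
  one <- function(g) data.frame(
    n = length(g), mean_ge = mean(g),
    pct_ge_2 = 100 * mean(g >= 2), pct_ge_3 = 100 * mean(g >= 3),
    pct_ge_3.5 = 100 * mean(g >= 3.5))
  out <- rbind(one(ge[inc]), one(ge[!inc]))
  rownames(out) <- c("included", "excluded")
  out
}
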