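test_that("r_squared is the squared Pearson correlation", {
  x <- c(1, 2, 3, 4)
  expect_equal(r_squared(x, 2 * x + 1), 1)
  expect_equal(r_squared(c(1, 2, 3), c(1, 3, 2)), 0.25)
  set.seed(430)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(r_squared(a, b), r_squared(b, a))
  expect_equal(r_squared(a, b), r2_byhand(a, b))
  expect_error(r_squared(rep(1, 5), 1:5), "constant")
  expect_error(r_squared(1:2, 1:2), "at least 3")
})

test_that("prune_random is seed-deterministic and removes exactly n tips", {
  tr <- random_tree(50, seed = 431)
  expect_same_tree(prune_random(tr, 0, seed = 1), tr)
  a <- prune_random(tr, 20, seed = 7)
  b <- prune_random(tr, 20, seed = 7)
  c <- prune_random(tr, 20, seed = 8)
  expect_same_tree(a, b)
  expect_equal(length(a$tip.label), 30)
  expect_false(setequal(a$tip.label, c$tip.label))
  expect_error(prune_random(tr, 48), "between 0 and")
})

test_that("pruning_experiment degenerates correctly at fraction zero and one replicate", {
  tr <- random_tree(30, seed = 432)
  e0 <- pruning_experiment(tr, 0, reps = 5, seed = 1)
  expect_true(all(e0$replicates == 1))
  e1 <- pruning_experiment(tr, 0.5, reps = 1, seed = 2)
  expect_length(e1$replicates, 1)
  expect_equal(unname(e1$band), rep(e1$replicates, 2))
  expect_identical(e1$arm, "reduced")
})

test_that("replicate R2 values are valid and the band brackets the mean", {
  tr <- random_tree(60, seed = 433)
  e <- pruning_experiment(tr, 0.6, reps = 50, seed = 3)
  expect_true(all(e$replicates >= 0 & e$replicates <= 1))
  expect_lte(e$band[1], e$mean_r2)
  expect_gte(e$band[2], e$mean_r2)
  # bit-identical reproducibility from the seed
  e2 <- pruning_experiment(tr, 0.6, reps = 50, seed = 3)
  expect_identical(e, e2)
})

test_that("mean R2 is non-increasing in the removal fraction", {
  tr <- random_tree(80, seed = 434)
  cv <- pruning_curve(tr, c(0.2, 0.5, 0.8), 80, seed = 4)
  s <- summary(cv)
  expect_equal(s$fraction_removed, c(0.2, 0.5, 0.8))
  expect_true(all(diff(s$mean_r2) <= 0.03))
  one <- pruning_curve(tr, 0, 3, seed = 5)
  expect_equal(summary(one)$mean_r2, 1)
})

test_that("heavy-tailed structured trees keep ED resilient at 71.2% missingness", {
  # mean replicate R2 far exceeds the retained fraction (0.288)
  tr <- random_tree(350, branch_law = "heavy_tail", seed = 435)
  e <- pruning_experiment(tr, 0.712, reps = 200, seed = 6)
  expect_gt(e$mean_r2, 0.288 + 0.2)
})

test_that("taxonomy reconstruction recovers ED lost to pruning", {
  # paired arms on the same scenario; classification-informed regrafting
  # should track the truth better than the bare reduced tree
  set.seed(436)
  diffs <- replicate(25, {
    sc <- make_scenario(150, sampling_fraction = 1)
    red <- pruning_experiment(sc$truth_tree, 0.7, reps = 1, seed = 99)
    rec <- pruning_experiment(sc$truth_tree, 0.7, reps = 1, seed = 99,
                              classification = sc$classification)
    expect_identical(rec$arm, "reconstructed")
    rec$mean_r2 - red$mean_r2
  })
  expect_gt(mean(diffs), -0.02)
  expect_gt(mean(diffs), 0)
})

test_that("inclusion-bias summaries report nested threat percentages", {
  st <- c(a = "threatened", b = "vigorous", c = "nearly extinct",
          d = "moribund", e = "national", f = "shifting")
  s <- inclusion_bias_summary(st, included = c("a", "b"))
  expect_equal(s["included", "pct_ge_2"], 50)
  expect_equal(s["included", "n"], 2)
  expect_equal(s["excluded", "n"], 4)
  for (r in rownames(s)) {
    expect_lte(s[r, "pct_ge_3.5"], s[r, "pct_ge_3"])
    expect_lte(s[r, "pct_ge_3"], s[r, "pct_ge_2"])
  }
  # mirrored sets give mirrored summaries
  s2 <- inclusion_bias_summary(st, included = c("c", "d", "e", "f"))
  expect_equal(s2["included", ], s["excluded", ], ignore_attr = TRUE)
  expect_error(inclusion_bias_summary(st, included = names(st)), "non-empty")
})
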