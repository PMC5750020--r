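test_that("fair proportion matches hand-computed path shares", {
  expect_equal(fair_proportion(parse_newick("((A:1,B:1):1,C:2);")),
               c(A = 1.5, B = 1.5, C = 2.0))
  expect_equal(fair_proportion(parse_newick("(A:1,B:2,C:3);")),
               c(A = 1, B = 2, C = 3))
  expect_error(fair_proportion(parse_newick("((A:1,B),C:2);")), "absent")
})

test_that("balanced binary trees give the closed-form ED 2 - 2^(1-k)", {
  for (k in 1:6) {
    tr <- ape::stree(2^k, type = "balanced")
    tr$edge.length <- rep(1, nrow(tr$edge))
    expect_equal(unname(fair_proportion(tr)),
                 rep(2 - 2^(1 - k), 2^k), tolerance = 1e-12)
  }
})

test_that("tip scores sum to total branch length and match the brute-force oracle", {
  set.seed(420)
  for (i in 1:60) {
    tr <- random_tree(sample(3:120, 1),
                      branch_law = sample(c("uniform", "heavy_tail"), 1))
    ed <- fair_proportion(tr)
    expect_equal(sum(ed), total_branch_length(tr), tolerance = 1e-9)
  }
  for (i in 1:40) {
    tr <- random_tree(sample(3:12, 1))
    ed <- fair_proportion(tr)
    bf <- fp_bruteforce(tr)
    expect_equal(ed[names(bf)], bf, tolerance = 1e-12)
  }
})

test_that("fair proportion agrees with an established independent implementation", {
  tr <- random_tree(60, branch_law = "heavy_tail", seed = 421)
  fp <- fair_proportion(tr)
  ref <- picante::evol.distinct(tr, type = "fair.proportion")
  expect_equal(unname(fp[as.character(ref$Species)]), ref$w, tolerance = 1e-9)
})

test_that("ED never decreases for tips surviving a root-spanning prune", {
  # shares are split among fewer tips; holds whenever the root is retained
  # (a prune confined to one side of the root discards the basal stub edge,
  # which legitimately lowers the survivors' ED)
  set.seed(422)
  done <- 0
  while (done < 20) {
    tr <- random_tree(sample(6:60, 1))
    keep <- sample(tr$tip.label, sample(3:(length(tr$tip.label) - 1), 1))
    if (tree_mrca(tr, keep) != length(tr$tip.label) + 1L) next
    before <- fair_proportion(tr)[keep]
    after <- fair_proportion(prune_tips(tr, keep))[keep]
    expect_true(all(after >= before - 1e-12))
    done <- done + 1
  }
})

test_that("relative ED has mean one over the normalization set", {
  expect_equal(relative_ed(c(A = 2, B = 4)), c(A = 2/3, B = 4/3))
  expect_equal(unname(relative_ed(c(A = 7, B = 7, C = 7))), rep(1, 3))
  set.seed(423)
  ed <- stats::setNames(runif(50, 0.1, 5), paste0("t", 1:50))
  sub <- sample(names(ed), 20)
  expect_equal(mean(relative_ed(ed, sub)), 1, tolerance = 1e-12)
  expect_error(relative_ed(c(A = 0, B = 0)), "positive")
})

test_that("the GE scale maps statuses, aliases and EGIDS codes", {
  expect_equal(ge_from_status("nearly extinct"), 4)
  expect_equal(ge_from_status("national"), 1/32)
  expect_equal(ge_from_status("vigorous"), 1)
  expect_equal(ge_from_status(c("Nearly Ext.", "wider comm.")), c(4, 1/8))
  expect_equal(ge_from_status(c("8b", "6a", "1")), c(4, 1, 1/32))
  expect_error(ge_from_status("9"), "dormant")
  expect_error(ge_from_status("flourishing"), "valid names")

  sc <- ge_scale_default()
  expect_true(all(diff(sc$ge) < 0))              # strictly decreasing
  below_vigorous <- sc$ge[sc$ge <= 1]
  expect_equal(below_vigorous[-1] / below_vigorous[-length(below_vigorous)],
               rep(1/2, length(below_vigorous) - 1))  # exact halving
})

test_that("edge_score reproduces the published worked examples", {
  # printed (ED_R, GE) pairs; printed EDGE values carry rounded inputs
  pairs <- list(
    list(3.36, 4, 2.17), list(2.21, 4, 1.86), list(2.50, 3, 1.774),
    list(3.13, 2, 1.765), list(1.88, 4, 1.75), list(3.66, 1, 1.7133),
    list(0.25, 1/8, 0.24), list(0.16, 1/32, 0.15))
  for (p in pairs)
    expect_lt(abs(edge_score(p[[1]], p[[2]]) - p[[3]]), 0.005)
  expect_equal(edge_score(0, 0), 0)
  expect_equal(edge_score(0, 0, variant = "original"), 0)
  expect_equal(edge_score(1, 2, variant = "original"), log(2) + 2 * log(2))
})

test_that("edge_score is strictly increasing in each argument", {
  d <- seq(0, 5, by = 0.25)
  for (v in c("modified", "original")) {
    expect_true(all(diff(edge_score(d, 2, variant = v)) > 0))
    expect_true(all(diff(edge_score(1, d, variant = v)) > 0))
  }
  # endangerment adds at most ln 2 under the modified variant's default scale
  expect_lte(edge_score(0, max(ge_scale_default()$ge)), log(2) + 1e-12)
})

test_that("rank_table orders by EDGE with deterministic tie-breaks", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  st <- c(A = "vigorous", B = "threatened", C = "nearly extinct")
  tab <- rank_table(tr, st)
  expect_equal(tab$rank, 1:3)
  expect_equal(tab$taxon[1], "C")
  expect_true(all(diff(tab$EDGE) <= 0))
  expect_equal(mean(tab$ED_R), 1, tolerance = 1e-12)

  # identical scores fall back to label order
  tie <- rank_table(parse_newick("(A:1,B:1);"),
                    c(A = "vigorous", B = "vigorous"))
  expect_equal(tie$taxon, c("A", "B"))

  # permutation invariance of the inputs
  set.seed(424)
  tr <- random_tree(20)
  st <- random_statuses(tr$tip.label)
  t1 <- rank_table(tr, st)
  t2 <- rank_table(tr, st[sample(names(st))])
  expect_identical(t1, t2)
})

test_that("dedupe_by_code keeps the highest-ED representative per code", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  out <- dedupe_by_code(tr, c(A = "x", B = "x", C = "y"))
  expect_setequal(out$tip.label, c("A", "C"))  # tie between A and B -> label order
  tr2 <- parse_newick("((A:1,B:2):1,C:2);")
  out2 <- dedupe_by_code(tr2, c(A = "x", B = "x", C = "y"))
  expect_setequal(out2$tip.label, c("B", "C"))

  all_unique <- dedupe_by_code(tr, c(A = "1", B = "2", C = "3"))
  expect_same_tree(all_unique, tr)
  set.seed(425)
  tr3 <- random_tree(30)
  codes <- stats::setNames(sample(letters[1:8], 30, replace = TRUE),
                           tr3$tip.label)
  expect_equal(length(dedupe_by_code(tr3, codes)$tip.label),
               length(unique(codes)))
})
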