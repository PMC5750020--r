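test_that("missing taxa graft at group crowns, singles via pendant insertion", {
  bb <- parse_newick("((English:4,German:1):1,(Icelandic:1,Norwegian:5):2);")
  g <- graft_missing(bb, germanic())
  expect_setequal(g$tree$tip.label, germanic()$taxon)
  # the classic reconstruction: Swedish joins the North crown, Dutch is
  # inserted beside German via the single-member pendant rule
  expect_equal(canon_topology(g$tree),
    "(((Dutch,German),English),(Icelandic,Norwegian,Swedish))")
  # backbone total length preserved exactly; new edges are zero
  expect_identical(total_branch_length(g$tree), total_branch_length(bb))
  # German keeps its full pendant edge
  ge <- g$tree$edge.length[g$tree$edge[, 2] == match("German", g$tree$tip.label)]
  expect_equal(ge, 1)
  expect_equal(nrow(g$report), 2L)
  expect_setequal(g$report$taxon, c("Dutch", "Swedish"))
  expect_length(g$warnings, 0)
})

test_that("grafting with no missing taxa is the identity, and grafting is idempotent", {
  sc <- make_scenario(40, sampling_fraction = 1, seed = 11)
  g <- graft_missing(sc$backbone, sc$classification)
  expect_same_tree(g$tree, sc$backbone)
  expect_equal(nrow(g$report), 0L)

  sc <- make_scenario(60, sampling_fraction = 0.5, seed = 12)
  g1 <- graft_missing(sc$backbone, sc$classification)
  g2 <- graft_missing(g1$tree, sc$classification)
  expect_same_tree(g1$tree, g2$tree)
})

test_that("grafting preserves total length, completes the tip set, and never raises backbone ED", {
  set.seed(410)
  for (i in 1:15) {
    sc <- make_scenario(sample(30:120, 1),
                        sampling_fraction = runif(1, 0.3, 0.9))
    ed_before <- fair_proportion(sc$backbone)
    g <- graft_missing(sc$backbone, sc$classification)
    expect_setequal(g$tree$tip.label, sc$classification$taxon)
    expect_equal(total_branch_length(g$tree),
                 total_branch_length(sc$backbone), tolerance = 1e-12)
    ed_after <- fair_proportion(g$tree)[names(ed_before)]
    expect_true(all(ed_after <= ed_before + 1e-12))
    # no unifurcations survive
    tab <- tabulate(g$tree$edge[, 1])
    expect_true(all(tab[tab > 0] >= 2))
  }
})

test_that("whole missing subgroups are imported as units with their structure", {
  bb <- parse_newick("((A:1,B:1):1,C:2);")
  cl <- classification(
    c("A", "B", "C", "x", "y", "z"),
    list(c("F", "P"), c("F", "P"), c("F", "Q"),
         c("F", "Q", "R"), c("F", "Q", "R"), c("F", "Q", "R", "S")))
  g <- graft_missing(bb, cl)
  # R (with x, y and nested S holding z) is one maximal missing unit whose
  # innermost backbone-bearing group is Q, whose only backbone member is C
  expect_setequal(g$tree$tip.label, cl$taxon)
  expect_equal(unique(g$report$unit_group), "R")
  expect_equal(unique(g$report$attachment_group), "Q")
  # C keeps its pendant length under the inserted junction
  ce <- g$tree$edge.length[g$tree$edge[, 2] == match("C", g$tree$tip.label)]
  expect_equal(ce, 2)
  expect_identical(total_branch_length(g$tree), 5)
  # z sits inside the grafted structure below x, y's group
  m_xyz <- tree_mrca(g$tree, c("x", "y", "z"))
  m_xy <- tree_mrca(g$tree, c("x", "y"))
  expect_equal(m_xyz, m_xy)  # S collapses into R's polytomy or nests below
})

test_that("non-monophyletic backbone groups warn and use the MRCA", {
  bb <- parse_newick("(((A:1,C:1):1,B:1):1,D:3);")
  cl <- classification(
    c("A", "B", "C", "D", "new"),
    list(c("F", "G"), c("F", "G"), c("F", "H"), c("F", "H"),
         c("F", "G", "Gsub")))
  g <- graft_missing(bb, cl)
  expect_true(length(g$warnings) > 0)
  expect_match(g$warnings[1], "not monophyletic")
  expect_false(all(g$report$monophyletic))
  expect_setequal(g$tree$tip.label, cl$taxon)
})

test_that("graft preconditions are enforced", {
  bb <- parse_newick("((A:1,B:1):1,C:2);")
  cl <- classification(c("A", "B"), list(c("F"), c("F")))
  expect_error(graft_missing(bb, cl), "absent from the classification")
})
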