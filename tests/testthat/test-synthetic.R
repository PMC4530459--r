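test_that("template trees implement the paralog-duplication geometry", {
  for (np in c(3, 6)) {
    tpl <- template_trees(np, seed = 2)
    expect_length(tpl$tree_global$tip.label, 2 * np)
    expect_length(tpl$tree_conv$tip.label, 2 * np)
    # the global tree splits the two paralog clades ...
    a_clade <- paste0("pair", seq_len(np), "_A")
    expect_true(is_monophyletic_unrooted(tpl$tree_global, a_clade))
    # ... and violates the conversion constraint, which the conversion tree
    # satisfies by construction
    expect_false(is_monophyletic_unrooted(tpl$tree_global, tpl$conv_clade))
    expect_true(is_monophyletic_unrooted(tpl$tree_conv, tpl$conv_clade))
  }
  expect_error(template_trees(2), "at least 3")
})

test_that("template trees are seed-deterministic and direction-aware", {
  t1 <- template_trees(4, seed = 9)
  t2 <- template_trees(4, seed = 9)
  expect_identical(ape::write.tree(t1$tree_global),
                   ape::write.tree(t2$tree_global))
  t3 <- template_trees(4, seed = 10)
  expect_false(identical(ape::write.tree(t1$tree_global),
                         ape::write.tree(t3$tree_global)))
  ab <- template_trees(4, conv_pair = 2, direction = "donor_A_to_B", seed = 1)
  expect_equal(ab$recipient, "pair2_B")
  expect_equal(ab$partner, "pair2_A")
})

test_that("scenario validation enforces the tract and tree invariants", {
  expect_error(conversion_scenario(tract = c(100, 300)), "tract")
  expect_error(conversion_scenario(tract = c(150, 100)), "tract")
  tpl <- template_trees(6, seed = 1)
  expect_error(conversion_scenario(tree_global = tpl$tree_global,
                                   tree_conv = tpl$tree_global, seed = 1),
               "constraint")
})

test_that("generated alignments have the scenario's shape and determinism", {
  sc <- conversion_scenario(seed = 3)
  g <- generate(sc)
  expect_equal(dim(unclass(g$alignment)), c(12L, 230L))
  expect_setequal(aln_ids(g$alignment), sc$tree_global$tip.label)
  g2 <- generate(sc)
  expect_identical(aln_strings(g$alignment), aln_strings(g2$alignment))
  expect_equal(g$truth$conv_clade, c("pair1_A", "pair1_B"))
  # the truth record can rebuild both trees
  expect_silent(ape::read.tree(text = g$truth$tree_global_newick))
  expect_silent(ape::read.tree(text = g$truth$tree_conv_newick))
})

test_that("an empty tract reduces to simulation on the global tree", {
  sc <- conversion_scenario(tract = NULL, total_length = 80, seed = 5)
  g <- generate(sc)
  direct <- simulate_alignment(sc$tree_global, sc$model, 80,
                               seed = derive_seed(5, "outside"))
  expect_identical(aln_strings(g$alignment), aln_strings(direct))
})

test_that("a whole-alignment tract leaves only the conversion history", {
  sc <- conversion_scenario(n_pairs = 3, total_length = 200,
                            tract = c(1, 200), seed = 8)
  g <- generate(sc)
  fit <- search_ml_tree(g$alignment, build_model("LG", alpha = 0.7),
                        method = "exhaustive")
  expect_true(is_monophyletic_unrooted(fit, sc$conv_clade))
})

test_that("scenarios round-trip through the key-value config format", {
  sc <- conversion_scenario(n_pairs = 4, total_length = 120,
                            tract = c(31, 90), direction = "donor_A_to_B",
                            conv_pair = 2, depth_scale = 0.25, seed = 17)
  path <- tempfile(fileext = ".cfg")
  write_scenario_config(sc, path)
  back <- read_scenario_config(path)
  for (f in c("n_pairs", "total_length", "tract", "direction", "conv_pair",
              "depth_scale", "seed"))
    expect_equal(back[[f]], sc[[f]], label = f)
  expect_equal(back$model$name, sc$model$name)
  expect_equal(back$model$alpha, sc$model$alpha)
  # identical seeds rebuild identical template trees
  expect_identical(ape::write.tree(back$tree_global),
                   ape::write.tree(sc$tree_global))
  # tract "none" means no conversion
  no <- conversion_scenario(tract = NULL, seed = 2)
  write_scenario_config(no, path)
  expect_null(read_scenario_config(path)$tract)
})

test_that("n-pair assembly subsets rows and keeps all columns", {
  sc <- conversion_scenario(seed = 2)
  g <- generate(sc)
  bg <- paste0("pair", rep(2:4, each = 2), c("_A", "_B"))
  sub <- make_npair_alignment(g$alignment, c("pair1_A", "pair1_B"), bg)
  expect_equal(nrow(sub), 8L)  # 1 focal + 3 background pairs
  expect_equal(aln_length(sub), 230L)
  expect_equal(aln_ids(sub)[1:2], c("pair1_A", "pair1_B"))
  bg5 <- paste0("pair", rep(2:6, each = 2), c("_A", "_B"))
  expect_equal(nrow(make_npair_alignment(g$alignment,
                                         c("pair1_A", "pair1_B"), bg5)), 12L)
  expect_error(make_npair_alignment(g$alignment, c("pair1_A", "pair9_B"),
                                    bg), "identifier")
})
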