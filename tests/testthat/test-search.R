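test_that("tip insertion and NNI produce valid unrooted binary trees", {
  tr <- quartet()
  t5 <- insert_tip(tr, 1L, "e")
  expect_equal(sort(t5$tip.label), c("a", "b", "c", "d", "e"))
  expect_equal(t5$Nnode, 3L)
  report <- capture.output(ape::checkValidPhylo(ape::reorder.phylo(t5)))
  expect_false(any(grepl("FATAL|MODERATE", report)))
  nb <- nni_neighbors(t5)
  expect_length(nb, 4L)  # 2 internal edges x 2 rearrangements
  keys <- vapply(nb, topo_key, character(1))
  expect_false(topo_key(t5) %in% keys)
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("unrooted monophyly detection finds exactly the present splits", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  expect_true(is_monophyletic_unrooted(tr, c("a", "b")))
  expect_true(is_monophyletic_unrooted(tr, c("c", "d", "e", "f")))
  expect_false(is_monophyletic_unrooted(tr, c("a", "c")))
  expect_false(is_monophyletic_unrooted(tr, c("a", "b", "c")))
  # trivial sets are always monophyletic
  expect_true(is_monophyletic_unrooted(tr, "a"))
  expect_true(is_monophyletic_unrooted(tr, c("a", "b", "c", "d", "e")))
})

test_that("exhaustive enumeration covers all unrooted topologies", {
  expect_length(all_topologies(letters[1:4]), 3L)
  tops <- all_topologies(letters[1:6])
  expect_length(tops, 105L)
  expect_equal(anyDuplicated(vapply(tops, topo_key, character(1))), 0L)
})

test_that("heuristic search equals exhaustive search on quartets", {
  mod <- build_model("LG", alpha = 0.8)
  for (seed in 1:3) {
    tr <- random_tree(4, seed = seed, bl = c(0.1, 0.4))
    aln <- simulate_alignment(tr, mod, 150, seed = seed + 10)
    ex <- search_ml_tree(aln, mod, method = "exhaustive")
    he <- search_ml_tree(aln, mod, seed = seed, n_starts = 2)
    expect_equal(topo_key(he), topo_key(ex))
    expect_equal(attr(he, "loglik"), attr(ex, "loglik"), tolerance = 1e-3)
  }
})

test_that("a quartet constraint leaves a single valid topology", {
  mod <- build_model("LG", alpha = 1)
  aln <- random_alignment(4, 60, "AA", seed = 1)
  rownames(aln) <- letters[1:4]
  fit <- search_ml_tree(aln, mod, constraint = c("a", "b"))
  expect_true(is_monophyletic_unrooted(fit, c("a", "b")))
  ex <- search_ml_tree(aln, mod, constraint = c("a", "b"),
                       method = "exhaustive")
  expect_equal(topo_key(fit), topo_key(ex))
})

test_that("constrained optima never beat unconstrained optima", {
  mod <- build_model("LG", alpha = 0.7)
  tr <- random_tree(6, seed = 5, bl = c(0.1, 0.4))
  aln <- simulate_alignment(tr, mod, 100, seed = 3)
  free <- search_ml_tree(aln, mod, method = "exhaustive")
  for (clade in list(tr$tip.label[1:2], tr$tip.label[c(1, 4)])) {
    con <- search_ml_tree(aln, mod, constraint = clade,
                          method = "exhaustive")
    expect_lte(attr(con, "loglik"), attr(free, "loglik") + 1e-9)
    expect_true(is_monophyletic_unrooted(con, clade))
  }
})

test_that("search recovers the generating topology from long alignments", {
  mod <- build_model("LG", alpha = 0.7)
  tr <- random_tree(12, seed = 8, bl = c(0.08, 0.4))
  aln <- simulate_alignment(tr, mod, 2000, seed = 17)
  fit <- search_ml_tree(aln, mod, seed = 4, n_starts = 5)
  expect_equal(topo_key(fit), topo_key(tr))
})

test_that("invalid constraints and tiny taxon sets are rejected", {
  mod <- build_model("LG")
  aln <- random_alignment(4, 30, "AA", seed = 2)
  expect_error(search_ml_tree(aln[1:3, ], mod), "at least 4")
  expect_error(search_ml_tree(aln, mod, constraint = c("seq1", "nope")),
               "missing")
  expect_error(search_ml_tree(aln, mod, constraint = c("seq1", "seq2",
                                                       "seq3")),
               "unsatisfiable")
  expect_error(search_ml_tree(aln, mod, constraint = "seq1"),
               "unsatisfiable")
})

test_that("identical seeds reproduce the search; results ignore row order", {
  mod <- build_model("LG", alpha = 0.9)
  tr <- random_tree(8, seed = 2)
  aln <- simulate_alignment(tr, mod, 120, seed = 6)
  f1 <- search_ml_tree(aln, mod, seed = 42)
  f2 <- search_ml_tree(aln, mod, seed = 42)
  expect_equal(topo_key(f1), topo_key(f2))
  expect_equal(attr(f1, "loglik"), attr(f2, "loglik"))
  f3 <- search_ml_tree(aln[rev(aln_ids(aln)), ], mod, seed = 42)
  expect_equal(topo_key(f3), topo_key(f1))
})
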