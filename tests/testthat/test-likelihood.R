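test_that("pruning equals exhaustive state enumeration on small trees", {
  cases <- list(
    list(tree = quartet(0.3), model = build_model("LG", alpha = 0.7),
         alphabet = "AA"),
    list(tree = random_tree(5, seed = 2), model = build_model("GTR",
         alpha = 1.2, exch = c(1, 2, 1, 1, 4, 1),
         freq = c(0.3, 0.2, 0.2, 0.3)), alphabet = "NT"),
    list(tree = random_tree(5, seed = 3), model = build_model("CF2",
         alpha = 0.5), alphabet = "RY"))
  for (cs in cases) {
    n <- length(cs$tree$tip.label)
    aln <- random_alignment(n, 20, cs$alphabet, gap_frac = 0.1, seed = 7)
    rownames(aln) <- cs$tree$tip.label
    mine <- site_log_likelihoods(aln, cs$tree, cs$model)
    oracle <- oracle_site_loglik(aln, cs$tree, cs$model)
    expect_lt(max(abs(as.numeric(mine) - oracle)), 1e-8)
    expect_equal(attr(mine, "total"), sum(oracle), tolerance = 1e-8)
  }
})

test_that("pruning agrees with an independent implementation", {
  tr <- random_tree(8, seed = 4)
  mod <- build_model("LG", alpha = 0.7)
  aln <- simulate_alignment(tr, mod, 120, seed = 9)
  m <- unclass(aln); attributes(m) <- attributes(m)["dim"]
  rownames(m) <- aln_ids(aln)
  fit <- phangorn::pml(tr, phangorn::phyDat(m, type = "AA"), model = "LG",
                       k = 4, shape = 0.7)
  expect_equal(tree_log_likelihood(aln, tr, mod), as.numeric(logLik(fit)),
               tolerance = 1e-6)
})

test_that("degenerate columns follow the missing-data conventions", {
  # identical residues on a zero-length star: site lnL -> log pi(residue)
  tr <- ape::read.tree(text = "(a:1e-8,b:1e-8,c:1e-8,d:1e-8);")
  mod <- build_model("LG", alpha = 1)
  aln <- alignment(c(a = "WC-", b = "WC-", c = "WC-", d = "WC-"), "AA")
  s <- site_log_likelihoods(aln, tr, mod)
  expect_equal(s[1], log(mod$pi[["W"]]), tolerance = 1e-6)
  expect_equal(s[2], log(mod$pi[["C"]]), tolerance = 1e-6)
  # an all-gap column carries no information: site lnL = 0
  expect_equal(s[3], 0, tolerance = 1e-10)
})

test_that("the likelihood is invariant to leaf order and re-rooting", {
  tr <- random_tree(7, seed = 11)
  mod <- build_model("LG", alpha = 0.9)
  aln <- simulate_alignment(tr, mod, 60, seed = 5)
  base <- tree_log_likelihood(aln, tr, mod)
  perm <- aln[sample(aln_ids(aln)), ]
  expect_equal(tree_log_likelihood(perm, tr, mod), base, tolerance = 1e-9)
  rerooted <- ape::unroot(ape::root(tr, outgroup = tr$tip.label[3],
                                    resolve.root = TRUE))
  expect_equal(tree_log_likelihood(aln, rerooted, mod), base,
               tolerance = 1e-9)
})

test_that("label and alphabet mismatches are rejected", {
  tr <- quartet()
  mod <- build_model("LG")
  aln <- random_alignment(4, 10, "AA")
  expect_error(site_log_likelihoods(aln, tr, mod), "label")
  rownames(aln) <- tr$tip.label
  expect_error(site_log_likelihoods(aln, tr, build_model("GTR")),
               "alphabet")
})

test_that("branch optimization improves the likelihood and hits closed forms", {
  # two identical sequences inside a quartet: their pendant edges go to the
  # lower bound
  mod <- build_model("CF2", alpha = 1, k = 1)
  aln <- alignment(c(a = strrep("RY", 25), b = strrep("RY", 25),
                     c = strrep("YR", 25), d = strrep("RR", 25)), "RY")
  fit <- optimize_branch_lengths(quartet(), aln, mod)
  ed <- fit$edge.length[fit$edge[, 2] <= 4]
  names(ed) <- fit$tip.label[fit$edge[fit$edge[, 2] <= 4, 2]]
  expect_lt(ed[["a"]] + ed[["b"]], 1e-6)
  # monotonicity on random instances
  for (seed in 1:3) {
    tr <- random_tree(6, seed = seed)
    aln2 <- simulate_alignment(tr, build_model("LG", alpha = 0.7), 80,
                               seed = seed)
    before <- tree_log_likelihood(aln2, tr, build_model("LG", alpha = 0.7))
    after <- optimize_branch_lengths(tr, aln2, build_model("LG", alpha = 0.7))
    expect_gte(attr(after, "loglik"), before)
  }
})

test_that("the two-taxon CF2 distance matches its closed form", {
  # t_hat = -log(1 - 2d)/2 for mismatch fraction d under the two-state model
  # (embedded in a quartet with two far outgroups to keep the tree binary)
  n <- 400
  withr::with_seed(21, {
    x <- sample(c("R", "Y"), n, replace = TRUE)
    flip <- seq_len(n) <= 0.2 * n   # exact mismatch fraction d = 0.2
    y <- ifelse(flip, ifelse(x == "R", "Y", "R"), x)
  })
  aln <- alignment(c(a = paste(x, collapse = ""),
                     b = paste(y, collapse = "")), "RY")
  mod <- build_model("CF2", alpha = 1, k = 1)
  # direct 1-D profile of the a-b path length via the pairwise likelihood
  d <- 0.2
  expected <- -0.5 * log(1 - 2 * d)
  ll <- function(t) {
    ps <- 0.5 * (1 + exp(-2 * t)); pd <- 0.5 * (1 - exp(-2 * t))
    n * ((1 - d) * log(0.5 * ps) + d * log(0.5 * pd))
  }
  opt <- stats::optimize(ll, c(1e-8, 10), maximum = TRUE)
  expect_equal(opt$maximum, expected, tolerance = 1e-4)
  # the engine recovers the same path length on the two-taxon tree (only the
  # sum of the two pendant edges is identifiable)
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  fit <- optimize_branch_lengths(tr, aln, mod)
  expect_equal(sum(fit$edge.length), expected, tolerance = 1e-4)
})

test_that("the shape estimate agrees with a grid-search oracle", {
  tr <- random_tree(6, seed = 14, bl = c(0.1, 0.4))
  aln <- simulate_alignment(tr, build_model("LG", alpha = 0.6), 400,
                            seed = 15)
  a_hat <- estimate_gamma_shape(tr, aln, build_model("LG", alpha = 1))
  grid <- seq(0.3, 1.5, by = 0.05)
  ll <- vapply(grid, function(a)
    attr(optimize_branch_lengths(tr, aln, build_model("LG", alpha = a)),
         "loglik"), numeric(1))
  expect_lte(abs(grid[which.max(ll)] - as.numeric(a_hat)), 0.05 + 1e-9)
})

test_that("the gamma-shape estimate recovers the simulating shape", {
  tr <- random_tree(12, seed = 31, bl = c(0.1, 0.5))
  mod <- build_model("LG", alpha = 0.7)
  aln <- simulate_alignment(tr, mod, 2000, seed = 13)
  a_hat <- estimate_gamma_shape(tr, aln, build_model("LG", alpha = 1))
  expect_gt(as.numeric(a_hat), 0.5)
  expect_lt(as.numeric(a_hat), 0.95)
  # local optimality of the profile at the estimate
  ll_at <- function(a) {
    attr(optimize_branch_lengths(attr(a_hat, "tree"), aln,
                                 build_model("LG", alpha = a)), "loglik")
  }
  expect_gte(attr(a_hat, "loglik") + 1e-6, ll_at(as.numeric(a_hat) + 0.1))
  expect_gte(attr(a_hat, "loglik") + 1e-6, ll_at(as.numeric(a_hat) - 0.1))
})
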