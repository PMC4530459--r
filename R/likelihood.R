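BL_MIN <- 1e-8
BL_MAX <- 10

# put a phylo in postorder with clamped branch lengths and matched tip data
prep_phylo <- function(tree, aln, model) {
  if (!inherits(tree, "phylo")) stop("expected an ape phylo tree", call. = FALSE)
  if (!setequal(tree$tip.label, aln_ids(aln)))
    stop("label mismatch: tree tips and alignment ids differ", call. = FALSE)
  check_model_alphabet(aln, model)
  tree <- ape::reorder.phylo(tree, "postorder")
  el <- tree$edge.length
  if (is.null(el)) el <- rep(0.1, nrow(tree$edge))
  el <- pmin(pmax(el, BL_MIN), BL_MAX)
  states <- encode_states(aln, model)
  list(tree = tree, edge = tree$edge, el = el,
       tipstates = states[tree$tip.label, , drop = FALSE],
       ntip = length(tree$tip.label))
}

model_args <- function(model) {
  list(U = model$eig$U, W = model$eig$W, lambda = model$eig$lambda,
       pi = unname(model$pi),
       rates = discrete_gamma_rates(model$alpha, model$k),
       weights = rep(1 / model$k, model$k))
}

#' Per-column log-likelihoods of an alignment on a fixed tree
#'
#' Felsenstein pruning under the model's rate matrix with `k` discrete-gamma
#' categories of equal weight; the site likelihood is the category average.
#' Gap and unknown characters contribute all-ones partial vectors, so an
#' all-gap column has log-likelihood 0.
#'
#' @param aln a `paraconv_alignment` whose ids equal the tree's tip labels.
#' @param tree an `ape::phylo` tree with branch lengths (substitutions/site).
#' @param model a [build_model()] object compatible with the alphabet.
#' @return numeric vector of site log-likelihoods (length = alignment
#'   columns) with attribute `total`.
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  pp <- prep_phylo(tree, aln, model)
  ma <- model_args(model)
  res <- cpp_site_loglik(pp$edge, pp$el, pp$ntip, pp$tipstates,
                         ma$U, ma$W, ma$lambda, ma$pi, ma$rates, ma$weights)
  out <- as.numeric(res$site)
  attr(out, "total") <- res$total
  out
}

#' Total log-likelihood of an alignment on a fixed tree
#'
#' @inheritParams site_log_likelihoods
#' @return scalar log-likelihood.
#' @export
tree_log_likelihood <- function(aln, tree, model) {
  sum(site_log_likelihoods(aln, tree, model))
}

#' Optimize branch lengths by per-edge Brent iteration
#'
#' Round-robin one-dimensional optimization of each branch length within
#' `[1e-8, 10]`, sweeping the tree until the total log-likelihood improves by
#' less than `tol`.  The returned likelihood never decreases relative to the
#' input lengths.
#'
#' @inheritParams site_log_likelihoods
#' @param tol convergence tolerance on the total log-likelihood (default 1e-4).
#' @param max_sweeps maximum number of optimization sweeps.
#' @return the tree with optimized `edge.length` (postorder), with attributes
#'   `loglik` and `sweeps`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-4,
                                    max_sweeps = 30L) {
  pp <- prep_phylo(tree, aln, model)
  ma <- model_args(model)
  res <- cpp_optim_edges(pp$edge, pp$el, pp$ntip, pp$tipstates,
                         ma$U, ma$W, ma$lambda, ma$pi, ma$rates, ma$weights,
                         BL_MIN, BL_MAX, tol, as.integer(max_sweeps))
  if (!is.finite(res$loglik))
    stop("numeric error: non-finite likelihood during branch optimization",
         call. = FALSE)
  out <- pp$tree
  out$edge.length <- as.numeric(res$el)
  attr(out, "loglik") <- res$loglik
  attr(out, "sweeps") <- res$sweeps
  out
}

#' Maximum-likelihood estimate of the gamma shape parameter
#'
#' One-dimensional bounded search for the discrete-gamma shape (on a log
#' scale), re-optimizing branch lengths at every candidate value.
#'
#' @inheritParams site_log_likelihoods
#' @param bounds search interval for the shape.
#' @param tol tolerance of the outer search (on log alpha).
#' @return the shape estimate, with attributes `loglik` and `tree` (the tree
#'   with branch lengths optimized at the estimate).
#' @export
estimate_gamma_shape <- function(tree, aln, model, bounds = c(0.02, 100),
                                 tol = 0.01) {
  pp <- prep_phylo(tree, aln, model)
  ma <- model_args(model)
  state <- new.env(parent = emptyenv())
  state$el <- pp$el
  obj <- function(la) {
    rates <- discrete_gamma_rates(exp(la), model$k)
    res <- cpp_optim_edges(pp$edge, state$el, pp$ntip, pp$tipstates,
                           ma$U, ma$W, ma$lambda, ma$pi, rates, ma$weights,
                           BL_MIN, BL_MAX, 1e-4, 30L)
    state$el <- as.numeric(res$el)  # warm start the next candidate
    -res$loglik
  }
  opt <- stats::optimize(obj, interval = log(bounds), tol = tol)
  alpha <- exp(opt$minimum)
  rates <- discrete_gamma_rates(alpha, model$k)
  res <- cpp_optim_edges(pp$edge, state$el, pp$ntip, pp$tipstates,
                         ma$U, ma$W, ma$lambda, ma$pi, rates, ma$weights,
                         BL_MIN, BL_MAX, 1e-4, 30L)
  fit_tree <- pp$tree
  fit_tree$edge.length <- as.numeric(res$el)
  structure(alpha, loglik = res$loglik, tree = fit_tree)
}

#' Simulate an alignment along a tree
#'
#' The root state of each column is drawn from the model's equilibrium
#' frequencies and evolved along every branch by the model's transition
#' matrices; each column is independently assigned one of the `k`
#' discrete-gamma rate categories with equal probability, mirroring the
#' discrete-gamma likelihood.  Identical seeds give identical alignments.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param model a [build_model()] object.
#' @param length number of columns to simulate.
#' @param seed integer seed.
#' @return a `paraconv_alignment` with rows named by the tree's tip labels.
#' @export
simulate_alignment <- function(tree, model, length, seed = 1L) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  tree <- ape::reorder.phylo(tree, "postorder")
  el <- pmin(pmax(tree$edge.length, BL_MIN), BL_MAX)
  ns <- base::length(model$states)
  ntip <- base::length(tree$tip.label)
  rates <- discrete_gamma_rates(model$alpha, model$k)
  root <- tree$edge[nrow(tree$edge), 1L]
  withr::with_seed(as.integer(seed), {
    cat_of <- sample.int(model$k, length, replace = TRUE)
    nodes <- matrix(0L, max(tree$edge), length)
    nodes[root, ] <- sample.int(ns, length, replace = TRUE, prob = model$pi)
    # preorder = reversed postorder edge list
    for (e in rev(seq_len(nrow(tree$edge)))) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      for (k in seq_len(model$k)) {
        P <- transition_matrix(model, el[e], rates[k])
        for (s in seq_len(ns)) {
          idx <- which(cat_of == k & nodes[p, ] == s)
          if (base::length(idx))
            nodes[ch, idx] <- sample.int(ns, base::length(idx),
                                         replace = TRUE, prob = P[s, ])
        }
      }
    }
  })
  m <- matrix(model$states[nodes[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(m) <- tree$tip.label
  structure(m, class = "paraconv_alignment", alphabet = model$alphabet)
}
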