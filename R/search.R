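# --- tree surgery -----------------------------------------------------------

# unrooted 3-taxon star (the unique 3-leaf topology)
star3 <- function(labels, bl = 0.1) {
  stopifnot(length(labels) == 3L)
  structure(list(edge = cbind(rep(4L, 3L), 1:3),
                 edge.length = rep(bl, 3L),
                 tip.label = as.character(labels), Nnode = 1L),
            class = "phylo")
}

# graft a new tip onto edge `edge_idx`, splitting it at its midpoint
insert_tip <- function(phy, edge_idx, label, pendant = 0.1) {
  n <- length(phy$tip.label)
  e <- phy$edge
  el <- phy$edge.length
  e[e > n] <- e[e > n] + 1L
  newtip <- n + 1L
  newnode <- n + 1L + phy$Nnode + 1L
  ch <- e[edge_idx, 2L]
  half <- el[edge_idx] / 2
  e[edge_idx, 2L] <- newnode
  el[edge_idx] <- half
  e <- rbind(e, c(newnode, ch), c(newnode, newtip))
  el <- c(el, half, pendant)
  phy$edge <- e
  phy$edge.length <- el
  phy$tip.label <- c(phy$tip.label, label)
  phy$Nnode <- phy$Nnode + 1L
  attr(phy, "order") <- NULL
  phy
}

#' Test whether a leaf set is monophyletic in an unrooted tree
#'
#' Monophyly in the unrooted sense: some branch separates exactly this leaf
#' set from all remaining leaves.  Sets of size < 2 or within one leaf of the
#' full set are trivially monophyletic.
#'
#' @param tree an `ape::phylo`.
#' @param clade character vector of tip labels.
#' @return logical.
#' @export
is_monophyletic_unrooted <- function(tree, clade) {
  tips <- tree$tip.label
  target <- sort(match(intersect(clade, tips), tips))
  k <- length(target)
  if (k < 2L || k > length(tips) - 2L) return(TRUE)
  compl <- setdiff(seq_along(tips), target)
  for (s in ape::prop.part(tree)) {
    ss <- sort(s)
    if (identical(ss, target) || identical(ss, compl)) return(TRUE)
  }
  FALSE
}

# constraint check usable on partially grown trees: only the clade members
# already present are required to form a split
constraint_ok <- function(tree, clade) {
  if (is.null(clade)) return(TRUE)
  present <- intersect(clade, tree$tip.label)
  if (length(present) < 2L) return(TRUE)
  if (length(setdiff(tree$tip.label, present)) < 2L) return(TRUE)
  is_monophyletic_unrooted(tree, present)
}

# the two nearest-neighbour-interchange alternatives around every internal
# edge (edge lengths stay with their position)
nni_neighbors <- function(phy) {
  n <- length(phy$tip.label)
  root <- n + 1L
  e <- phy$edge
  out <- list()
  for (ie in which(e[, 2L] > n)) {
    p <- e[ie, 1L]
    c0 <- e[ie, 2L]
    cedges <- which(e[, 1L] == c0)
    if (p == root) {
      dedges <- setdiff(which(e[, 1L] == p), ie)
      swaps <- list(c(cedges[1L], dedges[1L]), c(cedges[1L], dedges[2L]))
    } else {
      dedge <- setdiff(which(e[, 1L] == p), ie)
      swaps <- list(c(cedges[1L], dedge), c(cedges[2L], dedge))
    }
    for (sw in swaps) {
      e2 <- e
      tmp <- e2[sw[1L], 2L]
      e2[sw[1L], 2L] <- e2[sw[2L], 2L]
      e2[sw[2L], 2L] <- tmp
      ph2 <- phy
      ph2$edge <- e2
      attr(ph2, "order") <- NULL
      out[[length(out) + 1L]] <- ph2
    }
  }
  out
}

# every unrooted topology on the given labels (feasible up to ~8 leaves)
all_topologies <- function(labels, bl = 0.1) {
  if (length(labels) > 8L)
    stop("exhaustive enumeration limited to 8 leaves", call. = FALSE)
  trees <- list(star3(labels[1:3], bl))
  for (i in seq_along(labels)[-(1:3)]) {
    nxt <- list()
    for (tr in trees)
      for (eidx in seq_len(nrow(tr$edge)))
        nxt[[length(nxt) + 1L]] <- insert_tip(tr, eidx, labels[i], bl)
    trees <- nxt
  }
  trees
}

# --- scoring ----------------------------------------------------------------

# evaluation context: encoded states + spectral pieces, built once per search
make_scorer <- function(aln, model) {
  states <- encode_states(aln, model)
  ma <- model_args(model)
  list(
    eval = function(tree) {  # lnL at the tree's current branch lengths
      tree <- ape::reorder.phylo(tree, "postorder")
      el <- pmin(pmax(tree$edge.length, BL_MIN), BL_MAX)
      cpp_site_loglik(tree$edge, el, length(tree$tip.label),
                      states[tree$tip.label, , drop = FALSE],
                      ma$U, ma$W, ma$lambda, ma$pi, ma$rates,
                      ma$weights)$total
    },
    opt = function(tree, tol = 1e-4, max_sweeps = 30L) {
      tree <- ape::reorder.phylo(tree, "postorder")
      el <- pmin(pmax(tree$edge.length, BL_MIN), BL_MAX)
      res <- cpp_optim_edges(tree$edge, el, length(tree$tip.label),
                             states[tree$tip.label, , drop = FALSE],
                             ma$U, ma$W, ma$lambda, ma$pi, ma$rates,
                             ma$weights, BL_MIN, BL_MAX, tol,
                             as.integer(max_sweeps))
      tree$edge.length <- as.numeric(res$el)
      attr(tree, "loglik") <- res$loglik
      tree
    })
}

# canonical topology signature (unrooted): per split, the sorted side not
# containing the alphabetically first tip
topo_key <- function(phy) {
  labs <- phy$tip.label
  first <- labs[order(labs)[1L]]
  sigs <- vapply(ape::prop.part(phy), function(s) {
    side <- labs[s]
    if (first %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = ",")
  }, character(1L))
  paste(sort(sigs), collapse = "|")
}

# --- search -----------------------------------------------------------------

#' Maximum-likelihood tree search, optionally under a monophyly constraint
#'
#' Heuristic search: seeded random-order stepwise addition (each leaf grafted
#' at the log-likelihood-best position among constraint-compatible edges,
#' with a cheap branch-length refresh after every addition), followed by
#' nearest-neighbour interchanges accepting strictly improving moves; with
#' `n_starts` restarts the best tree is returned.  Exhaustive search scores
#' every (constraint-compatible) topology and is available for small leaf
#' sets.  Candidate topologies violating the constraint are rejected
#' throughout, and branch lengths of the returned tree are fully optimized.
#' Ties are broken by the first-encountered candidate in a deterministic
#' traversal order.
#'
#' @inheritParams site_log_likelihoods
#' @param constraint `NULL`, or a character vector of >= 2 tip labels that
#'   must form a clade of the unrooted tree (a proper subset leaving at least
#'   2 labels outside).
#' @param seed integer seed driving the randomized addition orders.
#' @param n_starts number of random-addition starts (heuristic search).
#' @param method `"heuristic"` (default) or `"exhaustive"`.
#' @return an `ape::phylo` with optimized branch lengths and attribute
#'   `loglik`.
#' @export
search_ml_tree <- function(aln, model, constraint = NULL, seed = 1L,
                           n_starts = 3L, method = c("heuristic", "exhaustive")) {
  method <- match.arg(method)
  check_model_alphabet(aln, model)
  labels <- aln_ids(aln)
  n <- length(labels)
  if (n < 4L) stop("need at least 4 sequences for a tree search", call. = FALSE)
  if (!is.null(constraint)) {
    constraint <- as.character(constraint)
    if (!all(constraint %in% labels))
      stop("constraint labels missing from the alignment: ",
           paste(setdiff(constraint, labels), collapse = ", "), call. = FALSE)
    if (length(constraint) < 2L || length(constraint) > n - 2L)
      stop("constraint unsatisfiable: clade must be a proper subset with ",
           ">= 2 labels on each side", call. = FALSE)
  }
  sc <- make_scorer(aln, model)

  labels <- sort(labels)  # results must not depend on alignment row order

  if (method == "exhaustive") {
    cands <- Filter(function(tr) constraint_ok(tr, constraint),
                    all_topologies(labels))
    best <- NULL
    for (tr in cands) {
      fit <- sc$opt(tr)
      if (is.null(best) || attr(fit, "loglik") > attr(best, "loglik"))
        best <- fit
    }
    return(best)
  }

  # full optimizations are memoized by topology: restarts and NNI loops
  # revisit the same candidates, and branch lengths depend only on topology
  memo <- new.env(parent = emptyenv())
  opt_memo <- function(tree) {
    key <- topo_key(tree)
    if (!is.null(memo[[key]])) return(memo[[key]])
    fit <- sc$opt(tree)
    memo[[key]] <- fit
    fit
  }

  best <- NULL
  for (st in seq_len(n_starts)) {
    ord <- withr::with_seed(derive_seed(seed, paste0("start", st)),
                            sample(labels))
    tr <- star3(ord[1:3])
    if (!constraint_ok(tr, constraint)) tr <- star3(ord[c(1, 3, 2)])
    for (lab in ord[-(1:3)]) {
      cand_best <- NULL
      cand_ll <- -Inf
      for (eidx in seq_len(nrow(tr$edge))) {
        cand <- insert_tip(tr, eidx, lab)
        if (!constraint_ok(cand, constraint)) next
        ll <- sc$eval(cand)
        if (ll > cand_ll) { cand_ll <- ll; cand_best <- cand }
      }
      if (is.null(cand_best))
        stop("constraint unsatisfiable during stepwise addition", call. = FALSE)
      tr <- sc$opt(cand_best, tol = 0.1, max_sweeps = 2L)
    }
    tr <- opt_memo(tr)
    cur <- attr(tr, "loglik")
    repeat {
      nbrs <- Filter(function(x) constraint_ok(x, constraint),
                     nni_neighbors(tr))
      if (!length(nbrs)) break
      quick <- vapply(nbrs, sc$eval, numeric(1L))
      improved <- FALSE
      for (i in utils::head(order(quick, decreasing = TRUE), 2L)) {
        fit <- opt_memo(nbrs[[i]])
        if (attr(fit, "loglik") > cur + 1e-6) {
          tr <- fit
          cur <- attr(fit, "loglik")
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    if (is.null(best) || cur > attr(best, "loglik")) best <- tr
  }
  best
}
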