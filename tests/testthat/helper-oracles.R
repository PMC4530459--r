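# Independent oracles: brute-force likelihood by exhaustive enumeration of
# internal-node states, direct-formula t statistics, and a naive quadratic
# window scan.  These deliberately share no code with the package's engine.

# exhaustive-enumeration site log-likelihoods (trees up to ~5 leaves)
oracle_site_loglik <- function(aln, tree, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  el <- pmin(pmax(tree$edge.length, 1e-8), 10)
  rates <- discrete_gamma_rates(model$alpha, model$k)
  s <- length(model$states)
  m <- unclass(aln)[tree$tip.label, , drop = FALSE]
  if (model$alphabet == "NT") m[m == "U"] <- "T"
  enc <- matrix(match(m, model$states), nrow(m))  # NA = gap/unknown
  L <- ncol(enc)
  root <- ntip + 1L
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), nnode)))
  n_assign <- nrow(grid)
  out <- numeric(L)
  for (i in seq_len(L)) {
    Lsite <- 0
    for (k in seq_len(model$k)) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
        transition_matrix(model, el[e], rates[k]))
      prob <- model$pi[grid[, root - ntip]]
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
        px <- grid[, p - ntip]
        if (ch <= ntip) {
          st <- enc[ch, i]
          fac <- if (is.na(st)) rep(1, n_assign) else Ps[[e]][cbind(px, st)]
        } else {
          fac <- Ps[[e]][cbind(px, grid[, ch - ntip])]
        }
        prob <- prob * fac
      }
      Lsite <- Lsite + sum(prob) / model$k
    }
    out[i] <- log(Lsite)
  }
  out
}

# direct-formula Welch t for one window of a vector
oracle_t <- function(x, start, end) {
  a <- x[start:end]
  b <- x[-(start:end)]
  (mean(a) - mean(b)) /
    sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
}

# naive quadratic scan: largest t over all windows of one width
oracle_max_t <- function(x, width) {
  L <- length(x)
  ts <- vapply(seq_len(L - width + 1L), function(s)
    oracle_t(x, s, s + width - 1L), numeric(1L))
  c(max(ts), which.max(ts))
}

# quadrature oracle for discrete-gamma bin means
oracle_gamma_rates <- function(alpha, k) {
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), alpha, alpha)
  r <- vapply(seq_len(k), function(i) {
    stats::integrate(function(x) x * stats::dgamma(x, alpha, alpha),
                     q[i], q[i + 1L], rel.tol = 1e-10)$value * k
  }, numeric(1L))
  r / mean(r)
}
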