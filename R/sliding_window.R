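#' Sliding-window geometry
#'
#' Windows of fixed width advanced by a fixed step, 1-based inclusive;
#' trailing columns not covered by a full window are dropped.  With the
#' default width 50 and step 10 over 230 columns there are 19 windows;
#' window 12 starts at column 111 and window 15 ends at column 190.
#'
#' @param L alignment length.
#' @param width window width in columns (default 50).
#' @param step advance between consecutive windows (default 10).
#' @return data frame with columns `window`, `start`, `end`.
#' @export
make_windows <- function(L, width = 50L, step = 10L) {
  if (width < 1L || width > L)
    stop("window width must lie in 1..", L, call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  starts <- seq.int(1L, L - width + 1L, by = step)
  data.frame(window = seq_along(starts), start = starts,
             end = starts + width - 1L)
}

#' Sliding-window log-likelihood contrast of conversion vs. no conversion
#'
#' The scan contrasts two topological hypotheses in every window:
#' `Tree_global`, the unconstrained ML tree of the full alignment (one
#' topology for all windows, branch lengths re-optimized per window),
#' representing paralog evolution without gene conversion; and `Tree_conv`,
#' the per-window ML tree under the constraint that the putative converted
#' pair forms a clade.  The per-window score is
#' `delta = lnL(Tree_conv) - lnL(Tree_global)`: negative when the global
#' topology explains the window at least as well (no conversion), positive in
#' windows whose columns share the converted history.
#'
#' The gamma shape is estimated once on the full alignment jointly with
#' `Tree_global` and held fixed for all windows and both test trees.
#'
#' @param aln a `paraconv_alignment` (>= 4 sequences).
#' @param conv_clade character vector of >= 2 ids forced monophyletic in
#'   `Tree_conv` (typically the candidate converted paralog pair).
#' @param model a [build_model()] object; its `alpha` is replaced by the
#'   full-alignment estimate unless `alpha` is supplied.
#' @param width,step window geometry, see [make_windows()].
#' @param seed integer seed driving all tree-search randomization.
#' @param n_starts random-addition starts for each per-window constrained
#'   search (default 3).
#' @param n_starts_global random-addition starts for the full-alignment
#'   searches (default 3).
#' @param method `"heuristic"` or `"exhaustive"` tree search (the latter for
#'   small taxon sets).
#' @param tree_global optionally, a precomputed global tree topology (its
#'   branch lengths are re-estimated); by default inferred by unconstrained
#'   search.
#' @param alpha optionally, a fixed gamma shape (skips estimation).
#' @return an object of class `paraconv_profile`: list with `windows` (data
#'   frame `window start end lnl_global lnl_conv delta`), `tree_global`,
#'   `alpha`, `conv_trees` (per-window constrained ML trees), and the call
#'   parameters.
#' @export
delta_lnl_profile <- function(aln, conv_clade, model, width = 50L,
                              step = 10L, seed = 1L, n_starts = 3L,
                              n_starts_global = 3L,
                              method = c("heuristic", "exhaustive"),
                              tree_global = NULL, alpha = NULL) {
  method <- match.arg(method)
  conv_clade <- as.character(conv_clade)
  if (!all(conv_clade %in% aln_ids(aln)))
    stop("conv_clade labels missing from the alignment: ",
         paste(setdiff(conv_clade, aln_ids(aln)), collapse = ", "),
         call. = FALSE)
  if (is.null(tree_global))
    tree_global <- search_ml_tree(aln, model, constraint = NULL,
                                  seed = derive_seed(seed, "global"),
                                  n_starts = n_starts_global, method = method)
  if (is.null(alpha)) {
    alpha_hat <- estimate_gamma_shape(tree_global, aln, model)
    alpha <- as.numeric(alpha_hat)
    tree_global <- attr(alpha_hat, "tree")
  }
  model$alpha <- alpha  # spectral pieces are shape-independent
  wins <- make_windows(aln_length(aln), width, step)
  global_in_constraint <- is_monophyletic_unrooted(tree_global, conv_clade)
  gap_rows <- function(sub) {
    g <- rowSums(unclass(sub) != "-") == 0L
    rownames(unclass(sub))[g]
  }
  lnl_global <- lnl_conv <- numeric(nrow(wins))
  conv_trees <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    sub <- slice_columns(aln, wins$start[i], wins$end[i])
    allgap <- gap_rows(sub)
    if (length(allgap))
      warning("window ", i, ": only gap columns for ",
              paste(allgap, collapse = ", "), call. = FALSE)
    fit_g <- optimize_branch_lengths(tree_global, sub, model)
    lnl_global[i] <- attr(fit_g, "loglik")
    fit_c <- search_ml_tree(sub, model, constraint = conv_clade,
                            seed = derive_seed(seed, paste0("win", i)),
                            n_starts = n_starts, method = method)
    lnl_conv[i] <- attr(fit_c, "loglik")
    conv_trees[[i]] <- fit_c
    # if the global topology itself satisfies the constraint it belongs to
    # the constrained space, so its fit is a lower bound for lnL_conv
    if (global_in_constraint && lnl_global[i] > lnl_conv[i]) {
      lnl_conv[i] <- lnl_global[i]
      conv_trees[[i]] <- fit_g
    }
  }
  wins$lnl_global <- lnl_global
  wins$lnl_conv <- lnl_conv
  wins$delta <- lnl_conv - lnl_global
  structure(list(windows = wins, tree_global = tree_global, alpha = alpha,
                 conv_trees = conv_trees, conv_clade = conv_clade,
                 width = as.integer(width), step = as.integer(step),
                 model_name = model$name, seed = as.integer(seed)),
            class = "paraconv_profile")
}

#' @export
print.paraconv_profile <- function(x, ...) {
  cat("<paraconv_profile> ", nrow(x$windows), " windows (width ", x$width,
      ", step ", x$step, "), model ", x$model_name,
      ", alpha ", signif(x$alpha, 4), "\n", sep = "")
  cat("  delta range: [", signif(min(x$windows$delta), 5), ", ",
      signif(max(x$windows$delta), 5), "]\n", sep = "")
  invisible(x)
}
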