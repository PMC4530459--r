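#' Site-wise log-likelihood table for the two test trees
#'
#' Infers `Tree_global` (unconstrained) and `Tree_conv` (conversion clade
#' forced monophyletic) from the full alignment, and computes per-column
#' log-likelihoods under each.  `delta_site = site_lnl_conv -
#' site_lnl_global` is the input to boundary estimation: columns inside a
#' converted tract tend to prefer `Tree_conv`.
#'
#' The gamma shape is estimated once with `Tree_global` and reused for both
#' trees.
#'
#' @inheritParams delta_lnl_profile
#' @return object of class `paraconv_sitetable`: list with
#'   `site_lnl_global`, `site_lnl_conv`, `delta_site`, `tree_global`,
#'   `tree_conv`, `alpha`, `model_name`.
#' @export
build_site_table <- function(aln, conv_clade, model, seed = 1L,
                             n_starts = 3L,
                             method = c("heuristic", "exhaustive"),
                             alpha = NULL) {
  method <- match.arg(method)
  conv_clade <- as.character(conv_clade)
  if (!all(conv_clade %in% aln_ids(aln)))
    stop("conv_clade labels missing from the alignment", call. = FALSE)
  tree_global <- search_ml_tree(aln, model, constraint = NULL,
                                seed = derive_seed(seed, "global"),
                                n_starts = n_starts, method = method)
  if (is.null(alpha)) {
    alpha_hat <- estimate_gamma_shape(tree_global, aln, model)
    alpha <- as.numeric(alpha_hat)
    tree_global <- attr(alpha_hat, "tree")
  }
  model$alpha <- alpha
  tree_global <- optimize_branch_lengths(tree_global, aln, model)
  tree_conv <- search_ml_tree(aln, model, constraint = conv_clade,
                              seed = derive_seed(seed, "conv"),
                              n_starts = n_starts, method = method)
  # a constraint-satisfying global tree is itself in the constrained space
  if (is_monophyletic_unrooted(tree_global, conv_clade) &&
      attr(tree_global, "loglik") > attr(tree_conv, "loglik"))
    tree_conv <- tree_global
  sg <- site_log_likelihoods(aln, tree_global, model)
  sc <- site_log_likelihoods(aln, tree_conv, model)
  structure(list(site_lnl_global = as.numeric(sg),
                 site_lnl_conv = as.numeric(sc),
                 delta_site = as.numeric(sc) - as.numeric(sg),
                 tree_global = tree_global, tree_conv = tree_conv,
                 alpha = alpha, model_name = model$name,
                 conv_clade = conv_clade),
            class = "paraconv_sitetable")
}

#' @export
print.paraconv_sitetable <- function(x, ...) {
  cat("<paraconv_sitetable> ", length(x$delta_site), " columns, model ",
      x$model_name, ", alpha ", signif(x$alpha, 4), "\n", sep = "")
  cat("  sum(delta_site) = ", signif(sum(x$delta_site), 6), "\n", sep = "")
  invisible(x)
}

#' Welch-form t statistic comparing a window against the rest
#'
#' Tests whether the mean per-site log-likelihood difference inside the
#' window equals the mean outside:
#' `t = (mean_in - mean_out) / sqrt(s2_in/n_in + s2_out/n_out)` with
#' unbiased variances.  If both variances vanish, `t` is 0 for equal means
#' and +/-1e300 otherwise.
#'
#' @param delta_site numeric vector of per-column differences.
#' @param window integer `c(start, end)`, 1-based inclusive; both the window
#'   and its complement must contain >= 2 sites.
#' @return the t statistic.
#' @export
t_statistic <- function(delta_site, window) {
  L <- length(delta_site)
  start <- window[1L]; end <- window[2L]
  if (start < 1L || end > L || start > end)
    stop("coordinate error: window outside 1..", L, call. = FALSE)
  if (end - start + 1L >= L - 1L || end - start + 1L < 2L)
    stop("degenerate-partition error: window and complement each need >= 2 ",
         "sites", call. = FALSE)
  inside <- delta_site[start:end]
  outside <- delta_site[-(start:end)]
  v <- stats::var(inside) / length(inside) + stats::var(outside) / length(outside)
  num <- mean(inside) - mean(outside)
  if (v <= 0) return(if (num == 0) 0 else sign(num) * 1e300)
  num / sqrt(v)
}

#' Boundary estimation by the corrected t statistic
#'
#' Scans every window of every integer width in `[min_width, max_width]`,
#' computing the Welch-form t of [t_statistic()] from per-site
#' log-likelihood differences.  Window-size bias is adjusted by a
#' max-statistic permutation test per width: the site order is permuted
#' `n_perm` times, the largest t over all windows of that width is recorded,
#' and the p-value is the proportion of permuted maxima strictly greater
#' than the observed per-width maximum.  The reported region is the window
#' with the largest t among widths significant at `level`.
#'
#' Permutation streams are independent per width (derived from the master
#' seed by width), so the observed statistics do not depend on the seed.
#'
#' @param table a [build_site_table()] result, or a numeric vector of
#'   per-site differences.
#' @param min_width,max_width inclusive range of window widths (columns).
#' @param n_perm permutations per width (default 10000).
#' @param level significance level for a width to qualify (default 0.01).
#' @param seed master permutation seed.
#' @return object of class `paraconv_boundary`: list with `best_window`
#'   (`c(start, end, width)` or `NULL` when no width is significant),
#'   `t_obs`, `p_value`, `per_width` (data frame `width start end t p`),
#'   `n_perm`, `level`, `seed`.
#' @export
scan_boundaries <- function(table, min_width = 30L, max_width = 90L,
                            n_perm = 10000L, level = 0.01, seed = 1L) {
  x <- if (inherits(table, "paraconv_sitetable")) table$delta_site
       else as.numeric(table)
  L <- length(x)
  if (min_width < 3L) stop("min_width must be >= 3", call. = FALSE)
  if (max_width >= L) stop("max_width must be below the sequence length",
                           call. = FALSE)
  widths <- seq.int(min_width, max_width)
  pw <- data.frame(width = widths, start = NA_integer_, end = NA_integer_,
                   t = NA_real_, p = NA_real_)
  for (i in seq_along(widths)) {
    w <- widths[i]
    obs <- cpp_max_t(x, w)
    pw$t[i] <- obs[1L]
    pw$start[i] <- as.integer(obs[2L])
    pw$end[i] <- as.integer(obs[2L]) + w - 1L
    perm <- withr::with_seed(derive_seed(seed, paste0("width", w)),
                             cpp_perm_max_t(x, w, as.integer(n_perm)))
    pw$p[i] <- mean(perm > obs[1L])
  }
  sig <- which(pw$p < level)
  if (length(sig)) {
    b <- sig[which.max(pw$t[sig])]
    best <- c(start = pw$start[b], end = pw$end[b], width = pw$width[b])
    t_obs <- pw$t[b]
    p_value <- pw$p[b]
  } else {
    best <- NULL
    t_obs <- max(pw$t)
    p_value <- min(pw$p)
  }
  structure(list(best_window = best, t_obs = t_obs, p_value = p_value,
                 per_width = pw, n_perm = as.integer(n_perm), level = level,
                 seed = as.integer(seed)),
            class = "paraconv_boundary")
}

#' @export
print.paraconv_boundary <- function(x, ...) {
  if (is.null(x$best_window)) {
    cat("<paraconv_boundary> no window significant at level ", x$level,
        " (min p = ", signif(x$p_value, 4), ")\n", sep = "")
  } else {
    cat("<paraconv_boundary> best window ", x$best_window[["start"]], "-",
        x$best_window[["end"]], " (width ", x$best_window[["width"]],
        "), t = ", signif(x$t_obs, 5), ", p = ", signif(x$p_value, 4),
        " [", x$n_perm, " permutations]\n", sep = "")
  }
  invisible(x)
}
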