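#' Parametric-bootstrap calibration of the critical window score
#'
#' Simulates `n_reps` replicate alignments on a no-conversion tree (a tree
#' violating the conversion constraint), runs the sliding-window scan on each
#' replicate, and pools all window scores into one empirical null
#' distribution of `delta`.  The critical value of the level-`test_alpha`
#' test is the nearest-rank `(1 - test_alpha)` quantile of the pooled
#' samples, i.e. the `ceiling((1 - test_alpha) * n)`-th order statistic.
#'
#' Simulation and the analysis of the simulated replicates both use
#' `model_sim` (classically a WAG+gamma fit of the original data, with shape
#' and branch lengths taken from the original fit), while the observed data
#' may have been scanned under a different model family.
#'
#' @param tree_global the fitted no-conversion tree (topology and branch
#'   lengths) used as the simulation tree; must violate the constraint.
#' @param model_sim [build_model()] object used both to simulate and to scan
#'   the replicates (its `alpha` should be the fitted shape).
#' @param n_reps number of simulated replicates.
#' @param length alignment length to simulate.
#' @param conv_clade constraint clade, as in [delta_lnl_profile()].
#' @param width,step window geometry.
#' @param test_alpha significance level (default 0.01).
#' @param seed master seed; replicate `r` uses the derived stream
#'   `derive_seed(seed, paste0("rep", r))`.
#' @param per_window if `TRUE`, also compute one critical value per window
#'   position from that window's own null samples.
#' @param ... further arguments passed to [delta_lnl_profile()] (e.g.
#'   `method`, `n_starts`).
#' @return object of class `paraconv_null`: list with `samples` (matrix
#'   n_reps x windows of null deltas), `critical`, `test_alpha`, `n_reps`,
#'   `width`, `step`, `sim_model`, `seed`, and optionally
#'   `critical_per_window`.
#' @export
calibrate <- function(tree_global, model_sim, n_reps, length, conv_clade,
                      width = 50L, step = 10L, test_alpha = 0.01, seed = 1L,
                      per_window = FALSE, ...) {
  conv_clade <- as.character(conv_clade)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (is_monophyletic_unrooted(tree_global, conv_clade))
    stop("misconfiguration: the simulation tree satisfies the conversion ",
         "constraint, so the null would be degenerate", call. = FALSE)
  n_win <- nrow(make_windows(length, width, step))
  samples <- matrix(NA_real_, n_reps, n_win)
  for (r in seq_len(n_reps)) {
    rs <- derive_seed(seed, paste0("rep", r))
    sim <- simulate_alignment(tree_global, model_sim, length, seed = rs)
    prof <- delta_lnl_profile(sim, conv_clade, model_sim, width = width,
                              step = step, seed = rs, ...)
    samples[r, ] <- prof$windows$delta
  }
  pooled <- as.numeric(samples)
  crit <- nearest_rank_quantile(pooled, 1 - test_alpha)
  out <- list(samples = samples, critical = crit, test_alpha = test_alpha,
              n_reps = as.integer(n_reps), width = as.integer(width),
              step = as.integer(step), sim_model = model_sim$name,
              seed = as.integer(seed))
  if (per_window)
    out$critical_per_window <- apply(samples, 2L, nearest_rank_quantile,
                                     p = 1 - test_alpha)
  structure(out, class = "paraconv_null")
}

# nearest-rank empirical quantile: the ceiling(p * n)-th order statistic
nearest_rank_quantile <- function(x, p) {
  n <- length(x)
  sort(x)[max(1L, ceiling(p * n))]
}

#' @export
print.paraconv_null <- function(x, ...) {
  cat("<paraconv_null> ", length(x$samples), " pooled window scores from ",
      x$n_reps, " replicates (", x$sim_model, ")\n", sep = "")
  cat("  critical delta at level ", x$test_alpha, ": ",
      signif(x$critical, 6), "\n", sep = "")
  invisible(x)
}

#' Flag windows whose score exceeds the calibrated critical value
#'
#' A window is significant iff its `delta` is strictly greater than the
#' critical value (a score exactly at the critical value is not flagged).
#'
#' @param profile a [delta_lnl_profile()] result.
#' @param null a [calibrate()] result with the same window geometry.
#' @return logical vector, one flag per window, with attribute `critical`.
#' @export
test_windows <- function(profile, null) {
  if (profile$width != null$width || profile$step != null$step)
    stop("configuration error: window geometry of profile and null differ",
         call. = FALSE)
  flags <- profile$windows$delta > null$critical
  attr(flags, "critical") <- null$critical
  flags
}
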