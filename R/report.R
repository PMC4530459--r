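#' Write a run manifest
#'
#' Every pipeline output directory gets one JSON manifest recording the
#' stage name, the full parameter set (including all seeds), md5 checksums
#' of any file inputs, the package version and a wall-clock timestamp —
#' enough to replay the run bit-identically on the same platform.
#'
#' @param dir output directory (created if needed).
#' @param stage stage name (e.g. `"simulate"`, `"scan"`, `"null"`,
#'   `"boundary"`).
#' @param params named list of parameters (must include any seeds used).
#' @param inputs character vector of input file paths to checksum.
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, stage, params, inputs = character(0L)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    stage = stage,
    params = params,
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs)) else stats::setNames(list(), character(0L)),
    package = "paraconv",
    version = as.character(utils::packageVersion("paraconv")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write sliding-window scan outputs
#'
#' Emits `profile.tsv` (`window start end lnL_global lnL_conv delta`),
#' `tree_global.nwk`, and one Newick per-window conversion tree under
#' `conv_trees/`.
#'
#' @param profile a [delta_lnl_profile()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_profile <- function(profile, dir) {
  dir.create(file.path(dir, "conv_trees"), recursive = TRUE,
             showWarnings = FALSE)
  tab <- profile$windows
  names(tab) <- c("window", "start", "end", "lnL_global", "lnL_conv",
                  "delta")
  utils::write.table(tab, file.path(dir, "profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(profile$tree_global, file.path(dir, "tree_global.nwk"))
  for (i in seq_along(profile$conv_trees))
    ape::write.tree(profile$conv_trees[[i]],
                    file.path(dir, "conv_trees",
                              sprintf("window_%02d.nwk", i)))
  invisible(dir)
}

#' Write parametric-bootstrap null outputs
#'
#' Emits `null_samples.tsv` (one row per replicate, one column per window)
#' and `null_summary.json` with the critical value.
#'
#' @param null a [calibrate()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_null <- function(null, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- as.data.frame(null$samples)
  names(samples) <- paste0("window_", seq_len(ncol(samples)))
  utils::write.table(cbind(rep = seq_len(nrow(samples)), samples),
                     file.path(dir, "null_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(critical = null$critical, test_alpha = null$test_alpha,
         n_samples = length(null$samples), n_reps = null$n_reps,
         sim_model = null$sim_model, seed = null$seed),
    file.path(dir, "null_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write boundary-estimation outputs
#'
#' Emits `per_width.tsv` (`width start end t p`) and `boundary.json`.
#'
#' @param boundary a [scan_boundaries()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_boundary <- function(boundary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(boundary$per_width, file.path(dir, "per_width.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bw <- boundary$best_window
  jsonlite::write_json(
    list(best_start = if (is.null(bw)) NULL else unname(bw[["start"]]),
         best_end = if (is.null(bw)) NULL else unname(bw[["end"]]),
         best_width = if (is.null(bw)) NULL else unname(bw[["width"]]),
         t = boundary$t_obs, p = boundary$p_value,
         n_perm = boundary$n_perm, level = boundary$level,
         seed = boundary$seed),
    file.path(dir, "boundary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write synthetic-scenario outputs
#'
#' Emits `alignment.fasta`, `tree_global.nwk`, `tree_conv.nwk` and a JSON
#' truth record.
#'
#' @param generated result of [generate()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment(generated$alignment, file.path(dir, "alignment.fasta"))
  writeLines(generated$truth$tree_global_newick,
             file.path(dir, "tree_global.nwk"))
  writeLines(generated$truth$tree_conv_newick,
             file.path(dir, "tree_conv.nwk"))
  sc <- generated$truth$scenario
  jsonlite::write_json(
    list(n_pairs = sc$n_pairs, total_length = sc$total_length,
         tract = sc$tract, direction = sc$direction,
         conv_pair = sc$conv_pair, model = sc$model$name,
         gamma_shape = sc$model$alpha, depth_scale = sc$depth_scale,
         conv_clade = sc$conv_clade, seed = sc$seed,
         tree_global = generated$truth$tree_global_newick,
         tree_conv = generated$truth$tree_conv_newick),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
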