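#' Template no-conversion and conversion trees for paralog pairs
#'
#' Builds the pair of test-tree templates the detector assumes.  The
#' no-conversion tree (`tree_global`) has two mirrored paralog clades — an
#' A clade and a B clade with identical topology over `n_pairs` leaves each,
#' leaf `pairK_A` matching `pairK_B` — joined by a long inter-paralog branch
#' of length `2 * depth_scale`, with all intra-clade branch lengths drawn
#' from a seeded exponential with mean `depth_scale`.  The conversion tree
#' (`tree_conv`) equals `tree_global` with the recipient leaf of the
#' converted pair pruned and regrafted as the sister of its paralog partner
#' (the partner's pendant branch is split at its midpoint and the recipient
#' receives a pendant of the same length).
#'
#' @param n_pairs number of paralog pairs (>= 3).
#' @param conv_pair index of the converted pair.
#' @param direction `"donor_B_to_A"` (the A-copy receives the tract and
#'   moves into the B clade) or `"donor_A_to_B"`.
#' @param depth_scale mean intra-clade branch length, substitutions/site.
#' @param seed integer seed (same seed, same branch lengths).
#' @return list with elements `tree_global`, `tree_conv` (both `ape::phylo`,
#'   unrooted, `2 * n_pairs` leaves), `recipient`, `partner` and
#'   `conv_clade`.
#' @export
template_trees <- function(n_pairs = 6L, conv_pair = 1L,
                           direction = c("donor_B_to_A", "donor_A_to_B"),
                           depth_scale = 0.3, seed = 1L) {
  direction <- match.arg(direction)
  if (n_pairs < 3L) stop("need at least 3 paralog pairs", call. = FALSE)
  if (conv_pair < 1L || conv_pair > n_pairs)
    stop("conv_pair out of range", call. = FALSE)
  tg <- withr::with_seed(derive_seed(seed, "template"), {
    shape <- ape::rtree(n_pairs, rooted = TRUE)
    # the converted pair must be nested within its family, not adjacent to
    # the inter-paralog junction: a junction-adjacent focal pair makes the
    # topological contrast degenerate (per-window branch re-optimization can
    # mimic the conversion), a regime the detector's design excludes
    unit <- shape
    unit$edge.length <- rep(1, nrow(shape$edge))
    depth <- ape::node.depth.edgelength(unit)[seq_len(n_pairs)]
    pair_of_tip <- integer(n_pairs)
    pair_of_tip[which.max(depth)] <- conv_pair
    pair_of_tip[pair_of_tip == 0L] <- setdiff(seq_len(n_pairs), conv_pair)
    a <- shape; a$tip.label <- paste0("pair", pair_of_tip, "_A")
    b <- shape; b$tip.label <- paste0("pair", pair_of_tip, "_B")
    a$edge.length <- stats::rexp(nrow(a$edge), rate = 1 / depth_scale)
    b$edge.length <- stats::rexp(nrow(b$edge), rate = 1 / depth_scale)
    nwk <- paste0("(", sub(";$", "", ape::write.tree(a)), ":", depth_scale,
                  ",", sub(";$", "", ape::write.tree(b)), ":", depth_scale,
                  ");")
    ape::unroot(ape::read.tree(text = nwk))
  })
  recipient <- paste0("pair", conv_pair,
                      if (direction == "donor_B_to_A") "_A" else "_B")
  partner <- paste0("pair", conv_pair,
                    if (direction == "donor_B_to_A") "_B" else "_A")
  tc <- ape::drop.tip(tg, recipient)
  pidx <- which(tc$edge[, 2L] == match(partner, tc$tip.label))
  tc <- insert_tip(tc, pidx, recipient,
                   pendant = tc$edge.length[pidx] / 2)
  list(tree_global = tg, tree_conv = tc, recipient = recipient,
       partner = partner, conv_clade = sort(c(recipient, partner)))
}

#' Ground-truth scenario for a synthetic gene-conversion data set
#'
#' Describes the generating process: a no-conversion tree for the columns
#' outside the converted tract, a conversion tree (recipient leaf sister to
#' its partner) for the columns inside, the tract coordinates, direction,
#' model and seed.  Defaults emulate a 6-pair, 230-column release-factor
#' alignment with a conversion tract at columns 111-190.
#'
#' @inheritParams template_trees
#' @param total_length alignment length in columns.
#' @param tract integer `c(start, end)` (1-based inclusive) or `NULL` for no
#'   conversion.
#' @param model [build_model()] object used to simulate (default LG with
#'   gamma shape 0.7).
#' @param tree_global,tree_conv optional explicit trees; by default built by
#'   [template_trees()].
#' @param seed master seed for the scenario (trees, outside columns, tract
#'   columns use derived streams).
#' @return object of class `paraconv_scenario`.
#' @export
conversion_scenario <- function(n_pairs = 6L, total_length = 230L,
                                tract = c(111L, 190L),
                                direction = c("donor_B_to_A", "donor_A_to_B"),
                                conv_pair = 1L, model = NULL,
                                depth_scale = 0.3, tree_global = NULL,
                                tree_conv = NULL, seed = 1L) {
  direction <- match.arg(direction)
  if (is.null(model)) model <- build_model("LG", alpha = 0.7)
  if (!is.null(tract)) {
    if (length(tract) != 2L || tract[1L] > tract[2L] || tract[1L] < 1L ||
        tract[2L] > total_length)
      stop("tract must be c(start, end) within 1..", total_length,
           call. = FALSE)
    tract <- as.integer(tract)
  }
  tpl <- NULL
  if (is.null(tree_global) || is.null(tree_conv)) {
    tpl <- template_trees(n_pairs, conv_pair, direction, depth_scale, seed)
    if (is.null(tree_global)) tree_global <- tpl$tree_global
    if (is.null(tree_conv)) tree_conv <- tpl$tree_conv
  }
  recipient <- paste0("pair", conv_pair,
                      if (direction == "donor_B_to_A") "_A" else "_B")
  partner <- paste0("pair", conv_pair,
                    if (direction == "donor_B_to_A") "_B" else "_A")
  conv_clade <- sort(c(recipient, partner))
  if (!setequal(tree_global$tip.label, tree_conv$tip.label))
    stop("tree_global and tree_conv must share a leaf set", call. = FALSE)
  if (!is_monophyletic_unrooted(tree_conv, conv_clade))
    stop("tree_conv must satisfy the conversion constraint", call. = FALSE)
  structure(list(n_pairs = as.integer(n_pairs),
                 total_length = as.integer(total_length), tract = tract,
                 direction = direction, conv_pair = as.integer(conv_pair),
                 model = model, depth_scale = depth_scale,
                 tree_global = tree_global, tree_conv = tree_conv,
                 recipient = recipient, partner = partner,
                 conv_clade = conv_clade, seed = as.integer(seed)),
            class = "paraconv_scenario")
}

#' @export
print.paraconv_scenario <- function(x, ...) {
  cat("<paraconv_scenario> ", x$n_pairs, " pairs x ", x$total_length,
      " columns, ", x$model$name, " model\n", sep = "")
  if (is.null(x$tract)) cat("  no conversion tract\n")
  else cat("  tract ", x$tract[1L], "-", x$tract[2L], " (", x$direction,
           ", pair ", x$conv_pair, ")\n", sep = "")
  invisible(x)
}

#' Generate a synthetic alignment with an implanted conversion tract
#'
#' Columns outside the tract are simulated on the no-conversion tree,
#' columns inside on the conversion tree (both under the scenario's model,
#' with per-region seed streams), and assembled in coordinate order — so
#' the tract's history is exactly the constrained topology the detector
#' tests.  Optionally an anchored motif block is inserted after
#' `motif_anchor`: the converted pair receives a shared 12-residue segment,
#' all other sequences a 4-residue segment (gap-padded), mimicking the
#' length-variant loop that flags conversion candidates in real data.
#'
#' @param scenario a [conversion_scenario()].
#' @param insert_motif insert the labelled motif block (default `FALSE`;
#'   the sliding-window alignments of interest exclude motif columns).
#' @param motif_anchor column after which the motif block is inserted.
#' @return list with `alignment` (a `paraconv_alignment`) and `truth` (the
#'   scenario plus Newick strings of both trees and, if inserted, the motif
#'   truth labels).
#' @export
generate <- function(scenario, insert_motif = FALSE, motif_anchor = 150L) {
  stopifnot(inherits(scenario, "paraconv_scenario"))
  L <- scenario$total_length
  model <- scenario$model
  if (is.null(scenario$tract)) {
    aln <- simulate_alignment(scenario$tree_global, model, L,
                              seed = derive_seed(scenario$seed, "outside"))
  } else {
    s <- scenario$tract[1L]; e <- scenario$tract[2L]
    w <- e - s + 1L
    inside <- simulate_alignment(scenario$tree_conv, model, w,
                                 seed = derive_seed(scenario$seed, "tract"))
    m <- matrix("", nrow(inside), L)
    rownames(m) <- rownames(inside)
    if (w < L) {
      outside <- simulate_alignment(scenario$tree_global, model, L - w,
                                    seed = derive_seed(scenario$seed,
                                                       "outside"))
      out_cols <- setdiff(seq_len(L), s:e)
      m[, out_cols] <- unclass(outside)[rownames(m), ]
    }
    m[, s:e] <- unclass(inside)
    aln <- structure(m, class = "paraconv_alignment",
                     alphabet = model$alphabet)
  }
  truth <- list(scenario = scenario,
                tree_global_newick = ape::write.tree(scenario$tree_global),
                tree_conv_newick = ape::write.tree(scenario$tree_conv),
                conv_clade = scenario$conv_clade)
  if (insert_motif) {
    res <- withr::with_seed(derive_seed(scenario$seed, "motif"), {
      ids <- aln_ids(aln)
      block <- matrix("-", length(ids), 12L, dimnames = list(ids, NULL))
      classes <- stats::setNames(rep("4aa", length(ids)), ids)
      for (id in ids) {
        len <- if (id %in% scenario$conv_clade) 12L else 4L
        block[id, seq_len(len)] <- sample(aa_states(), len, replace = TRUE)
        classes[id] <- if (len == 12L) "12aa" else "4aa"
      }
      # the converted pair shares one motif copy
      block[scenario$conv_clade[2L], ] <- block[scenario$conv_clade[1L], ]
      list(block = block, classes = classes)
    })
    m <- unclass(aln)
    m2 <- cbind(m[, seq_len(motif_anchor), drop = FALSE], res$block,
                m[, (motif_anchor + 1L):L, drop = FALSE])
    colnames(m2) <- NULL
    aln <- structure(m2, class = "paraconv_alignment",
                     alphabet = model$alphabet)
    truth$motif <- list(left_anchor = as.integer(motif_anchor),
                        right_anchor = as.integer(motif_anchor + 13L),
                        classes = res$classes)
  }
  list(alignment = aln, truth = truth)
}

#' Read or write a scenario as a flat key-value configuration file
#'
#' One `key value` pair per line (whitespace-separated; `tract` takes two
#' values, or `none`); lines starting with `#` are comments.  Recognized
#' keys: `n_pairs`, `total_length`, `tract`, `direction`, `conv_pair`,
#' `model`, `gamma_shape`, `depth_scale`, `seed`.  Missing keys take the
#' [conversion_scenario()] defaults.
#'
#' @param path config file path.
#' @return [read_scenario_config()] returns a `paraconv_scenario`.
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s+")
  keys <- vapply(kv, `[`, character(1L), 1L)
  vals <- lapply(kv, `[`, -1L)
  names(vals) <- keys
  num <- function(key, default) {
    if (is.null(vals[[key]])) default else as.numeric(vals[[key]][1L])
  }
  tract <- if (is.null(vals$tract) ||
               identical(tolower(vals$tract[1L]), "none"))
    c(111L, 190L) else as.integer(vals$tract[1:2])
  if (!is.null(vals$tract) && identical(tolower(vals$tract[1L]), "none"))
    tract <- NULL
  model_name <- if (is.null(vals$model)) "LG" else vals$model[1L]
  conversion_scenario(
    n_pairs = as.integer(num("n_pairs", 6)),
    total_length = as.integer(num("total_length", 230)),
    tract = tract,
    direction = if (is.null(vals$direction)) "donor_B_to_A"
                else vals$direction[1L],
    conv_pair = as.integer(num("conv_pair", 1)),
    model = build_model(model_name, alpha = num("gamma_shape", 0.7)),
    depth_scale = num("depth_scale", 0.3),
    seed = as.integer(num("seed", 1)))
}

#' @rdname read_scenario_config
#' @param scenario a `paraconv_scenario`.
#' @return [write_scenario_config()] returns `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "paraconv_scenario"))
  lines <- c(
    paste("n_pairs", scenario$n_pairs),
    paste("total_length", scenario$total_length),
    paste("tract", if (is.null(scenario$tract)) "none"
          else paste(scenario$tract, collapse = " ")),
    paste("direction", scenario$direction),
    paste("conv_pair", scenario$conv_pair),
    paste("model", scenario$model$name),
    paste("gamma_shape", scenario$model$alpha),
    paste("depth_scale", scenario$depth_scale),
    paste("seed", scenario$seed))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble an n-pair alignment from a pool of paralog pairs
#'
#' Restricts a pooled alignment to one focal pair plus a chosen set of
#' background pairs (the sensitivity design varies the background count:
#' 3, 5, 7 or 9 pairs).  Columns are unchanged.
#'
#' @param pool_aln alignment containing all candidate sequences.
#' @param focal_pair character vector of the focal pair's two ids.
#' @param background_pairs character vector (or list of pairs) of background
#'   ids.
#' @return a `paraconv_alignment` with `2 * (1 + n_background_pairs)` rows.
#' @export
make_npair_alignment <- function(pool_aln, focal_pair, background_pairs) {
  ids <- c(as.character(focal_pair), unlist(background_pairs,
                                            use.names = FALSE))
  missing <- setdiff(ids, aln_ids(pool_aln))
  if (length(missing))
    stop("identifier error: ids not in pool: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pool_aln[ids, ]
}
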