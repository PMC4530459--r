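# Fixture builders (everything generated in code; no stored data files).

# random alignment of i.i.d. columns, optionally with gaps
random_alignment <- function(n_seq, n_col, alphabet = "AA", gap_frac = 0,
                             seed = 1) {
  chars <- switch(alphabet,
                  AA = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]],
                  NT = c("A", "C", "G", "T"),
                  RY = c("R", "Y"))
  withr::with_seed(seed, {
    m <- matrix(sample(chars, n_seq * n_col, replace = TRUE), n_seq, n_col)
    if (gap_frac > 0) {
      idx <- sample(length(m), round(gap_frac * length(m)))
      m[idx] <- "-"
    }
    rownames(m) <- paste0("seq", seq_len(n_seq))
    alignment(m, alphabet)
  })
}

# random unrooted tree with given tip count and branch-length range
random_tree <- function(n, seed = 1, bl = c(0.05, 0.6)) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), bl[1L], bl[2L])
    tr
  })
}

# the same model with a different gamma shape
mod_at <- function(model, alpha) {
  model$alpha <- alpha
  model
}

quartet <- function(bl = 0.2) {
  ape::read.tree(text = sprintf(
    "((a:%f,b:%f):%f,c:%f,d:%f);", bl, bl, bl, bl, bl))
}
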