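#' Classify the anchored indel motif carried by each sequence
#'
#' Extracts, for every sequence, the non-gap residues strictly between two
#' anchor columns and labels the sequence by the exact length of that
#' segment (e.g. classes `c("4" = "4aa", "7" = "7aa", "12" = "12aa")` for
#' the short/intermediate/long loop variants of release-factor domain 3).
#' A fully gapped segment is `"absent"`; a length matching no class is
#' `"unclassified"`.  Classification depends only on the non-gap count, not
#' on gap placement within the segment; the raw segment is retained for
#' inspection.
#'
#' @param aln a `paraconv_alignment`.
#' @param left_anchor,right_anchor anchor columns (1-based); the motif
#'   occupies the columns strictly between them.  Defaults 150 and 151, the
#'   columns flanking the excluded motif block of a 230-column release-factor
#'   alignment.
#' @param classes named character vector mapping segment length (as the
#'   name) to a class label.
#' @return data frame with columns `id`, `motif_class`, `segment`,
#'   `segment_length`.
#' @export
classify_motifs <- function(aln, left_anchor = 150L, right_anchor = 151L,
                            classes = c("4" = "4aa", "7" = "7aa",
                                        "12" = "12aa")) {
  L <- aln_length(aln)
  if (left_anchor < 1L || right_anchor > L || left_anchor >= right_anchor)
    stop("anchor error: need 1 <= left_anchor < right_anchor <= ", L,
         call. = FALSE)
  m <- unclass(aln)
  cols <- if (right_anchor - left_anchor > 1L)
    (left_anchor + 1L):(right_anchor - 1L) else integer(0L)
  seg <- apply(m[, cols, drop = FALSE], 1L, function(r)
    paste(r[r != "-"], collapse = ""))
  len <- nchar(seg)
  lab <- ifelse(len == 0L, "absent",
                ifelse(is.na(classes[as.character(len)]), "unclassified",
                       classes[as.character(len)]))
  data.frame(id = rownames(m), motif_class = unname(lab),
             segment = unname(seg), segment_length = unname(len),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition sequence ids by motif class
#'
#' @param calls result of [classify_motifs()].
#' @return named list of disjoint id vectors keyed by class label; their
#'   union is the full id set.
#' @export
motif_partition <- function(calls) {
  if (nrow(calls) == 0L) return(structure(list(), names = character(0L)))
  split(calls$id, calls$motif_class)
}
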