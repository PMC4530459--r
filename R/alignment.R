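#' Multiple sequence alignment container
#'
#' A `paraconv_alignment` is a rectangular character matrix (rows = sequences,
#' columns = alignment positions, 1-based inclusive coordinates throughout)
#' with unique row names (sequence identifiers) and an `alphabet` attribute,
#' one of `"AA"`, `"NT"` or `"RY"`.  Gaps are `-`; unknown characters are `X`
#' (amino acid) or `N` (nucleotide).
#'
#' @param seqs named character vector of equal-length sequence strings, or a
#'   character matrix of single characters with row names.
#' @param alphabet one of `"AA"`, `"NT"`, `"RY"`.
#' @return an object of class `paraconv_alignment`.
#' @export
alignment <- function(seqs, alphabet = c("AA", "NT", "RY")) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop("alignment-shape error: rows have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- ids
  }
  if (is.null(rownames(mat)) || anyNA(rownames(mat)))
    stop("identifier error: sequences must be named", call. = FALSE)
  if (anyDuplicated(rownames(mat)))
    stop("identifier error: duplicate sequence identifiers: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "),
         call. = FALSE)
  structure(mat, class = "paraconv_alignment", alphabet = alphabet)
}

#' @export
print.paraconv_alignment <- function(x, ...) {
  cat("<paraconv_alignment> ", nrow(x), " sequences x ", ncol(x),
      " columns (", attr(x, "alphabet"), ")\n", sep = "")
  invisible(x)
}

#' @rdname alignment
#' @param aln a `paraconv_alignment`.
#' @export
aln_ids <- function(aln) rownames(aln)

#' @rdname alignment
#' @export
aln_length <- function(aln) ncol(aln)

#' @rdname alignment
#' @export
aln_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1L, paste, collapse = ""), rownames(aln))
}

#' Read an alignment from FASTA or relaxed sequential PHYLIP
#'
#' The PHYLIP dialect is relaxed: names are whitespace-delimited tokens of any
#' length (no 10-character truncation), each record on one line (sequence may
#' contain internal whitespace).
#'
#' @param path file path.
#' @param format `"fasta"`, `"phylip"`, or `"auto"` (sniff the first
#'   non-blank character).
#' @param alphabet alphabet of the data, see [alignment()].
#' @return a `paraconv_alignment`; input record order is preserved.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip"),
                           alphabet = c("AA", "NT", "RY")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, seqtype = if (alphabet == "AA") "AA" else "DNA",
                               as.string = TRUE, forceDNAtolower = FALSE,
                               seqonly = FALSE)
    seqs <- toupper(vapply(recs, as.character, character(1L)))
    names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1L))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- scan(text = lines[1L], what = integer(), n = 2L, quiet = TRUE)
    if (length(hdr) != 2L)
      stop("alignment-shape error: malformed PHYLIP header", call. = FALSE)
    body <- lines[-1L]
    if (length(body) != hdr[1L])
      stop("alignment-shape error: expected ", hdr[1L], " sequences, found ",
           length(body), call. = FALSE)
    ids <- character(hdr[1L]); seqs <- character(hdr[1L])
    for (i in seq_along(body)) {
      toks <- strsplit(trimws(body[i]), "\\s+")[[1L]]
      ids[i] <- toks[1L]
      seqs[i] <- toupper(paste(toks[-1L], collapse = ""))
    }
    if (any(nchar(seqs) != hdr[2L]))
      stop("alignment-shape error: sequence length disagrees with header",
           call. = FALSE)
    names(seqs) <- ids
  }
  alignment(seqs, alphabet)
}

#' Write an alignment to FASTA or relaxed sequential PHYLIP
#'
#' @inheritParams read_alignment
#' @param aln a `paraconv_alignment`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- aln_strings(aln)
  if (format == "fasta") {
    seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                        file.out = path, nbchar = 60)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(length(seqs), aln_length(aln)), con)
    writeLines(paste(names(seqs), seqs), con)
  }
  invisible(path)
}

#' Extract a contiguous block of alignment columns
#'
#' Coordinates are 1-based and inclusive: `slice_columns(aln, 116, 186)`
#' returns 71 columns.
#'
#' @param aln a `paraconv_alignment`.
#' @param start,end first and last column to keep.
#' @return a `paraconv_alignment` of length `end - start + 1`.
#' @export
slice_columns <- function(aln, start, end) {
  L <- aln_length(aln)
  if (start < 1L || end > L || start > end)
    stop("coordinate error: [", start, ", ", end, "] outside 1..", L,
         call. = FALSE)
  out <- unclass(aln)[, start:end, drop = FALSE]
  structure(out, class = "paraconv_alignment", alphabet = attr(aln, "alphabet"))
}

#' Concatenate two alignments column-wise, matching rows by identifier
#'
#' @param aln_a,aln_b alignments over the same identifier set (row order may
#'   differ; `aln_b` rows are joined to `aln_a` rows by id).
#' @return a `paraconv_alignment` of length `length(a) + length(b)` in the row
#'   order of `aln_a`.
#' @export
concat <- function(aln_a, aln_b) {
  if (!setequal(aln_ids(aln_a), aln_ids(aln_b)))
    stop("identifier error: alignments have different id sets", call. = FALSE)
  if (ncol(aln_b) == 0L) return(aln_a)
  if (ncol(aln_a) == 0L) return(aln_b[aln_ids(aln_b), , drop = FALSE])
  out <- cbind(unclass(aln_a),
               unclass(aln_b)[aln_ids(aln_a), , drop = FALSE])
  structure(out, class = "paraconv_alignment", alphabet = attr(aln_a, "alphabet"))
}

#' @export
`[.paraconv_alignment` <- function(x, i, j, ...) {
  out <- unclass(x)[i, j, drop = FALSE]
  structure(out, class = "paraconv_alignment", alphabet = attr(x, "alphabet"))
}

#' Recode a nucleotide alignment to purine/pyrimidine (RY) characters
#'
#' A and G become `R`; C and T become `Y`; gaps stay gaps; every other
#' character (ambiguity codes, `N`) becomes unknown (`N`).  RY recoding
#' removes transition signal and is the standard remedy for G+C-content
#' heterogeneity across lineages.
#'
#' @param aln_nt a nucleotide (`NT`) `paraconv_alignment`.
#' @return an `RY` `paraconv_alignment`.
#' @export
ry_recode <- function(aln_nt) {
  if (!attr(aln_nt, "alphabet") %in% c("NT", "RY"))
    stop("alphabet error: RY recoding requires a nucleotide alignment",
         call. = FALSE)
  m <- unclass(aln_nt)
  out <- matrix("N", nrow(m), ncol(m), dimnames = dimnames(m))
  out[m %in% c("A", "G", "R")] <- "R"
  out[m %in% c("C", "T", "U", "Y")] <- "Y"
  out[m == "-"] <- "-"
  structure(out, class = "paraconv_alignment", alphabet = "RY")
}

#' Screen sequences whose G+C content departs from the across-sequence mean
#'
#' For each sequence the G+C fraction `p` is computed over its unambiguous
#' bases (A, C, G, T/U only; gaps and ambiguity codes are excluded from the
#' denominator), with a Wald normal-approximation confidence interval
#' `p +/- z * sqrt(p (1 - p) / n)`.  A sequence is flagged when the grand
#' mean of the per-sequence fractions lies outside its interval.
#'
#' @param aln_nt a nucleotide alignment.
#' @param conf confidence level of the interval (default 0.95).
#' @return a data frame with columns `id`, `gc`, `n`, `ci_low`, `ci_high`,
#'   `flagged`, plus attributes `grand_mean`, `conf` and `ci_method`.
#' @export
gc_screen <- function(aln_nt, conf = 0.95) {
  if (attr(aln_nt, "alphabet") != "NT")
    stop("alphabet error: G+C screening requires a nucleotide alignment",
         call. = FALSE)
  m <- unclass(aln_nt)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n_base <- rowSums(matrix(m %in% c("A", "C", "G", "T", "U"), nrow(m)))
  if (any(n_base == 0L))
    stop("degenerate-sequence error: no unambiguous bases in ",
         paste(rownames(m)[n_base == 0L], collapse = ", "), call. = FALSE)
  n_gc <- rowSums(matrix(m %in% c("G", "C"), nrow(m)))
  p <- n_gc / n_base
  half <- z * sqrt(p * (1 - p) / n_base)
  grand <- mean(p)
  out <- data.frame(id = rownames(m), gc = p, n = n_base,
                    ci_low = p - half, ci_high = p + half,
                    flagged = grand < p - half | grand > p + half,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "grand_mean") <- grand
  attr(out, "conf") <- conf
  attr(out, "ci_method") <- "wald"
  out
}

#' Write a G+C screening report as TSV
#'
#' @param report result of [gc_screen()].
#' @param path output file.
#' @export
write_gc_report <- function(report, path) {
  out <- report[, c("id", "gc", "ci_low", "ci_high", "flagged")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
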