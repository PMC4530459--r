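test_that("FASTA and PHYLIP writing then reading is the identity", {
  aln <- random_alignment(12, 230, "AA", gap_frac = 0.03, seed = 5)
  for (fmt in c("fasta", "phylip")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_alignment(aln, path, fmt)
    back <- read_alignment(path, fmt, "AA")
    expect_identical(aln_strings(back), aln_strings(aln))
    expect_identical(aln_ids(back), aln_ids(aln))
    expect_equal(aln_length(back), 230L)
  }
})

test_that("format auto-detection distinguishes FASTA from PHYLIP", {
  aln <- random_alignment(4, 30, "NT", seed = 2)
  fa <- tempfile(); ph <- tempfile()
  write_alignment(aln, fa, "fasta")
  write_alignment(aln, ph, "phylip")
  expect_identical(aln_strings(read_alignment(fa, alphabet = "NT")),
                   aln_strings(read_alignment(ph, alphabet = "NT")))
})

test_that("malformed inputs are rejected with shape/identifier errors", {
  f <- tempfile()
  writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGTACGTA"), f)
  expect_error(read_alignment(f, "fasta", "NT"), "shape")
  writeLines(c(">s1", "ACGTACGTAC", ">s1", "ACGTACGTAC"), f)
  expect_error(read_alignment(f, "fasta", "NT"), "identifier")
  writeLines(c("2 10", "s1 ACGTACGTAC", "s2 ACGTACG"), f)
  expect_error(read_alignment(f, "phylip", "NT"), "shape")
  expect_error(read_alignment(tempfile(), "fasta"), "not found")
})

test_that("column slicing uses 1-based inclusive coordinates", {
  aln <- random_alignment(6, 230, "AA", seed = 3)
  expect_equal(aln_length(slice_columns(aln, 116, 186)), 71L)
  expect_equal(aln_length(slice_columns(aln, 111, 190)), 80L)
  expect_identical(aln_strings(slice_columns(aln, 1, 230)),
                   aln_strings(aln))
  expect_error(slice_columns(aln, 0, 10), "coordinate")
  expect_error(slice_columns(aln, 200, 231), "coordinate")
  expect_error(slice_columns(aln, 50, 40), "coordinate")
})

test_that("concat joins rows by id and adds lengths", {
  a <- random_alignment(5, 40, "NT", seed = 4)
  b <- random_alignment(5, 25, "NT", seed = 9)
  ab <- concat(a, b)
  expect_equal(aln_length(ab), 65L)
  expect_identical(unname(substr(aln_strings(ab)["seq2"], 41, 65)),
                   unname(aln_strings(b)["seq2"]))
  # permuted row order in the second argument gives the same result
  b_perm <- b[rev(aln_ids(b)), ]
  expect_identical(aln_strings(concat(a, b_perm)), aln_strings(ab))
  # zero-length second argument is the identity
  empty <- b[, 0]
  expect_identical(aln_strings(concat(a, empty)), aln_strings(a))
  names_off <- b
  rownames(names_off)[1L] <- "other"
  expect_error(concat(a, names_off), "identifier")
})

test_that("slicing then concatenating reassembles the original block", {
  aln <- random_alignment(4, 100, "AA", seed = 8)
  left <- slice_columns(aln, 10, 49)
  right <- slice_columns(aln, 50, 80)
  expect_identical(aln_strings(concat(left, right)),
                   aln_strings(slice_columns(aln, 10, 80)))
})

test_that("RY recoding maps purines/pyrimidines and is idempotent in effect", {
  aln <- alignment(c(x = "ACGT-", y = "NNAGG", z = "TTTTT"), "NT")
  ry <- ry_recode(aln)
  expect_identical(attr(ry, "alphabet"), "RY")
  expect_identical(unname(aln_strings(ry)),
                   c("RYRY-", "NNRRR", "YYYYY"))
  # an all-purine row becomes constant R
  expect_identical(unname(aln_strings(ry)["z"]), "YYYYY")
  # recoding an already-recoded alignment is the identity
  expect_identical(aln_strings(ry_recode(ry)), aln_strings(ry))
  expect_error(ry_recode(random_alignment(2, 5, "AA")), "alphabet")
})

test_that("G+C screening matches the closed-form Wald interval", {
  # p = 0.5 over n = 100 unambiguous bases
  s <- paste(rep(c("G", "A"), 50), collapse = "")
  aln <- alignment(c(a = s, b = s, c = s), "NT")
  rep <- gc_screen(aln)
  expect_equal(rep$gc, rep(0.5, 3))
  expect_equal(rep$ci_low, rep(0.5 - 1.959964 * sqrt(0.25 / 100), 3),
               tolerance = 1e-6)
  expect_equal(rep$ci_high, rep(0.598, 3), tolerance = 1e-3)
  # all sequences identical: the grand mean equals every p, nothing flagged
  expect_false(any(rep$flagged))
})

test_that("G+C outliers relative to the grand mean are flagged", {
  # one sequence at p ~ 0.595 among many near 0.52: half-width at n = 3729
  # is ~0.0158, so the grand mean falls outside its interval
  n <- 3729
  make_seq <- function(p) {  # exact composition, no sampling noise
    k <- round(p * n)
    paste(c(rep("G", k), rep("A", n - k)), collapse = "")
  }
  seqs <- c(hot = make_seq(0.595),
            stats::setNames(rep(make_seq(0.53), 20), paste0("bg", 1:20)))
  rep <- gc_screen(alignment(seqs, "NT"))
  expect_true(rep$flagged[rep$id == "hot"])
  expect_false(any(rep$flagged[rep$id != "hot"]))
  # flag count invariant under row reordering
  rep2 <- gc_screen(alignment(seqs[c(15, 1, 3, 2, 21, 9, 4:8, 10:14,
                                     16:20)], "NT"))
  expect_equal(sum(rep2$flagged), sum(rep$flagged))
  # gap-only sequences are rejected
  expect_error(gc_screen(alignment(c(x = "----", y = "ACGT"), "NT")),
               "degenerate")
})

test_that("the G+C report round-trips through its TSV form", {
  aln <- random_alignment(5, 60, "NT", seed = 12)
  rep <- gc_screen(aln)
  path <- tempfile(fileext = ".tsv")
  write_gc_report(rep, path)
  back <- utils::read.delim(path)
  expect_identical(names(back), c("id", "gc", "ci_low", "ci_high", "flagged"))
  expect_equal(back$gc, rep$gc, tolerance = 1e-12)
})
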