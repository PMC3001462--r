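test_that("FASTA and Stockholm round-trip and parse errors surface", {
  aln <- new_alignment(c("s1", "s2", "s3"),
                       c("AC-DEF", "ACQDEF", "AC-D-F"))
  for (fmt in c("fasta", "stockholm")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_alignment(aln, path, fmt)
    back <- read_alignment(path, fmt)
    expect_identical(back$ids, aln$ids)
    expect_identical(back$mat, aln$mat)
  }
  # normalisation: lowercase, dots, odd letters
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a desc", "ac.d", ">b", "ACBD"), f)
  got <- read_alignment(f, "fasta")
  expect_identical(got$ids, c("a", "b"))
  expect_identical(unname(got$mat[1, ]), c("A", "C", "-", "D"))
  expect_identical(unname(got$mat[2, 3]), "X")  # B is not a residue letter
  # shape / id errors
  writeLines(c(">a", "ACDE", ">b", "ACD"), f)
  expect_error(read_alignment(f, "fasta"), "alignment-shape")
  writeLines(c(">a", "ACDE", ">a", "ACDE"), f)
  expect_error(read_alignment(f, "fasta"), "duplicate")
  writeLines(character(0), f)
  expect_error(read_alignment(f, "fasta"), "empt")
  s <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "one  QWERTYQWER", "//"), s)
  expect_identical(n_columns(read_alignment(s, "stockholm")), 10L)
})

test_that("position-based weights match hand enumeration and symmetries", {
  # {"AA","AA","AC"}: col 1 gives 1/3 each; col 2 gives 1/4, 1/4, 1/2;
  # sums (7/12, 7/12, 5/6), normalised by the max
  aln <- new_alignment(c("a", "b", "c"), c("AA", "AA", "AC"))
  w <- compute_weights(aln, "position_based")
  expect_equal(unname(w$weights), c(7 / 12, 7 / 12, 5 / 6) / (5 / 6))
  expect_equal(w$effective_count, sum(w$weights))
  expect_gt(w$weights[["c"]], w$weights[["a"]])  # unique sequence up-weighted
  # identical sequences get identical weights
  aln2 <- new_alignment(c("a", "b"), c("QWERTY", "QWERTY"))
  w2 <- compute_weights(aln2, "position_based")
  expect_equal(w2$weights[["a"]], w2$weights[["b"]])
  # uniform: effective count = record count
  expect_equal(compute_weights(aln, "uniform")$effective_count, 3)
  # weights in (0, 1], max exactly 1
  expect_true(all(w$weights > 0 & w$weights <= 1))
  expect_equal(max(w$weights), 1)
})

test_that("column profiles are weighted, gap-aware and sum to one", {
  aln <- new_alignment(c("a", "b"), c("QQ-", "QE-"))
  w <- structure(list(weights = c(a = 1, b = 0.5), effective_count = 1.5,
                      method = "uniform"), class = "seq_weights")
  prof <- column_profile(aln, w)
  expect_equal(unname(prof$freq[1, "Q"]), 1)
  expect_equal(unname(prof$freq[2, "Q"]), 2 / 3)
  expect_equal(unname(prof$freq[2, "E"]), 1 / 3)
  # all-gap column: NA frequencies, gap_fraction 1 (not an error)
  expect_true(all(is.na(prof$freq[3, ])))
  expect_equal(prof$gap_fraction[3], 1)
  # gap handling: (Q, -) at equal weight -> freq 1 conditional, gap 0.5
  aln2 <- new_alignment(c("a", "b"), c("QA", "-A"))
  p2 <- column_profile(aln2, compute_weights(aln2, "uniform"))
  expect_equal(unname(p2$freq[1, "Q"]), 1)
  expect_equal(p2$gap_fraction[1], 0.5)
  # X counts as missing, not a residue bin
  aln3 <- new_alignment(c("a", "b"), c("QA", "XA"))
  p3 <- column_profile(aln3, compute_weights(aln3, "uniform"))
  expect_equal(unname(p3$freq[1, "Q"]), 1)
  expect_equal(p3$gap_fraction[1], 0.5)
})

test_that("profile rows sum to one for random subsets (conservation law)", {
  set.seed(42)
  g <- generate_msa(synth_msa_config(n_fore = 15, n_back = 25, L = 30,
                                     gap_rate = 0.1, seed = 9))
  w <- compute_weights(g$alignment, "position_based")
  for (k in 1:5) {
    subset <- sample(g$alignment$ids, sample(2:30, 1))
    prof <- column_profile(g$alignment, w, subset)
    sums <- rowSums(prof$freq)
    ok <- !is.na(sums)
    expect_true(all(abs(sums[ok] - 1) < 1e-9))
    expect_true(all(prof$gap_fraction >= 0 & prof$gap_fraction <= 1))
  }
})

test_that("duplicating sequences barely moves position-based frequencies", {
  # at the benchmark diversity (250 distinct sequences) a ten-fold
  # duplication shifts every weighted column frequency by under 0.02
  g <- generate_msa(synth_msa_config(gap_rate = 0, seed = 4))
  aln <- g$alignment
  w0 <- compute_weights(aln, "position_based")
  base <- column_profile(aln, w0, aln$ids)
  set.seed(1)
  dup <- sample(aln$ids, 1)
  k <- 10
  ids2 <- c(aln$ids, paste0(dup, "_copy", seq_len(k)))
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  aln2 <- new_alignment(ids2, c(seqs, rep(seqs[dup], k)))
  w2 <- compute_weights(aln2, "position_based")
  prof2 <- column_profile(aln2, w2, ids2)
  expect_lt(max(abs(prof2$freq - base$freq), na.rm = TRUE), 0.02)
})

test_that("column-to-reference mapping honours gaps and the signal offset", {
  aln <- new_alignment(c("ref", "q"), c("-ACD-", "AACDE"))
  rm24 <- map_columns(aln, "ref", 24)
  expect_equal(rm24$refpos, c(NA, 25L, 26L, 27L, NA))
  rm0 <- map_columns(new_alignment(c("r", "q"), c("AC", "AC")), "r", 0)
  expect_equal(rm0$refpos, c(1L, 2L))
  # strictly increasing over mapped columns
  mapped <- rm24$refpos[!is.na(rm24$refpos)]
  expect_true(all(diff(mapped) > 0))
  expect_error(map_columns(aln, "nope"), "lookup")
})

test_that("partition label files round-trip including query labels", {
  part <- new_partition(c(a = "fore", b = "fore", c = "back"))
  part$query_ids <- "a"
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, f)
  back <- read_partition(f)
  expect_equal(back$membership, part$membership)
  expect_equal(back$query_ids, "a")
  writeLines("a\tmiddle", f)
  expect_error(read_partition(f), "unknown partition label")
})
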