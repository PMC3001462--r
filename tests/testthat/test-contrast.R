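test_that("ball-in-urn score matches closed forms and direct summation", {
  # P(X >= 0) = 1
  expect_equal(ball_in_urn_score(0, 50, 0.5), 0)
  # all 50 of 50 at p = 1/2: (1/2)^50
  expect_equal(ball_in_urn_score(50, 50, 0.5), 50 * log10(2),
               tolerance = 1e-12)
  # 8 of 10 at p = 0.2 against the brute-force tail sum
  expect_equal(ball_in_urn_score(8, 10, 0.2),
               oracle_binom_tail_score(8, 10, 0.2), tolerance = 1e-12)
  # weighted counts round half-up
  expect_equal(ball_in_urn_score(7.5, 10.2, 0.2),
               oracle_binom_tail_score(8, 10, 0.2), tolerance = 1e-12)
  # no underflow deep in the tail (scores beyond 300)
  expect_gt(ball_in_urn_score(500, 500, 0.01), 300)
  expect_true(is.finite(ball_in_urn_score(500, 500, 0.01)))
  # domain errors
  expect_error(ball_in_urn_score(5, 3, 0.5), "domain")
  expect_error(ball_in_urn_score(1, 3, 1.5), "domain")
})

test_that("score is monotone in n_match and antitone in p_back", {
  p <- seq(0.05, 0.95, by = 0.05)
  s_p <- ball_in_urn_score(30, 40, p)
  expect_true(all(diff(s_p) <= 1e-12))
  k <- 0:40
  s_k <- ball_in_urn_score(k, 40, 0.3)
  expect_true(all(diff(s_k) >= -1e-12))
})

test_that("continuous beta tail agrees with the binomial at integer counts", {
  # the regularised-incomplete-beta alternative reproduces the exact
  # binomial tail when the counts are whole numbers
  for (k in c(1, 5, 9)) {
    expect_equal(ball_in_urn_score(k, 10, 0.2, tail = "beta"),
                 ball_in_urn_score(k, 10, 0.2, tail = "binomial"),
                 tolerance = 1e-9)
  }
  # and interpolates smoothly between them
  s <- ball_in_urn_score(c(4, 4.5, 5), 10, 0.2, tail = "beta")
  expect_true(s[1] < s[2] && s[2] < s[3])
})

test_that("select_pattern finds planted single- and multi-residue sets", {
  n <- 50
  fore <- stats::setNames(rep(0, 20), AMINO_ACIDS)
  back <- fore
  fore["Q"] <- 1
  back[c("A", "L", "S")] <- 1 / 3
  call <- select_pattern(fore, back, n, p_floor = 1e-3)
  expect_identical(call$pattern_set, "Q")
  expect_true(call$selected)
  expect_equal(call$score, oracle_binom_tail_score(50, 50, 1e-3),
               tolerance = 1e-9)
  # a two-residue pattern beats both singletons
  fore2 <- stats::setNames(rep(0, 20), AMINO_ACIDS)
  fore2[c("Y", "F")] <- 0.5
  back2 <- stats::setNames(rep(0.9 / 18, 20), AMINO_ACIDS)
  back2[c("Y", "F")] <- 0.05
  call2 <- select_pattern(fore2, back2, n, p_floor = 1e-3)
  expect_identical(call2$pattern_set, "FY")
  oracle2 <- oracle_select_pattern(fore2, back2, n, 1e-3)
  expect_identical(call2$pattern_set, oracle2$key)
  # identical fore and back profiles: essentially no contrast
  same <- stats::setNames(rep(0.05, 20), AMINO_ACIDS)
  call3 <- select_pattern(same, same, n, p_floor = 1e-3)
  expect_false(call3$selected)
  # all-gap foreground column: unselected, score 0
  gap <- stats::setNames(rep(NA_real_, 20), AMINO_ACIDS)
  call4 <- select_pattern(gap, same, 0)
  expect_false(call4$selected)
  expect_equal(call4$score, 0)
})

test_that("select_pattern matches exhaustive enumeration on random profiles", {
  set.seed(101)
  for (rep in 1:25) {
    n_total <- sample(5:20, 1)
    fore <- stats::setNames(as.numeric(stats::rmultinom(1, n_total,
                            rep(1, 20))) / n_total, AMINO_ACIDS)
    back <- stats::setNames(as.numeric(stats::rgamma(20, 0.4)), AMINO_ACIDS)
    back <- back / sum(back)
    got <- select_pattern(fore, back, n_total, p_floor = 1e-3)
    want <- oracle_select_pattern(fore, back, n_total, 1e-3)
    expect_identical(got$pattern_set, want$key)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("contrast analysis recovers planted columns and maps positions", {
  bench <- run_benchmark_contrast(seed = 3)
  planted <- bench$gen$truth$pattern_columns
  expect_gte(length(intersect(bench$selected, planted)), 9)
  expect_lte(length(setdiff(bench$selected, planted)), 1)
  # histogram: heights in [0,1], argmax at the top-scoring selected column
  h <- bench$result$histogram
  expect_true(all(h >= 0 & h <= 1))
  expect_equal(which.max(h),
               bench$result$calls$column[which.max(
                 ifelse(bench$result$calls$selected,
                        bench$result$calls$score, -Inf))])
  # refpos carried through a reference map
  aln <- bench$gen$alignment
  rmap <- map_columns(aln, aln$ids[1], 24)
  res2 <- contrast_analysis(aln, bench$gen$partition, bench$weights, rmap)
  expect_equal(res2$calls$refpos, rmap$refpos)
  # foreground == background composition -> nothing selected
  ids <- paste0("s", 1:8)
  seqs <- rep(c("QWERTYQW", "QWERTYQA"), 4)
  dup <- new_alignment(ids, seqs)
  part <- new_partition(stats::setNames(rep(c("fore", "back"), each = 4),
                                        ids))
  res3 <- contrast_analysis(dup, part, compute_weights(dup, "uniform"))
  expect_equal(sum(res3$calls$selected), 0)
  expect_true(all(res3$histogram == 0))
  # configuration errors
  expect_error(contrast_analysis(dup, new_partition(
    stats::setNames(c("fore", rep("back", 7)), ids))), "at least 2")
})

test_that("single planted column dominates the histogram", {
  g <- generate_msa(synth_msa_config(n_pattern = 1, seed = 8))
  res <- contrast_analysis(g$alignment, g$partition)
  expect_equal(which.max(res$histogram), g$truth$pattern_columns)
  expect_equal(max(res$histogram), 1)
})

test_that("selected columns survive foreground duplication under weighting", {
  bench <- run_benchmark_contrast(seed = 2)
  aln <- bench$gen$alignment
  set.seed(7)
  dup <- sample(names(bench$gen$partition$membership)[
    bench$gen$partition$membership == "fore"], 1)
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  aln2 <- new_alignment(c(aln$ids, paste0(dup, "_d", 1:10)),
                        c(seqs, rep(seqs[dup], 10)))
  part2 <- new_partition(c(bench$gen$partition$membership,
                           stats::setNames(rep("fore", 10),
                                           paste0(dup, "_d", 1:10))))
  res2 <- contrast_analysis(aln2, part2,
                            compute_weights(aln2, "position_based"))
  expect_identical(which(res2$calls$selected), bench$selected)
})

test_that("jackknife stability reports overlap and boundary cases", {
  bench <- run_benchmark_contrast(seed = 1)
  part <- bench$gen$partition
  fore_ids <- names(part$membership)[part$membership == "fore"]
  # empty group: overlap exactly 1
  rep0 <- jackknife_stability(bench$gen$alignment, part, character(0),
                              bench$weights)
  expect_equal(rep0$jaccard_overlap, 1)
  # removing 25% of the foreground barely changes the pattern
  set.seed(11)
  rep1 <- jackknife_stability(bench$gen$alignment, part,
                              sample(fore_ids, 13), bench$weights)
  expect_gte(rep1$jaccard_overlap, 0.9)
  expect_length(rep1$score_delta, n_columns(bench$gen$alignment))
  # removing all but 2 is legal (wide deltas expected, just no error)
  rep2 <- jackknife_stability(bench$gen$alignment, part,
                              fore_ids[-(1:2)], bench$weights)
  expect_s3_class(rep2, "stability_report")
  # exhausting the foreground is not
  expect_error(jackknife_stability(bench$gen$alignment, part,
                                   fore_ids[-1], bench$weights),
               "configuration error")
  expect_error(jackknife_stability(bench$gen$alignment, part,
                                   c("back_001"), bench$weights),
               "non-foreground")
})

test_that("contrast TSV output carries calls and metadata sidecar", {
  bench <- run_benchmark_contrast(seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contrast(bench$result, f, seed = 5)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 100)
  expect_true(all(c("column", "pattern_set", "score", "selected",
                    "p_back") %in% names(tab)))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$weighting, "position_based")
  expect_equal(meta$n_fore, 50)
  expect_equal(meta$seed, 5)
})
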