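# Foreground/background conservation contrast: per-column ball-in-urn
# divergence scores, pattern-set selection and jackknife stability.

#' Construct a foreground/background partition
#'
#' @param membership named character vector mapping every sequence id to
#'   `"fore"` or `"back"`.
#' @param source `"given"` (user-supplied) or `"sampled"` (inferred by
#'   [sample_partition()]).
#' @return An object of class `"partition_spec"`.
#' @export
new_partition <- function(membership, source = c("given", "sampled")) {
  source <- match.arg(source)
  membership <- vapply(membership, as.character, character(1))
  if (is.null(names(membership)) || any(!nzchar(names(membership)))) {
    stop("membership must be named by sequence id")
  }
  if (!all(membership %in% c("fore", "back"))) {
    stop("membership values must be 'fore' or 'back'")
  }
  structure(list(membership = membership, source = source,
                 query_ids = character(0)),
            class = "partition_spec")
}

#' @export
print.partition_spec <- function(x, ...) {
  cat(sprintf("Partition (%s): %d foreground, %d background sequences\n",
              x$source, sum(x$membership == "fore"),
              sum(x$membership == "back")))
  invisible(x)
}

#' Configuration for the contrast analysis
#'
#' @param max_set_size largest residue-set size considered per column
#'   (default 3).
#' @param score_threshold minimum ball-in-urn score (in -log10 units) for a
#'   column to be selected as a pattern position (default 10).
#' @param min_fore_conservation minimum weighted foreground frequency of the
#'   pattern set for selection (default 0.6).
#' @param pseudocount additive pseudocount used by the partition sampler's
#'   per-class match likelihoods (default 0.5).
#' @param tail `"binomial"` scores the rounded weighted counts with an exact
#'   binomial tail; `"beta"` uses the continuous analogue (regularised
#'   incomplete beta on the unrounded counts).
#' @param p_floor background-frequency floor; `NULL` (default) means
#'   `1 / (2 * effective background count)`, computed at analysis time.
#' @return A list of class `"contrast_config"`.
#' @export
contrast_config <- function(max_set_size = 3L, score_threshold = 10,
                            min_fore_conservation = 0.6, pseudocount = 0.5,
                            tail = c("binomial", "beta"), p_floor = NULL) {
  tail <- match.arg(tail)
  stopifnot(max_set_size >= 1L, score_threshold >= 0,
            min_fore_conservation >= 0, min_fore_conservation <= 1,
            pseudocount > 0)
  structure(list(max_set_size = as.integer(max_set_size),
                 score_threshold = score_threshold,
                 min_fore_conservation = min_fore_conservation,
                 pseudocount = pseudocount, tail = tail, p_floor = p_floor),
            class = "contrast_config")
}

#' Ball-in-urn divergence score
#'
#' The column statistic at the heart of the contrast analysis. Imagine
#' drawing `n_total` balls from an urn in which a fraction `p_back` of balls
#' match the pattern residue set (the background composition); the score is
#' the negative log10 probability of drawing at least `n_match` matching
#' balls, i.e. the upper binomial tail
#' \deqn{-\log_{10} P(X \ge k), \quad X \sim \mathrm{Binomial}(n, p)}
#' with `k = round(n_match)`, `n = round(n_total)` (round half up, since the
#' counts are weighted and generally non-integer) and
#' `p = max(p_back, p_floor)`. With `tail = "beta"` the unrounded counts are
#' used via the regularised incomplete beta function
#' \eqn{I_p(n_{match}, n_{total}-n_{match}+1)}. A score of 0 is returned
#' when `n_match` rounds to 0 (the tail probability is 1). The tail is
#' evaluated in log space, so scores of several hundred do not underflow.
#'
#' @param n_match weighted number of foreground sequences matching the
#'   pattern set (vectorised).
#' @param n_total weighted number of non-gap foreground sequences.
#' @param p_back weighted background frequency of the pattern set, in
#'   \[0, 1\].
#' @param p_floor lower floor applied to `p_back` (default `1e-6`), so that
#'   a pattern residue entirely absent from the background yields a large
#'   finite score.
#' @param tail `"binomial"` (default) or `"beta"`; see
#'   [contrast_config()].
#' @return Non-negative numeric score(s), `-log10` of the tail probability.
#' @examples
#' ball_in_urn_score(50, 50, 0.5)   # 50 * log10(2) ~ 15.05
#' ball_in_urn_score(0, 50, 0.5)    # 0
#' @export
ball_in_urn_score <- function(n_match, n_total, p_back, p_floor = 1e-6,
                              tail = c("binomial", "beta")) {
  tail <- match.arg(tail)
  n <- max(length(n_match), length(n_total), length(p_back))
  n_match <- rep_len(n_match, n)
  n_total <- rep_len(n_total, n)
  p_back <- rep_len(p_back, n)
  if (any(n_match < 0) || any(n_total < 0)) {
    stop("domain error: counts must be non-negative")
  }
  if (any(n_match > n_total + 1e-9)) {
    stop("domain error: n_match exceeds n_total")
  }
  if (any(p_back < 0) || any(p_back > 1)) {
    stop("domain error: p_back outside [0, 1]")
  }
  p <- pmin(pmax(p_back, p_floor), 1)
  if (tail == "binomial") {
    k <- floor(n_match + 0.5)
    nn <- floor(n_total + 0.5)
    k <- pmin(k, nn)
    out <- numeric(n)
    pos <- k > 0
    out[pos] <- -stats::pbinom(k[pos] - 1, nn[pos], p[pos],
                               lower.tail = FALSE, log.p = TRUE) / log(10)
  } else {
    out <- numeric(n)
    pos <- n_match > 0
    # P(X >= k) = I_p(k, n - k + 1), continuous in the weighted counts
    out[pos] <- -stats::pbeta(p[pos], n_match[pos],
                              n_total[pos] - n_match[pos] + 1,
                              log.p = TRUE) / log(10)
  }
  pmax(out, 0)
}

# All residue subsets of size <= max_set_size over the given letters,
# as a list of integer index vectors into `letters` (kept in sorted order
# so ties resolve alphabetically).
residue_subsets <- function(n_letters, max_set_size) {
  sets <- lapply(seq_len(n_letters), function(i) i)
  for (m in seq_len(max_set_size)[-1]) {
    if (n_letters >= m) {
      cmb <- utils::combn(n_letters, m, simplify = FALSE)
      sets <- c(sets, cmb)
    }
  }
  sets
}

#' Select the most divergent residue set for one column
#'
#' Enumerates every residue set of size up to `config$max_set_size` drawn
#' from the residues observed in the foreground, scores each with
#' [ball_in_urn_score()] (foreground weighted match count against the
#' background set frequency), and returns the maximiser. Ties are broken
#' deterministically: smaller set first, then alphabetical residue order.
#' The call is `selected` when the score reaches
#' `config$score_threshold` and the foreground set frequency reaches
#' `config$min_fore_conservation`.
#'
#' @param fore_freq named numeric vector of foreground residue frequencies
#'   for the column (conditional on non-gap; `NA` for an all-gap column).
#' @param back_freq background frequencies, same form.
#' @param n_fore_total weighted number of non-gap foreground sequences at
#'   the column.
#' @param config a [contrast_config()].
#' @param p_floor background-frequency floor (see [ball_in_urn_score()]).
#' @return A one-row data.frame: `pattern_set` (residues pasted in
#'   alphabetical order), `n_fore_match`, `n_fore_total`, `fore_freq`,
#'   `p_back` (floored set frequency actually scored), `score`, `selected`.
#' @export
select_pattern <- function(fore_freq, back_freq, n_fore_total,
                           config = contrast_config(), p_floor = 1e-6) {
  empty <- data.frame(pattern_set = "", n_fore_match = 0,
                      n_fore_total = n_fore_total, fore_freq = NA_real_,
                      p_back = NA_real_, score = 0, selected = FALSE,
                      stringsAsFactors = FALSE)
  if (is.null(n_fore_total) || n_fore_total <= 0 || all(is.na(fore_freq))) {
    empty$n_fore_total <- max(n_fore_total, 0)
    return(empty)
  }
  fore_freq <- fore_freq[AMINO_ACIDS]
  back_freq <- back_freq[AMINO_ACIDS]
  back_freq[is.na(back_freq)] <- 0  # all-gap background column
  present <- which(!is.na(fore_freq) & fore_freq > 0)
  if (!length(present)) return(empty)
  letters <- AMINO_ACIDS[present]
  sets <- residue_subsets(length(letters), config$max_set_size)
  ff <- unname(fore_freq[letters])
  bf <- unname(back_freq[letters])
  set_ff <- vapply(sets, function(s) sum(ff[s]), numeric(1))
  set_bf <- vapply(sets, function(s) sum(bf[s]), numeric(1))
  scores <- ball_in_urn_score(set_ff * n_fore_total, n_fore_total,
                              pmin(set_bf, 1), p_floor = p_floor,
                              tail = config$tail)
  sizes <- lengths(sets)
  keys <- vapply(sets, function(s) paste(letters[s], collapse = ""),
                 character(1))
  best <- order(-scores, sizes, keys)[1L]
  s <- sets[[best]]
  data.frame(pattern_set = keys[best],
             n_fore_match = set_ff[best] * n_fore_total,
             n_fore_total = n_fore_total,
             fore_freq = set_ff[best],
             p_back = min(max(set_bf[best], p_floor), 1),
             score = scores[best],
             selected = scores[best] >= config$score_threshold &&
               set_ff[best] >= config$min_fore_conservation,
             stringsAsFactors = FALSE)
}

#' Foreground/background contrast analysis of an alignment
#'
#' Runs [select_pattern()] on every alignment column, contrasting the
#' weighted residue composition of the foreground sequences against the
#' background, and assembles the per-column calls, the normalised score
#' histogram used for rendering, and the profiles. The background frequency
#' floor defaults to `1 / (2 * effective background count)` so a residue
#' never observed in the background still has a finite urn probability.
#'
#' @param aln an `"msa"` object.
#' @param part a `"partition_spec"` covering all ids, with at least two
#'   sequences in each class.
#' @param w a `"seq_weights"` object; `NULL` (default) computes Henikoff
#'   position-based weights.
#' @param refmap optional `"reference_map"` attaching reference residue
#'   numbers to the calls.
#' @param config a [contrast_config()].
#' @return An object of class `"contrast_result"`: list with `calls` (one
#'   row per column: `column` (1-based), `refpos`, `pattern_set`,
#'   `n_fore_match`, `n_fore_total`, `fore_freq`, `p_back`, `score`,
#'   `selected`), `histogram` (per-column heights in \[0, 1\], the selected
#'   column scores divided by their maximum, 0 elsewhere), `fore_profile`,
#'   `back_profile`, `partition`, `weights`, `config`, `p_floor`.
#' @export
contrast_analysis <- function(aln, part, w = NULL, refmap = NULL,
                              config = contrast_config()) {
  miss <- setdiff(aln$ids, names(part$membership))
  if (length(miss)) stop("configuration error: partition does not cover: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  fore_ids <- intersect(aln$ids, names(part$membership)[part$membership == "fore"])
  back_ids <- intersect(aln$ids, names(part$membership)[part$membership == "back"])
  if (length(fore_ids) < 2L || length(back_ids) < 2L) {
    stop("configuration error: each class needs at least 2 sequences")
  }
  if (is.null(w)) w <- compute_weights(aln, "position_based")
  fore <- column_profile(aln, w, fore_ids)
  back <- column_profile(aln, w, back_ids)
  p_floor <- config$p_floor
  if (is.null(p_floor)) p_floor <- 1 / (2 * sum(w$weights[back_ids]))
  L <- n_columns(aln)
  calls <- vector("list", L)
  for (j in seq_len(L)) {
    calls[[j]] <- select_pattern(fore$freq[j, ], back$freq[j, ],
                                 fore$n_eff[j], config, p_floor)
  }
  calls <- do.call(rbind, calls)
  calls <- cbind(data.frame(column = seq_len(L),
                            refpos = if (is.null(refmap)) NA_integer_
                                     else refmap$refpos),
                 calls)
  hist <- numeric(L)
  if (any(calls$selected)) {
    top <- max(calls$score[calls$selected])
    hist[calls$selected] <- calls$score[calls$selected] / top
  }
  structure(list(calls = calls, histogram = hist,
                 fore_profile = fore, back_profile = back,
                 partition = part, weights = w, config = config,
                 p_floor = p_floor, refmap = refmap),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  sel <- x$calls[x$calls$selected, , drop = FALSE]
  cat(sprintf(paste0("Contrast analysis: %d columns, %d pattern positions ",
                     "(score >= %.1f, fore conservation >= %.2f)\n"),
              nrow(x$calls), nrow(sel), x$config$score_threshold,
              x$config$min_fore_conservation))
  if (nrow(sel)) {
    sel <- sel[order(-sel$score), ]
    lab <- ifelse(is.na(sel$refpos), paste0("col ", sel$column),
                  paste0(sel$pattern_set, sel$refpos))
    cat("  top positions:",
        paste(utils::head(sprintf("%s (%.1f)", lab, sel$score), 8),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Selected pattern positions of a contrast result
#'
#' @param result a `"contrast_result"`.
#' @param use_refpos return reference residue numbers instead of alignment
#'   columns when a reference map was attached (default `FALSE`).
#' @return Integer vector of selected columns (or reference positions).
#' @export
pattern_positions <- function(result, use_refpos = FALSE) {
  sel <- result$calls[result$calls$selected, , drop = FALSE]
  if (use_refpos) sel$refpos[!is.na(sel$refpos)] else sel$column
}

#' Write contrast calls as TSV with a JSON metadata sidecar
#'
#' The sidecar (`<path>.json`) records the weighting scheme, effective and
#' total sequence counts per class, the configuration and the background
#' floor, so a run is reproducible from its outputs.
#'
#' @param result a `"contrast_result"`.
#' @param path output TSV path.
#' @param seed optional seed to record in the metadata.
#' @return `path`, invisibly.
#' @export
write_contrast <- function(result, path, seed = NULL) {
  utils::write.table(result$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  m <- result$partition$membership
  meta <- list(
    weighting = result$weights$method,
    n_fore = sum(m == "fore"), n_back = sum(m == "back"),
    effective_fore = sum(result$weights$weights[names(m)[m == "fore"]]),
    effective_back = sum(result$weights$weights[names(m)[m == "back"]]),
    p_floor = result$p_floor,
    config = unclass(result$config),
    seed = seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Jackknife stability of the selected pattern
#'
#' Emulates a subfamily-removal robustness check: removes a group of
#' foreground sequences, recomputes weights and the contrast analysis on
#' the reduced alignment, and reports the Jaccard overlap between the
#' selected-column sets before and after removal together with per-column
#' score deltas.
#'
#' @param aln an `"msa"` object.
#' @param part a `"partition_spec"`.
#' @param group character vector of foreground ids to remove (may be
#'   empty, giving overlap 1).
#' @param w optional `"seq_weights"` for the full alignment; weights for
#'   the reduced alignment are always recomputed with the same method.
#' @param refmap optional `"reference_map"`.
#' @param config a [contrast_config()].
#' @return An object of class `"stability_report"`: list with
#'   `removed_group`, `jaccard_overlap`, `selected_before`,
#'   `selected_after` (column indices), `score_delta` (per column,
#'   after - before), and the reduced-run `"contrast_result"`.
#' @export
jackknife_stability <- function(aln, part, group, w = NULL, refmap = NULL,
                                config = contrast_config()) {
  fore_ids <- names(part$membership)[part$membership == "fore"]
  if (length(setdiff(group, fore_ids))) {
    stop("configuration error: group contains non-foreground ids")
  }
  if (length(setdiff(fore_ids, group)) < 2L) {
    stop("configuration error: removal leaves fewer than 2 foreground sequences")
  }
  if (is.null(w)) w <- compute_weights(aln, "position_based")
  before <- contrast_analysis(aln, part, w, refmap, config)
  keep <- setdiff(aln$ids, group)
  red_aln <- subset_alignment(aln, keep)
  red_part <- new_partition(part$membership[keep], source = part$source)
  red_w <- compute_weights(red_aln, w$method)
  after <- contrast_analysis(red_aln, red_part, red_w, refmap, config)
  a <- which(before$calls$selected)
  b <- which(after$calls$selected)
  jac <- if (!length(a) && !length(b)) 1 else
    length(intersect(a, b)) / length(union(a, b))
  structure(list(removed_group = group, jaccard_overlap = jac,
                 selected_before = a, selected_after = b,
                 score_delta = after$calls$score - before$calls$score,
                 reduced_result = after),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("Jackknife stability: removed %d sequences, Jaccard ",
                     "overlap of selected columns %.3f (%d -> %d selected)\n"),
              length(x$removed_group), x$jaccard_overlap,
              length(x$selected_before), length(x$selected_after)))
  invisible(x)
}
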