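# Joint inference of the foreground/background partition and the pattern:
# a Gibbs-style alternation between pattern selection given the membership
# and per-sequence membership resampling given the pattern, seeded by a
# spectral split of the residue-indicator matrix.

#' Sample a foreground/background partition jointly with its pattern
#'
#' Alternates two steps for `n_sweeps` sweeps: (i) given the current
#' membership, run [contrast_analysis()] and take the selected pattern
#' columns; (ii) given those columns, reassign every sequence to
#' foreground or background with probability proportional to the product
#' over pattern columns of per-class pattern-match likelihoods with
#' additive pseudocounts (`config$pseudocount`). Gapped positions are
#' skipped in a sequence's likelihood; while no column passes the
#' selection threshold the reassignment probabilities are uniform, so the
#' chain keeps exploring without amplifying noise columns.
#'
#' Because the family signal lives in the co-occurrence of pattern
#' residues across columns, the first restart is initialised by a spectral
#' split: the sign of the first principal component of the centred
#' residue-indicator (one-hot) matrix, which separates a two-class
#' alignment up to label swap. Further restarts start from random
#' memberships (`init_fore_frac`). The converged end state of the restart
#' with the highest final joint score (sum of selected-column scores) is
#' returned — the raw joint score is not used to pick intermediate states,
#' since it grows when pattern-matching background carriers are folded
#' into the foreground — and the full sweep trace is kept for
#' diagnostics. Classes are prevented from shrinking below 2 sequences.
#' Results are reproducible for a fixed `seed`.
#'
#' @param aln an `"msa"` object with at least 10 sequences.
#' @param w optional `"seq_weights"`; default Henikoff position-based.
#' @param config a [contrast_config()].
#' @param n_sweeps sweeps per restart (default 10).
#' @param n_restarts restarts (default 2: one spectral, one random).
#' @param init `"spectral"` (default) or `"random"` for the first restart.
#' @param init_fore_frac probability a sequence starts in the foreground
#'   under random initialisation (default 0.5).
#' @param seed integer seed.
#' @return An object of class `"sampled_partition"`: list with `partition`
#'   (a `"partition_spec"` with source `"sampled"`), `result` (the
#'   `"contrast_result"` at the best state), `joint_score`, `degenerate`
#'   (`TRUE` when no visited state had a column passing the selection
#'   threshold, i.e. the alignment shows no stable two-class signal) and
#'   `trace` (data.frame: restart, sweep, n_fore, n_selected,
#'   joint_score).
#' @export
sample_partition <- function(aln, w = NULL, config = contrast_config(),
                             n_sweeps = 10L, n_restarts = 2L,
                             init = c("spectral", "random"),
                             init_fore_frac = 0.5, seed = 1L) {
  init <- match.arg(init)
  if (n_sequences(aln) < 10L) {
    stop("configuration error: sampler needs at least 10 sequences")
  }
  if (is.null(w)) w <- compute_weights(aln, "position_based")
  set.seed(as.integer(seed))
  n <- n_sequences(aln)
  # returned state: the converged end state of the best restart (the raw
  # column-score sum is inflated by folding pattern-matching background
  # carriers into the foreground, so the max-joint state visited is
  # systematically impurer than the converged one; the trace keeps both)
  best <- list(score = -Inf, membership = NULL, result = NULL)
  trace <- list()
  for (r in seq_len(n_restarts)) {
    if (r == 1L && init == "spectral") {
      membership <- spectral_split(aln)
    } else {
      membership <- ifelse(stats::runif(n) < init_fore_frac, "fore", "back")
      names(membership) <- aln$ids
    }
    membership <- enforce_min_class(membership, 2L)
    for (sweep in seq_len(n_sweeps + 1L)) {
      part <- new_partition(membership, source = "sampled")
      res <- contrast_analysis(aln, part, w, config = config)
      sel <- which(res$calls$selected)
      joint <- sum(res$calls$score[sel])
      if (sweep == 1L) {
        # the contrast is orientation-sensitive (the pattern lives in the
        # foreground); try the label swap and keep the better orientation
        swapped <- ifelse(membership == "fore", "back", "fore")
        names(swapped) <- names(membership)
        part2 <- new_partition(swapped, source = "sampled")
        res2 <- contrast_analysis(aln, part2, w, config = config)
        sel2 <- which(res2$calls$selected)
        joint2 <- sum(res2$calls$score[sel2])
        if (joint2 > joint) {
          membership <- swapped; part <- part2; res <- res2
          sel <- sel2; joint <- joint2
        }
      }
      trace[[length(trace) + 1L]] <-
        data.frame(restart = r, sweep = sweep,
                   n_fore = sum(membership == "fore"),
                   n_selected = length(sel), joint_score = joint)
      if (sweep > n_sweeps) {
        if (joint > best$score) {
          best <- list(score = joint, membership = membership, result = res)
        }
        break
      }
      membership <- resample_membership(aln, res, sel, config$pseudocount)
      membership <- enforce_min_class(membership, 2L)
    }
  }
  trace <- do.call(rbind, trace)
  structure(list(partition = new_partition(best$membership,
                                           source = "sampled"),
                 result = best$result, joint_score = best$score,
                 degenerate = best$score < config$score_threshold,
                 trace = trace, seed = as.integer(seed)),
            class = "sampled_partition")
}

# Sign split of the first principal component of the centred one-hot
# residue matrix: the leading co-variation direction across sequences,
# which for a two-class alignment is the class contrast.
spectral_split <- function(aln) {
  mat <- aln$mat
  n <- nrow(mat); L <- ncol(mat)
  X <- matrix(0, n, L * 20L)
  for (r in seq_along(AMINO_ACIDS)) {
    idx <- which(mat == AMINO_ACIDS[r])
    i <- (idx - 1L) %% n + 1L
    j <- (idx - 1L) %/% n + 1L
    X[cbind(i, (j - 1L) * 20L + r)] <- 1
  }
  X <- sweep(X, 2L, colMeans(X))
  pc1 <- svd(X, nu = 1L, nv = 0L)$u[, 1L]
  membership <- ifelse(pc1 > 0, "fore", "back")
  names(membership) <- aln$ids
  membership
}

# Gibbs reassignment of every sequence given the selected pattern columns
# `sel` of contrast result `res`: per class, the likelihood that a
# sequence matches / mismatches the column's pattern set, with
# pseudocount alpha. No selected columns -> uniform reassignment.
resample_membership <- function(aln, res, sel, alpha) {
  m <- res$partition$membership[aln$ids]
  wts <- res$weights$weights[aln$ids]
  out <- m
  llf <- llb <- numeric(length(m))
  for (j in sel) {
    set <- strsplit(res$calls$pattern_set[j], "")[[1]]
    if (!length(set)) next
    col <- aln$mat[, j]
    nongap <- col %in% AMINO_ACIDS
    match <- nongap & col %in% set
    wf <- sum(wts[m == "fore" & nongap])
    wb <- sum(wts[m == "back" & nongap])
    mf <- sum(wts[m == "fore" & match])
    mb <- sum(wts[m == "back" & match])
    pf <- (mf + alpha) / (wf + 2 * alpha)
    pb <- (mb + alpha) / (wb + 2 * alpha)
    llf[nongap] <- llf[nongap] + ifelse(match[nongap], log(pf), log1p(-pf))
    llb[nongap] <- llb[nongap] + ifelse(match[nongap], log(pb), log1p(-pb))
  }
  pfore <- 1 / (1 + exp(llb - llf))
  draw <- stats::runif(length(m))
  out[] <- ifelse(draw < pfore, "fore", "back")
  out
}

# Flip randomly chosen members of the larger class into a class that has
# fallen below `k` sequences (keeps both classes analysable).
enforce_min_class <- function(membership, k) {
  for (cls in c("fore", "back")) {
    short <- k - sum(membership == cls)
    if (short > 0) {
      other <- which(membership != cls)
      flip <- sample(other, short)
      membership[flip] <- cls
    }
  }
  membership
}

#' @export
print.sampled_partition <- function(x, ...) {
  cat(sprintf(paste0("Sampled partition: %d fore / %d back, joint score ",
                     "%.1f%s (seed %d)\n"),
              sum(x$partition$membership == "fore"),
              sum(x$partition$membership == "back"),
              x$joint_score,
              if (x$degenerate) " [degenerate: no stable pattern]" else "",
              x$seed))
  invisible(x)
}

#' Agreement between two partitions up to class-label swap
#'
#' Fraction of sequences assigned to the same class, maximised over the
#' two possible labelings of the second partition.
#'
#' @param a,b `"partition_spec"` objects (or named membership vectors)
#'   over the same sequence ids.
#' @return A number in \[0.5, 1\].
#' @export
partition_agreement <- function(a, b) {
  ma <- if (inherits(a, "partition_spec")) a$membership else a
  mb <- if (inherits(b, "partition_spec")) b$membership else b
  ids <- names(ma)
  if (!setequal(ids, names(mb))) stop("partitions cover different ids")
  mb <- mb[ids]
  same <- mean(ma == mb)
  max(same, 1 - same)
}
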