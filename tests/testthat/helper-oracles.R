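# Independent brute-force oracles and small fixture builders shared by the
# tests. These deliberately avoid the package's own code paths: tail
# probabilities are direct log-space summations, pattern selection is an
# exhaustive loop, Fisher p-values are hypergeometric enumerations with
# choose().

# -log10 P(X >= k), X ~ Binomial(n, p), by direct summation of terms
oracle_binom_tail_score <- function(k, n, p) {
  if (k <= 0) return(0)
  kk <- k:n
  lt <- lchoose(n, kk) + kk * log(p) + (n - kk) * log1p(-p)
  m <- max(lt)
  -(m + log(sum(exp(lt - m)))) / log(10)
}

# exhaustive residue-set search mirroring the documented tie-break
# (max score, then smaller set, then alphabetical)
oracle_select_pattern <- function(fore_freq, back_freq, n_fore_total,
                                  p_floor, max_set = 3L) {
  best <- NULL
  for (m in seq_len(max_set)) {
    for (set in utils::combn(AMINO_ACIDS, m, simplify = FALSE)) {
      ff <- sum(fore_freq[set], na.rm = TRUE)
      if (ff == 0) next
      pb <- min(max(sum(back_freq[set], na.rm = TRUE), p_floor), 1)
      k <- min(floor(ff * n_fore_total + 0.5), floor(n_fore_total + 0.5))
      sc <- oracle_binom_tail_score(k, floor(n_fore_total + 0.5), pb)
      key <- paste(set, collapse = "")
      if (is.null(best) || sc > best$score ||
          (sc == best$score &&
           (m < best$size || (m == best$size && key < best$key)))) {
        best <- list(score = sc, size = m, key = key)
      }
    }
  }
  best
}

# one-sided (greater) Fisher exact p for table rbind(c(a, c), c(b, d)) with
# a = mutated & pattern, by hypergeometric enumeration over choose()
oracle_fisher_greater <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  K <- a + b          # pattern positions
  n <- a + c_         # mutated positions
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n))
  sum(probs[ks >= a])
}

# random proper rotation matrix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# tiny structure fixtures -----------------------------------------------

atom_row <- function(chain, resno, resid, atom, element, x, y, z) {
  data.frame(chain = chain, resno = resno, resid = resid, atom = atom,
             element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# a serine OG donor (with CB antecedent) facing an asparagine OD1 acceptor
# (with CG antecedent) at the given O...O distance
make_hbond_pair <- function(d = 2.9, structure_id = "pair") {
  structure_from_atoms(rbind(
    atom_row("A", 1, "SER", "CB", "C", 0, 0, 1.5),
    atom_row("A", 1, "SER", "OG", "O", 0, 0, 0),
    atom_row("A", 5, "ASN", "CG", "C", d + 1.0, 1.0, 0),
    atom_row("A", 5, "ASN", "OD1", "O", d, 0, 0)),
    structure_id)
}

# regular PHE ring (radius 1.39 A, z = 0 plane) centred at the origin, and
# a probe carbon at `probe` belonging to another residue
make_chpi_fixture <- function(probe, structure_id = "chpi") {
  ang <- (0:5) * pi / 3
  ring <- do.call(rbind, lapply(seq_along(ang), function(i) {
    atom_row("A", 1, "PHE",
             c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")[i], "C",
             1.39 * cos(ang[i]), 1.39 * sin(ang[i]), 0)
  }))
  structure_from_atoms(rbind(
    ring,
    atom_row("A", 10, "ALA", "CB", "C", probe[1], probe[2], probe[3])),
    structure_id)
}

# benchmark synthetic alignment at the study conditions (see
# synth_msa_config defaults), pre-weighted and contrasted
run_benchmark_contrast <- function(seed, cfg = synth_msa_config(seed = seed)) {
  g <- generate_msa(cfg)
  w <- compute_weights(g$alignment, "position_based")
  res <- contrast_analysis(g$alignment, g$partition, w)
  list(gen = g, weights = w, result = res,
       selected = which(res$calls$selected))
}
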