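# Seed-deterministic synthetic-data generators with known ground truth:
# alignments with planted family-specific pattern columns, ideal helices
# with a known backbone hydrogen-bond ladder, and mutation tables with a
# known overlap with a designated pattern-position set. They emulate the
# shape of a receptor-kinase superfamily analysis (a conserved foreground
# family inside a diverse background) without any external downloads.

#' Configuration for the synthetic alignment generator
#'
#' Defaults reproduce the benchmark conditions used throughout the test
#' suite: 50 foreground and 200 background sequences, 100 columns of which
#' 10 are planted pattern columns, foreground conservation 0.9 of the
#' planted residue against a background frequency of 0.05.
#'
#' @param n_fore,n_back numbers of foreground / background sequences.
#' @param L number of alignment columns.
#' @param n_pattern number of planted pattern columns (ignored when
#'   `pattern_columns` is given).
#' @param pattern_columns explicit 1-based pattern column indices, or
#'   `NULL` to sample them.
#' @param theta_fore probability a foreground sequence carries the planted
#'   residue at a pattern column.
#' @param p_back_pattern background frequency of the planted residue at a
#'   pattern column (must be below `theta_fore`).
#' @param dirichlet concentration of the symmetric Dirichlet from which
#'   each column's background residue profile is drawn (default 0.5,
#'   giving realistically uneven columns).
#' @param gap_rate i.i.d. per-site gap probability (default 0.02).
#' @param n_duplicate_clones exact copies of randomly chosen foreground
#'   sequences appended to exercise sequence weighting (default 0).
#' @param seed integer seed.
#' @return A list of class `"synth_msa_config"`.
#' @export
synth_msa_config <- function(n_fore = 50L, n_back = 200L, L = 100L,
                             n_pattern = 10L, pattern_columns = NULL,
                             theta_fore = 0.9, p_back_pattern = 0.05,
                             dirichlet = 0.5, gap_rate = 0.02,
                             n_duplicate_clones = 0L, seed = 1L) {
  if (!is.null(pattern_columns)) {
    pattern_columns <- as.integer(pattern_columns)
    if (any(pattern_columns < 1L | pattern_columns > L)) {
      stop("config error: pattern_columns outside 1..L")
    }
    n_pattern <- length(pattern_columns)
  }
  if (n_pattern > L) stop("config error: more pattern columns than columns")
  if (theta_fore <= 0 || theta_fore > 1) {
    stop("config error: theta_fore outside (0, 1]")
  }
  if (p_back_pattern < 0 || p_back_pattern >= theta_fore) {
    stop("config error: need 0 <= p_back_pattern < theta_fore")
  }
  if (p_back_pattern >= 1) stop("config error: p_back_pattern >= 1")
  if (gap_rate < 0 || gap_rate >= 1) stop("config error: gap_rate outside [0, 1)")
  structure(list(n_fore = as.integer(n_fore), n_back = as.integer(n_back),
                 L = as.integer(L), n_pattern = as.integer(n_pattern),
                 pattern_columns = pattern_columns,
                 theta_fore = theta_fore, p_back_pattern = p_back_pattern,
                 dirichlet = dirichlet, gap_rate = gap_rate,
                 n_duplicate_clones = as.integer(n_duplicate_clones),
                 seed = as.integer(seed)),
            class = "synth_msa_config")
}

#' Generate a synthetic alignment with planted pattern columns
#'
#' Per column, a background residue profile is drawn from a symmetric
#' Dirichlet. Non-pattern columns are sampled i.i.d. from that profile in
#' both classes. At pattern columns, foreground sequences carry the
#' planted residue with probability `theta_fore` (otherwise sampling the
#' profile), while background sequences sample a modified profile giving
#' the planted residue exactly `p_back_pattern` with the remainder
#' renormalised. Gaps are inserted i.i.d. at `gap_rate`, and
#' `n_duplicate_clones` exact copies of randomly chosen foreground
#' sequences are appended. Sequences are i.i.d. given the column profiles
#' (no phylogeny); the clone mechanism stands in for tree redundancy when
#' exercising weighting. Fixed seed gives identical output.
#'
#' @param cfg a [synth_msa_config()].
#' @return A list with `alignment` (an `"msa"`), `partition` (a
#'   `"partition_spec"`), and `truth`: list with `pattern_columns`,
#'   `planted_residue` (named by column), `labels` (the generating class
#'   per sequence id, clones labelled foreground) and `cfg`.
#' @export
generate_msa <- function(cfg = synth_msa_config()) {
  set.seed(cfg$seed)
  L <- cfg$L
  pat <- cfg$pattern_columns
  if (is.null(pat)) pat <- sort(sample.int(L, cfg$n_pattern))
  planted <- sample(AMINO_ACIDS, length(pat), replace = TRUE)
  names(planted) <- as.character(pat)
  profiles <- matrix(stats::rgamma(L * 20, shape = cfg$dirichlet), L, 20)
  profiles <- profiles / rowSums(profiles)
  colnames(profiles) <- AMINO_ACIDS
  n_f <- cfg$n_fore; n_b <- cfg$n_back
  fore <- matrix("", n_f, L)
  back <- matrix("", n_b, L)
  for (j in seq_len(L)) {
    prof <- profiles[j, ]
    if (j %in% pat) {
      r <- planted[[as.character(j)]]
      hit <- stats::runif(n_f) < cfg$theta_fore
      fore[, j] <- ifelse(hit, r, sample(AMINO_ACIDS, n_f, replace = TRUE,
                                         prob = prof))
      bprof <- prof
      bprof[r] <- 0
      bprof <- bprof / sum(bprof) * (1 - cfg$p_back_pattern)
      bprof[r] <- cfg$p_back_pattern
      back[, j] <- sample(AMINO_ACIDS, n_b, replace = TRUE, prob = bprof)
    } else {
      fore[, j] <- sample(AMINO_ACIDS, n_f, replace = TRUE, prob = prof)
      back[, j] <- sample(AMINO_ACIDS, n_b, replace = TRUE, prob = prof)
    }
  }
  mat <- rbind(fore, back)
  if (cfg$gap_rate > 0) {
    mat[matrix(stats::runif(length(mat)) < cfg$gap_rate, nrow(mat))] <- "-"
  }
  ids <- c(sprintf("fore_%03d", seq_len(n_f)),
           sprintf("back_%03d", seq_len(n_b)))
  labels <- c(rep("fore", n_f), rep("back", n_b))
  if (cfg$n_duplicate_clones > 0) {
    src <- sample.int(n_f, cfg$n_duplicate_clones, replace = TRUE)
    mat <- rbind(mat, mat[src, , drop = FALSE])
    ids <- c(ids, sprintf("%s_clone%02d", ids[src],
                          seq_len(cfg$n_duplicate_clones)))
    labels <- c(labels, rep("fore", cfg$n_duplicate_clones))
  }
  aln <- new_alignment(ids, apply(mat, 1L, paste, collapse = ""))
  names(labels) <- ids
  part <- new_partition(labels, source = "given")
  list(alignment = aln, partition = part,
       truth = list(pattern_columns = pat, planted_residue = planted,
                    labels = labels, cfg = cfg))
}

#' Generate an ideal poly-alanine alpha-helix with known hydrogen bonds
#'
#' Builds an N-CA-C-O backbone from standard internal geometry (bond
#' lengths 1.458 / 1.525 / 1.329 Angstrom, C=O 1.231) at backbone
#' dihedrals phi = -57, psi = -47, omega = 180 degrees — the canonical
#' alpha-helix. The ground truth is the i -> i+4 backbone O...N
#' hydrogen-bond ladder: `n_res - 4` pairs.
#'
#' @param n_res number of residues (at least 5).
#' @param structure_id structure identifier.
#' @param phi,psi backbone dihedrals in degrees.
#' @return A list with `structure` (a `"protein_structure"`) and `truth`,
#'   a data.frame of the planted bonds: `resno_a` (carbonyl O residue),
#'   `resno_b` (amide N residue, `resno_a + 4`).
#' @export
generate_helix <- function(n_res, structure_id = "ideal_helix",
                           phi = -57, psi = -47) {
  if (n_res < 5L) stop("config error: helix needs at least 5 residues")
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329; bCO <- 1.231
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7; aCACO <- 120.5
  omega <- 180
  place <- function(a, b, c, bond, angle, torsion) {
    ang <- angle * pi / 180; tor <- torsion * pi / 180
    d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
            bond * sin(ang) * sin(tor))
    bc <- unit3(c - b)
    n <- unit3(cross3(b - a, bc))
    m <- cbind(bc, cross3(n, bc), n)
    c(m %*% d2) + c
  }
  rows <- vector("list", n_res * 4L)
  k <- 0L
  N <- c(0, 0, 0); CA <- c(bNCA, 0, 0)
  C <- place(c(0, -1, 0), N, CA, bCAC, aNCAC, phi)
  for (i in seq_len(n_res)) {
    O <- place(N, CA, C, bCO, aCACO, psi + 180)
    for (at in list(list("N", N), list("CA", CA), list("C", C),
                    list("O", O))) {
      k <- k + 1L
      rows[[k]] <- data.frame(chain = "A", resno = i, resid = "ALA",
                              atom = at[[1]],
                              element = substr(at[[1]], 1, 1),
                              x = at[[2]][1], y = at[[2]][2],
                              z = at[[2]][3], stringsAsFactors = FALSE)
    }
    if (i < n_res) {
      Nn <- place(N, CA, C, bCN, aCACN, psi)
      CAn <- place(CA, C, Nn, bNCA, aCNCA, omega)
      Cn <- place(C, Nn, CAn, bCAC, aNCAC, phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  s <- structure_from_atoms(do.call(rbind, rows), structure_id)
  truth <- data.frame(resno_a = seq_len(n_res - 4L),
                      resno_b = seq_len(n_res - 4L) + 4L)
  list(structure = s, truth = truth)
}

#' Generate a mutation table with a known pattern overlap
#'
#' Designates `n_pattern` pattern positions among positions
#' `1..n_positions`, then places `n_mut` mutated positions so that exactly
#' `overlap` of them fall on pattern positions. Each mutated position gets
#' a random wild-type/variant residue pair, a primary site drawn from a
#' small vocabulary, and a recurrence count in 1..30.
#'
#' @param n_positions size of the position universe.
#' @param n_pattern number of designated pattern positions.
#' @param n_mut number of mutated positions.
#' @param overlap exact number of mutated positions on pattern positions
#'   (at most `min(n_pattern, n_mut)`).
#' @param seed integer seed.
#' @param path optional path; when given, the table is written as TSV
#'   (readable by [read_mutations()]).
#' @return A list with `mutations` (a `"mutation_table"` data.frame),
#'   `pattern_positions`, `truth` (list with the planted 2x2 counts:
#'   `overlap`, `pattern_only`, `mut_only`, `neither`) and `path`.
#' @export
generate_mutation_fixture <- function(n_positions = 100L, n_pattern = 10L,
                                      n_mut = 10L, overlap = 8L,
                                      seed = 1L, path = NULL) {
  if (overlap > min(n_pattern, n_mut)) {
    stop("config error: overlap exceeds min(n_pattern, n_mut)")
  }
  if (n_pattern > n_positions ||
      (n_mut - overlap) > (n_positions - n_pattern)) {
    stop("config error: infeasible counts for the position universe")
  }
  set.seed(as.integer(seed))
  pattern <- sort(sample.int(n_positions, n_pattern))
  off <- setdiff(seq_len(n_positions), pattern)
  mut_pos <- sort(c(sample(pattern, overlap),
                    sample(off, n_mut - overlap)))
  sites <- c("lung", "prostate", "thyroid", "oesophagus",
             "central_nervous_system", "upper_aerodigestive_tract")
  wt <- sample(AMINO_ACIDS, n_mut, replace = TRUE)
  variant <- vapply(wt, function(w) sample(setdiff(AMINO_ACIDS, w), 1L),
                    character(1))
  muts <- data.frame(refpos = mut_pos, wt = wt, variant = unname(variant),
                     site = sample(sites, n_mut, replace = TRUE),
                     count = sample.int(30L, n_mut, replace = TRUE),
                     stringsAsFactors = FALSE)
  class(muts) <- c("mutation_table", "data.frame")
  if (!is.null(path)) {
    utils::write.table(
      data.frame(position = muts$refpos, wt = muts$wt,
                 variant = muts$variant, site = muts$site,
                 count = muts$count),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- list(overlap = overlap, pattern_only = n_pattern - overlap,
                mut_only = n_mut - overlap,
                neither = n_positions - n_pattern - (n_mut - overlap))
  list(mutations = muts, pattern_positions = pattern, truth = truth,
       path = path)
}
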