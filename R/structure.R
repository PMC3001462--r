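# Structure handling and geometric interaction detection: hydrogen bonds,
# van der Waals contacts and CH-pi interactions, interaction frequencies
# across a crystal-structure ensemble, and tether-class labelling of
# pattern positions.

#' Construct a protein structure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno` (author residue
#'   number), `resid` (3-letter residue name), `atom` (PDB atom name),
#'   `element`, `x`, `y`, `z` (Angstrom).
#' @param structure_id identifier for the structure.
#' @param state `"active"`, `"inactive"` or `"unassigned"`.
#' @return An object of class `"protein_structure"`.
#' @export
structure_from_atoms <- function(atoms, structure_id,
                                 state = c("unassigned", "active",
                                           "inactive")) {
  state <- match.arg(state)
  need <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ",
                         paste(miss, collapse = ", "))
  atoms <- atoms[need]
  if (!nrow(atoms)) stop("input error: empty structure")
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key)) {
    stop("duplicate atom records: ", key[duplicated(key)][1L])
  }
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  structure(list(structure_id = structure_id, atoms = atoms, state = state),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("Structure %s (%s): %d atoms, %d residues, chain(s) %s\n",
              x$structure_id, x$state, nrow(x$atoms),
              nrow(unique(x$atoms[c("chain", "resno")])),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Parses with `bio3d::read.pdb`. Only the first model of a multi-model
#' file is used; waters, other heteroatoms and hydrogens are dropped; where
#' alternate locations exist, the highest-occupancy altloc of each atom is
#' kept (ties: first in file order).
#'
#' @param path path to a PDB file.
#' @param structure_id identifier (default: file name without extension).
#' @param state functional state label (see [structure_from_atoms()]).
#' @return A `"protein_structure"`.
#' @export
read_structure <- function(path, structure_id = NULL,
                           state = c("unassigned", "active", "inactive")) {
  state <- match.arg(state)
  if (is.null(structure_id)) structure_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("format error reading PDB ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("input error: no protein atoms in ", path)
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                                substr(gsub("[0-9' ]", "", at$elety), 1, 1),
                                at$elesy)))
  heavy <- !elem %in% c("H", "D")
  at <- at[heavy, , drop = FALSE]
  elem <- elem[heavy]
  # resolve altlocs: keep the highest-occupancy record of each atom
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(-occ)
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  keep_rows <- ord[!duplicated(key[ord])]
  keep_rows <- sort(keep_rows)
  at <- at[keep_rows, , drop = FALSE]
  elem <- elem[keep_rows]
  structure_from_atoms(
    data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
               resno = at$resno, resid = at$resid, atom = at$elety,
               element = elem, x = at$x, y = at$y, z = at$z,
               stringsAsFactors = FALSE),
    structure_id, state)
}

#' Write a structure as a minimal PDB file
#'
#' @param s a `"protein_structure"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$atom, elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Apply a rigid motion to a structure
#'
#' @param s a `"protein_structure"`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return The transformed `"protein_structure"`.
#' @export
transform_structure <- function(s, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[c("x", "y", "z")])
  xyz <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  s$atoms[c("x", "y", "z")] <- xyz
  s
}

## ---- geometry helpers -----------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

# angle p-q-r at vertex q, degrees
angle3 <- function(p, q, r) {
  v1 <- unit3(p - q); v2 <- unit3(r - q)
  acos(pmin(pmax(sum(v1 * v2), -1), 1)) * 180 / pi
}

## ---- hydrogen bonds -------------------------------------------------------

# Donor / acceptor capability of polar heavy atoms in the standard residues.
# Atoms not listed (unknown residue or atom) are treated as both capable.
.HB_DONOR <- c(
  "SER:OG", "THR:OG1", "TYR:OH", "CYS:SG", "ASN:ND2", "GLN:NE2",
  "LYS:NZ", "ARG:NE", "ARG:NH1", "ARG:NH2", "HIS:ND1", "HIS:NE2",
  "TRP:NE1")
.HB_ACCEPTOR <- c(
  "SER:OG", "THR:OG1", "TYR:OH", "CYS:SG", "MET:SD",
  "ASN:OD1", "GLN:OE1", "ASP:OD1", "ASP:OD2", "GLU:OE1", "GLU:OE2",
  "HIS:ND1", "HIS:NE2")
.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

hb_capability <- function(resid, atom) {
  key <- paste0(resid, ":", atom)
  donor <- rep(NA, length(key))  # NA = unknown -> both capable
  acceptor <- donor
  known <- resid %in% c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                        "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                        "PRO", "SER", "THR", "TRP", "TYR", "VAL")
  donor[known] <- key[known] %in% .HB_DONOR
  acceptor[known] <- key[known] %in% .HB_ACCEPTOR
  # backbone chemistry: amide N donates (not proline), carbonyl O accepts
  bbN <- atom == "N"
  donor[bbN] <- resid[bbN] != "PRO"
  acceptor[bbN & known] <- FALSE
  bbO <- atom %in% c("O", "OXT")
  acceptor[bbO] <- TRUE
  donor[bbO & known] <- FALSE
  donor[is.na(donor)] <- TRUE
  acceptor[is.na(acceptor)] <- TRUE
  list(donor = donor, acceptor = acceptor)
}

#' Geometric criteria for hydrogen-bond detection
#'
#' Heavy-atom criteria (no explicit hydrogens): donor-acceptor distance at
#' most `d_max`; for backbone amide-nitrogen donors the amide hydrogen is
#' reconstructed in the peptide plane (opposite the bisector of the two
#' covalent neighbours, `h_length` from N) and the N-H...acceptor angle
#' must reach `theta_h`; for every other donor with a unique covalent
#' antecedent, the antecedent-donor-acceptor angle must reach `theta_min`,
#' and likewise on the acceptor side. Donor-acceptor pairs from the same
#' residue are never reported, and pairs closer than two residues along a
#' chain are reported only when both atoms are side-chain atoms.
#'
#' @param d_max donor-acceptor heavy-atom distance cutoff, Angstrom
#'   (default 3.5).
#' @param theta_min minimum antecedent-donor-acceptor (and
#'   antecedent-acceptor-donor) angle, degrees (default 90).
#' @param theta_h minimum reconstructed N-H...acceptor angle at the
#'   hydrogen, degrees (default 120).
#' @param h_length reconstructed N-H bond length, Angstrom (default 1.0).
#' @param covalent_max distance under which two atoms of a residue are
#'   considered covalently bonded when finding antecedents (default 1.8).
#' @param min_seq_sep minimum residue-number separation for
#'   backbone-involving pairs (default 2).
#' @return A list of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(d_max = 3.5, theta_min = 90, theta_h = 120,
                           h_length = 1.0, covalent_max = 1.8,
                           min_seq_sep = 2L) {
  structure(list(d_max = d_max, theta_min = theta_min, theta_h = theta_h,
                 h_length = h_length, covalent_max = covalent_max,
                 min_seq_sep = as.integer(min_seq_sep)),
            class = "hbond_criteria")
}

# all candidate atom pairs within `cutoff`, as a two-column index matrix
close_pairs <- function(xyz, cutoff) {
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

# same-residue covalent neighbours of atom i (indices into the atom table)
antecedents <- function(atoms, xyz, i, covalent_max) {
  same <- which(atoms$chain == atoms$chain[i] &
                  atoms$resno == atoms$resno[i])
  same <- setdiff(same, i)
  if (!length(same)) return(integer(0))
  dd <- sqrt(colSums((t(xyz[same, , drop = FALSE]) - xyz[i, ])^2))
  same[dd <= covalent_max]
}

# reconstructed amide hydrogen for a backbone N: opposite the bisector of
# the CA(i) and C(i-1) directions, in the peptide plane
amide_hydrogen <- function(atoms, xyz, i, h_length) {
  ca <- which(atoms$chain == atoms$chain[i] &
                atoms$resno == atoms$resno[i] & atoms$atom == "CA")
  cp <- which(atoms$chain == atoms$chain[i] &
                atoms$resno == atoms$resno[i] - 1L & atoms$atom == "C")
  if (length(ca) != 1L || length(cp) != 1L) return(NULL)
  npos <- xyz[i, ]
  h <- unit3(-(unit3(xyz[ca, ] - npos) + unit3(xyz[cp, ] - npos)))
  npos + h * h_length
}

#' Detect hydrogen bonds in a structure
#'
#' Heavy-atom geometric detection between polar (N, O, S) atoms; see
#' [hbond_criteria()] for the geometry. Donor/acceptor roles follow the
#' chemistry of the standard residues (a backbone carbonyl oxygen never
#' donates; a non-proline backbone nitrogen donates); atoms of
#' non-standard residues are permissively treated as both.
#'
#' @param s a `"protein_structure"`.
#' @param criteria an [hbond_criteria()] list.
#' @return A data.frame of class `"interaction_table"`, one row per
#'   residue-atom pair: `kind` (`"hbond"`), `chain_a`, `resno_a`,
#'   `resid_a`, `atom_a`, the `_b` counterparts, `distance` (Angstrom),
#'   `angle` (the donor-side angle actually tested, degrees; `NA` when no
#'   angle test applied) and `structure_id`. Partners are stored in
#'   canonical order (`chain`, `resno`, `atom` of a sorts before b).
#' @export
detect_hbonds <- function(s, criteria = hbond_criteria()) {
  atoms <- s$atoms
  polar <- which(atoms$element %in% c("N", "O", "S"))
  empty <- empty_interactions(s$structure_id)
  if (length(polar) < 2L) return(empty)
  sub <- atoms[polar, , drop = FALSE]
  xyz_all <- as.matrix(atoms[c("x", "y", "z")])
  xyz <- xyz_all[polar, , drop = FALSE]
  cand <- close_pairs(xyz, criteria$d_max)
  if (!nrow(cand)) return(empty)
  cap <- hb_capability(sub$resid, sub$atom)
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    if (sub$chain[i] == sub$chain[j] && sub$resno[i] == sub$resno[j]) next
    same_chain <- sub$chain[i] == sub$chain[j]
    seq_sep <- abs(sub$resno[i] - sub$resno[j])
    both_side <- !(sub$atom[i] %in% .BACKBONE_ATOMS) &&
      !(sub$atom[j] %in% .BACKBONE_ATOMS)
    if (same_chain && seq_sep < criteria$min_seq_sep && !both_side) next
    found <- FALSE
    angle_used <- NA_real_
    for (ori in list(c(i, j), c(j, i))) {
      d <- ori[1L]; a <- ori[2L]
      if (!cap$donor[d] || !cap$acceptor[a]) next
      gi <- polar[d]; gj <- polar[a]
      dpos <- xyz_all[gi, ]; apos <- xyz_all[gj, ]
      ok <- TRUE; ang <- NA_real_
      if (sub$atom[d] == "N") {  # backbone amide donor: inferred-H angle
        h <- amide_hydrogen(atoms, xyz_all, gi, criteria$h_length)
        if (!is.null(h)) {
          ang <- angle3(dpos, h, apos)
          ok <- ang >= criteria$theta_h
        } else {
          ok <- antecedent_angle_ok(atoms, xyz_all, gi, apos, criteria)
          ang <- attr(ok, "angle")
        }
      } else {
        ok <- antecedent_angle_ok(atoms, xyz_all, gi, apos, criteria)
        ang <- attr(ok, "angle")
      }
      if (!isTRUE(as.logical(ok))) next
      # acceptor-side antecedent angle
      aok <- antecedent_angle_ok(atoms, xyz_all, gj, dpos, criteria)
      if (!isTRUE(as.logical(aok))) next
      found <- TRUE
      angle_used <- ang
      break
    }
    if (!found) next
    rows[[length(rows) + 1L]] <-
      interaction_row("hbond", sub[i, ], sub[j, ],
                      distance = sqrt(sum((xyz[i, ] - xyz[j, ])^2)),
                      angle = angle_used, structure_id = s$structure_id)
  }
  bind_interactions(rows, s$structure_id)
}

# antecedent-vertex-partner angle test at atom `i` toward `partner_pos`;
# passes vacuously unless a unique covalent antecedent exists
antecedent_angle_ok <- function(atoms, xyz_all, i, partner_pos, criteria) {
  ant <- antecedents(atoms, xyz_all, i, criteria$covalent_max)
  if (length(ant) != 1L) return(structure(TRUE, angle = NA_real_))
  ang <- angle3(xyz_all[ant, ], xyz_all[i, ], partner_pos)
  structure(ang >= criteria$theta_min, angle = ang)
}

## ---- van der Waals contacts ----------------------------------------------

#' Criteria for van der Waals contact detection
#'
#' A heavy-atom pair from distinct residues is a contact when its distance
#' is at most the sum of the two van der Waals radii plus `tolerance`, and
#' at least `d_min` (excluding covalent neighbours). Pairs already reported
#' as hydrogen bonds are excluded by [detect_vdw()].
#'
#' @param tolerance added to the radii sum, Angstrom (default 0.5).
#' @param d_min lower distance bound excluding covalent contacts, Angstrom
#'   (default 2.0).
#' @param radii named vector of van der Waals radii by element, Angstrom;
#'   elements not listed use `default_radius`.
#' @param default_radius fallback radius (default 1.7).
#' @return A list of class `"vdw_criteria"`.
#' @export
vdw_criteria <- function(tolerance = 0.5, d_min = 2.0,
                         radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                                   P = 1.80),
                         default_radius = 1.7) {
  structure(list(tolerance = tolerance, d_min = d_min, radii = radii,
                 default_radius = default_radius),
            class = "vdw_criteria")
}

#' Detect van der Waals contacts
#'
#' @param s a `"protein_structure"`.
#' @param criteria a [vdw_criteria()] list.
#' @param hbonds optional precomputed hydrogen-bond table for the same
#'   structure (default: computed with default [hbond_criteria()]); atom
#'   pairs present there are not reported again as contacts.
#' @return An `"interaction_table"` data.frame (see [detect_hbonds()]),
#'   `kind = "vdw"`.
#' @export
detect_vdw <- function(s, criteria = vdw_criteria(), hbonds = NULL) {
  atoms <- s$atoms
  if (is.null(hbonds)) hbonds <- detect_hbonds(s)
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  rad <- criteria$radii[atoms$element]
  rad[is.na(rad)] <- criteria$default_radius
  cand <- close_pairs(xyz, max(rad) * 2 + criteria$tolerance)
  if (!nrow(cand)) return(empty_interactions(s$structure_id))
  hb_keys <- character(0)
  if (nrow(hbonds)) {
    hb_keys <- paste(hbonds$chain_a, hbonds$resno_a, hbonds$atom_a,
                     hbonds$chain_b, hbonds$resno_b, hbonds$atom_b)
  }
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    if (atoms$chain[i] == atoms$chain[j] &&
        atoms$resno[i] == atoms$resno[j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < criteria$d_min || d > rad[i] + rad[j] + criteria$tolerance) next
    ord <- canonical_order(atoms[i, ], atoms[j, ])
    a <- if (ord) i else j; b <- if (ord) j else i
    key <- paste(atoms$chain[a], atoms$resno[a], atoms$atom[a],
                 atoms$chain[b], atoms$resno[b], atoms$atom[b])
    if (key %in% hb_keys) next
    rows[[length(rows) + 1L]] <-
      interaction_row("vdw", atoms[i, ], atoms[j, ], distance = d,
                      angle = NA_real_, structure_id = s$structure_id)
  }
  bind_interactions(rows, s$structure_id)
}

## ---- CH-pi interactions ---------------------------------------------------

.RING_ATOMS <- list(
  PHE = list(ring6 = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring6 = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring5 = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(ring5 = c("CG", "CD1", "CD2", "NE1", "CE2"),
             ring6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

#' Criteria for CH-pi interaction detection
#'
#' A carbon atom interacts with an aromatic ring when its distance to the
#' ring centroid is at most `d_max` and its elevation angle above the ring
#' plane is at least `theta_min`. The rings considered are the aromatic
#' systems of Phe, Tyr, His and both Trp rings.
#'
#' @param d_max carbon-centroid distance cutoff, Angstrom (default 4.5).
#' @param theta_min minimum elevation from the ring plane, degrees
#'   (default 30).
#' @return A list of class `"chpi_criteria"`.
#' @export
chpi_criteria <- function(d_max = 4.5, theta_min = 30) {
  structure(list(d_max = d_max, theta_min = theta_min),
            class = "chpi_criteria")
}

#' Detect CH-pi interactions
#'
#' @param s a `"protein_structure"`.
#' @param criteria a [chpi_criteria()] list.
#' @return An `"interaction_table"` data.frame; the ring partner's `atom`
#'   field carries a ring descriptor (e.g. `"ring6"`), and `angle` the
#'   elevation angle in degrees.
#' @export
detect_chpi <- function(s, criteria = chpi_criteria()) {
  atoms <- s$atoms
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  carb <- which(atoms$element == "C")
  res <- unique(atoms[c("chain", "resno", "resid")])
  rows <- list()
  for (k in seq_len(nrow(res))) {
    rings <- .RING_ATOMS[[res$resid[k]]]
    if (is.null(rings)) next
    for (ring_name in names(rings)) {
      sel <- which(atoms$chain == res$chain[k] &
                     atoms$resno == res$resno[k] &
                     atoms$atom %in% rings[[ring_name]])
      if (length(sel) != length(rings[[ring_name]])) next  # incomplete ring
      pts <- xyz[sel, , drop = FALSE]
      centroid <- colMeans(pts)
      sv <- svd(sweep(pts, 2, centroid))
      normal <- sv$v[, 3L]
      for (ci in carb) {
        if (atoms$chain[ci] == res$chain[k] &&
            atoms$resno[ci] == res$resno[k]) next
        v <- xyz[ci, ] - centroid
        d <- sqrt(sum(v^2))
        if (d == 0 || d > criteria$d_max) next
        elev <- asin(min(abs(sum(unit3(v) * normal)), 1)) * 180 / pi
        if (elev < criteria$theta_min) next
        ring_partner <- data.frame(chain = res$chain[k],
                                   resno = res$resno[k],
                                   resid = res$resid[k], atom = ring_name,
                                   stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <-
          interaction_row("chpi", atoms[ci, ], ring_partner, distance = d,
                          angle = elev, structure_id = s$structure_id)
      }
    }
  }
  bind_interactions(rows, s$structure_id)
}

## ---- interaction table plumbing -------------------------------------------

canonical_order <- function(a, b) {
  # TRUE if partner a sorts before b on (chain, resno, atom)
  ka <- sprintf("%s|%09d|%s", a$chain, a$resno, a$atom)
  kb <- sprintf("%s|%09d|%s", b$chain, b$resno, b$atom)
  ka <= kb
}

interaction_row <- function(kind, a, b, distance, angle, structure_id) {
  if (!canonical_order(a, b)) { tmp <- a; a <- b; b <- tmp }
  data.frame(kind = kind,
             chain_a = a$chain, resno_a = a$resno, resid_a = a$resid,
             atom_a = a$atom,
             chain_b = b$chain, resno_b = b$resno, resid_b = b$resid,
             atom_b = b$atom,
             distance = distance, angle = angle,
             structure_id = structure_id, stringsAsFactors = FALSE)
}

empty_interactions <- function(structure_id) {
  out <- data.frame(kind = character(0), chain_a = character(0),
                    resno_a = integer(0), resid_a = character(0),
                    atom_a = character(0), chain_b = character(0),
                    resno_b = integer(0), resid_b = character(0),
                    atom_b = character(0), distance = numeric(0),
                    angle = numeric(0), structure_id = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("interaction_table", "data.frame")
  out
}

bind_interactions <- function(rows, structure_id) {
  if (!length(rows)) return(empty_interactions(structure_id))
  out <- do.call(rbind, rows)
  out <- out[order(out$chain_a, out$resno_a, out$atom_a,
                   out$chain_b, out$resno_b, out$atom_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Detect all interaction kinds in one structure
#'
#' Convenience wrapper running [detect_hbonds()], [detect_vdw()] (with the
#' hydrogen bonds excluded) and [detect_chpi()].
#'
#' @param s a `"protein_structure"`.
#' @param hbond,vdw,chpi criteria lists for the three detectors.
#' @return A combined `"interaction_table"`.
#' @export
detect_interactions <- function(s, hbond = hbond_criteria(),
                                vdw = vdw_criteria(),
                                chpi = chpi_criteria()) {
  hb <- detect_hbonds(s, hbond)
  out <- rbind(hb, detect_vdw(s, vdw, hbonds = hb), detect_chpi(s, chpi))
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Interaction frequencies across a structure ensemble
#'
#' Detects interactions in every structure, maps author residue numbers to
#' reference numbering, keeps residue pairs touching the positions of
#' interest and tabulates, for each (kind, residue pair), in how many
#' structures the interaction occurs. The denominator of a pair counts
#' only the structures in which both residues are present (disordered
#' residues are excluded from the denominator and recorded in the coverage
#' report). Frequencies are additionally stratified by the structures'
#' functional state labels.
#'
#' @param structures list of `"protein_structure"` objects.
#' @param positions integer vector of reference positions of interest; a
#'   pair is kept when at least one end is in `positions`. `NULL` keeps
#'   every pair.
#' @param seq_offsets named numeric vector, per structure id, added to the
#'   author residue numbers to obtain reference numbering (default 0 for
#'   every structure).
#' @param hbond,vdw,chpi criteria lists passed to [detect_interactions()].
#' @return An object of class `"ensemble_table"`: list with `table`
#'   (data.frame: `kind`, `refpos_a`, `refpos_b`, `n_present`, `n_total`,
#'   `frequency`, `freq_active`, `freq_inactive`, `structure_ids`),
#'   `coverage` (data.frame: `refpos`, `structure_id`, `present`),
#'   `n_structures`, `states`.
#' @export
ensemble_frequency <- function(structures, positions = NULL,
                               seq_offsets = NULL,
                               hbond = hbond_criteria(),
                               vdw = vdw_criteria(),
                               chpi = chpi_criteria()) {
  if (!length(structures)) stop("need at least one structure")
  ids <- vapply(structures, function(s) s$structure_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate structure ids")
  states <- vapply(structures, function(s) s$state, character(1))
  names(states) <- ids
  offs <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(seq_offsets)) offs[names(seq_offsets)] <- seq_offsets
  per <- lapply(structures, function(s) {
    tab <- detect_interactions(s, hbond, vdw, chpi)
    o <- offs[[s$structure_id]]
    tab$refpos_a <- tab$resno_a + o
    tab$refpos_b <- tab$resno_b + o
    tab
  })
  present_res <- lapply(structures, function(s) {
    unique(s$atoms$resno) + offs[[s$structure_id]]
  })
  names(present_res) <- ids
  # coverage of the positions of interest
  covpos <- if (is.null(positions)) {
    sort(unique(unlist(present_res)))
  } else sort(unique(positions))
  coverage <- do.call(rbind, lapply(ids, function(id) {
    data.frame(refpos = covpos, structure_id = id,
               present = covpos %in% present_res[[id]],
               stringsAsFactors = FALSE)
  }))
  # collect pairwise keys touching the positions
  keyed <- lapply(seq_along(per), function(k) {
    tab <- per[[k]]
    if (!is.null(positions)) {
      tab <- tab[tab$refpos_a %in% positions |
                   tab$refpos_b %in% positions, , drop = FALSE]
    }
    lo <- pmin(tab$refpos_a, tab$refpos_b)
    hi <- pmax(tab$refpos_a, tab$refpos_b)
    unique(data.frame(kind = tab$kind, refpos_a = lo, refpos_b = hi,
                      stringsAsFactors = FALSE))
  })
  all_keys <- unique(do.call(rbind, keyed))
  if (is.null(all_keys) || !nrow(all_keys)) {
    return(structure(list(table = data.frame(), coverage = coverage,
                          n_structures = length(ids), states = states),
                     class = "ensemble_table"))
  }
  key_str <- function(df) paste(df$kind, df$refpos_a, df$refpos_b)
  pres_mat <- vapply(seq_along(per), function(k) {
    key_str(all_keys) %in% key_str(keyed[[k]])
  }, logical(nrow(all_keys)))
  pres_mat <- matrix(pres_mat, nrow = nrow(all_keys))
  cover_mat <- vapply(ids, function(id) {
    all_keys$refpos_a %in% present_res[[id]] &
      all_keys$refpos_b %in% present_res[[id]]
  }, logical(nrow(all_keys)))
  cover_mat <- matrix(cover_mat, nrow = nrow(all_keys))
  strat <- function(state) {
    sel <- which(states == state)
    if (!length(sel)) return(rep(NA_real_, nrow(all_keys)))
    np <- rowSums(pres_mat[, sel, drop = FALSE])
    nt <- rowSums(cover_mat[, sel, drop = FALSE])
    ifelse(nt > 0, np / nt, NA_real_)
  }
  n_present <- rowSums(pres_mat)
  n_total <- rowSums(cover_mat)
  tab <- cbind(all_keys,
               data.frame(n_present = n_present, n_total = n_total,
                          frequency = ifelse(n_total > 0,
                                             n_present / n_total, NA_real_),
                          freq_active = strat("active"),
                          freq_inactive = strat("inactive"),
                          structure_ids = apply(pres_mat, 1, function(p) {
                            paste(ids[p], collapse = ",")
                          }),
                          stringsAsFactors = FALSE))
  tab <- tab[order(tab$kind, tab$refpos_a, tab$refpos_b), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, coverage = coverage,
                 n_structures = length(ids), states = states),
            class = "ensemble_table")
}

#' @export
print.ensemble_table <- function(x, ...) {
  cat(sprintf("Ensemble interaction table: %d interactions over %d structures\n",
              nrow(x$table), x$n_structures))
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Write an ensemble interaction table (and coverage report) as TSV
#'
#' @param ens an `"ensemble_table"`.
#' @param path output TSV path; the coverage report goes to
#'   `<path sans extension>_coverage.tsv`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  utils::write.table(ens$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cov_path <- paste0(sub("\\.[^.]*$", "", path), "_coverage.tsv")
  utils::write.table(ens$coverage, cov_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a residue-region annotation table
#'
#' Tab-separated with header columns `refpos`, `region`, `tether` (tether
#' one of `NLT`, `AST`, `CLT`, `none`).
#'
#' @param path file path.
#' @return data.frame with the three columns.
#' @export
read_region_annotation <- function(path) {
  df <- utils::read.delim(path, colClasses = c(refpos = "integer",
                                               region = "character",
                                               tether = "character"))
  miss <- setdiff(c("refpos", "region", "tether"), names(df))
  if (length(miss)) stop("annotation lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !df$tether %in% c("NLT", "AST", "CLT", "none")
  if (any(bad)) stop("unknown tether class: ",
                     paste(unique(df$tether[bad]), collapse = ", "))
  df
}

#' Label selected pattern positions with region and tether class
#'
#' A deterministic join of the selected pattern positions (by reference
#' number) against a region annotation table. Unannotated positions get
#' tether class `"none"`.
#'
#' @param result a `"contrast_result"` with a reference map attached, or
#'   an integer vector of reference positions.
#' @param annot annotation data.frame as from [read_region_annotation()].
#' @return data.frame: `refpos`, `region`, `tether` (plus `pattern_set`
#'   and `score` when a contrast result is supplied).
#' @export
classify_tethers <- function(result, annot) {
  if (inherits(result, "contrast_result")) {
    sel <- result$calls[result$calls$selected & !is.na(result$calls$refpos), ,
                        drop = FALSE]
    out <- data.frame(refpos = sel$refpos, pattern_set = sel$pattern_set,
                      score = sel$score, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(refpos = as.integer(result))
  }
  if (!nrow(out)) {
    out$region <- character(0)
    out$tether <- character(0)
    return(out)
  }
  idx <- match(out$refpos, annot$refpos)
  out$region <- ifelse(is.na(idx), NA_character_, annot$region[idx])
  out$tether <- ifelse(is.na(idx), "none", annot$tether[idx])
  out[order(out$refpos), , drop = FALSE]
}
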