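pdb_line <- function(serial, name, alt, resid, chain, resno, x, y, z, occ,
                     elem) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resid, chain, resno, x, y, z, occ, 0, elem)
}

test_that("PDB reading honours altlocs, models and heteroatom removal", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL     1",
    pdb_line(1, " N  ", " ", "ALA", "A", 1, 0, 0, 0, 1, "N"),
    pdb_line(2, " CA ", "A", "ALA", "A", 1, 1.5, 0, 0, 0.6, "C"),
    pdb_line(3, " CA ", "B", "ALA", "A", 1, 9.5, 0, 0, 0.4, "C"),
    pdb_line(4, " H  ", " ", "ALA", "A", 1, -1, 0, 0, 1, "H"),
    sub("^ATOM  ", "HETATM", pdb_line(5, " O  ", " ", "HOH", "A", 90,
                                      5, 5, 5, 1, "O")),
    "ENDMDL",
    "MODEL     2",
    pdb_line(1, " N  ", " ", "ALA", "A", 1, 50, 0, 0, 1, "N"),
    pdb_line(2, " CA ", "A", "ALA", "A", 1, 51, 0, 0, 0.6, "C"),
    pdb_line(3, " CA ", "B", "ALA", "A", 1, 59, 0, 0, 0.4, "C"),
    "ENDMDL", "END"), f)
  s <- read_structure(f, "toy")
  expect_equal(nrow(s$atoms), 2)              # N + one CA, model 1 only
  expect_equal(s$atoms$x[s$atoms$atom == "CA"], 1.5)  # occupancy 0.6 wins
  expect_false(any(s$atoms$resid == "HOH"))
  expect_false(any(s$atoms$element == "H"))
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")),
               "format error")
})

test_that("structures written to PDB re-read with identical geometry", {
  h <- generate_helix(8)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h$structure, f)
  back <- read_structure(f)
  expect_equal(nrow(back$atoms), nrow(h$structure$atoms))
  a <- h$structure$atoms[order(h$structure$atoms$resno,
                               h$structure$atoms$atom), ]
  b <- back$atoms[order(back$atoms$resno, back$atoms$atom), ]
  expect_equal(a$atom, b$atom)
  expect_equal(as.matrix(a[c("x", "y", "z")]),
               as.matrix(b[c("x", "y", "z")]), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("hydrogen bonds: distance window, angles and helix ladder", {
  expect_equal(nrow(detect_hbonds(make_hbond_pair(2.9))), 1)
  expect_equal(nrow(detect_hbonds(make_hbond_pair(10))), 0)
  # ideal helix: exactly the i -> i+4 O...N ladder, nothing else
  h <- generate_helix(12)
  hb <- detect_hbonds(h$structure)
  expect_equal(nrow(hb), nrow(h$truth))          # 8 interior pairs
  expect_equal(hb$resno_a, h$truth$resno_a)
  expect_equal(hb$resno_b, h$truth$resno_b)
  expect_equal(hb$atom_a, rep("O", 8))
  expect_equal(hb$atom_b, rep("N", 8))
  expect_true(all(hb$distance <= 3.5))
  # truth count is forced by construction: n_res - 4
  h20 <- generate_helix(20)
  expect_equal(nrow(h20$truth), 16)
  expect_error(generate_helix(4), "at least 5")
})

test_that("van der Waals contacts follow the radii-plus-tolerance rule", {
  two_carbons <- function(d) structure_from_atoms(rbind(
    atom_row("A", 1, "ALA", "CB", "C", 0, 0, 0),
    atom_row("A", 5, "ALA", "CB", "C", d, 0, 0)), "c2")
  expect_equal(nrow(detect_vdw(two_carbons(3.6))), 1)   # 1.7+1.7+0.5 = 3.9
  expect_equal(nrow(detect_vdw(two_carbons(4.1))), 0)
  # a fixture with exactly three constructed contacts
  s3 <- structure_from_atoms(rbind(
    atom_row("A", 1, "ALA", "CB", "C", 0, 0, 0),
    atom_row("A", 5, "ALA", "CB", "C", 3.6, 0, 0),
    atom_row("A", 9, "ALA", "CB", "C", 1.8, 3.2, 0),
    atom_row("A", 13, "ALA", "CB", "C", 30, 0, 0)), "c3")
  expect_equal(nrow(detect_vdw(s3)), 3)
  # pairs already counted as hydrogen bonds are excluded
  hp <- make_hbond_pair(2.9)
  hb <- detect_hbonds(hp)
  vd <- detect_vdw(hp, hbonds = hb)
  keys <- function(t) paste(t$resno_a, t$atom_a, t$resno_b, t$atom_b)
  expect_false(any(keys(vd) %in% keys(hb)))
})

test_that("CH-pi detection needs both proximity and elevation", {
  above <- make_chpi_fixture(c(0, 0, 3.8))
  hits <- detect_chpi(above)
  expect_equal(nrow(hits), 1)
  # ring partner carries the ring descriptor (canonical order may place
  # it on either side)
  expect_true("ring6" %in% c(hits$atom_a, hits$atom_b))
  expect_gt(hits$angle, 85)                     # on the ring normal
  in_plane <- make_chpi_fixture(c(3.8, 0, 0))
  expect_equal(nrow(detect_chpi(in_plane)), 0)  # elevation fails
  far <- make_chpi_fixture(c(0, 0, 5.5))
  expect_equal(nrow(detect_chpi(far)), 0)       # distance fails
})

test_that("all detectors are invariant under rigid motions", {
  set.seed(31)
  h <- generate_helix(10)$structure
  mixed <- structure_from_atoms(rbind(
    h$atoms,
    atom_row("A", 40, "PHE", "CG", "C", 11.39, 10, 0),
    atom_row("A", 40, "PHE", "CD1", "C", 10.695, 11.204, 0),
    atom_row("A", 40, "PHE", "CE1", "C", 9.305, 11.204, 0),
    atom_row("A", 40, "PHE", "CZ", "C", 8.61, 10, 0),
    atom_row("A", 40, "PHE", "CE2", "C", 9.305, 8.796, 0),
    atom_row("A", 40, "PHE", "CD2", "C", 10.695, 8.796, 0),
    atom_row("A", 44, "ALA", "CB", "C", 10, 10, 3.8)), "mixed")
  base <- list(hb = detect_hbonds(mixed), vdw = detect_vdw(mixed),
               chpi = detect_chpi(mixed))
  strip <- function(t) t[setdiff(names(t), c("distance", "angle"))]
  for (trial in 1:8) {
    moved <- transform_structure(mixed, random_rotation(),
                                 stats::rnorm(3, sd = 20))
    got <- list(hb = detect_hbonds(moved), vdw = detect_vdw(moved),
                chpi = detect_chpi(moved))
    for (kind in names(base)) {
      expect_identical(strip(got[[kind]]), strip(base[[kind]]))
      expect_equal(got[[kind]]$distance, base[[kind]]$distance,
                   tolerance = 1e-6)
      expect_equal(got[[kind]]$angle, base[[kind]]$angle, tolerance = 1e-6)
    }
  }
})

test_that("interactions are stored in canonical partner order", {
  hb <- detect_hbonds(generate_helix(12)$structure)
  expect_true(all(hb$resno_a <= hb$resno_b))
  v <- detect_vdw(structure_from_atoms(rbind(
    atom_row("A", 9, "ALA", "CB", "C", 0, 0, 0),
    atom_row("A", 2, "ALA", "CB", "C", 3.6, 0, 0)), "swap"))
  expect_equal(v$resno_a, 2)
  expect_equal(v$resno_b, 9)
})

test_that("ensemble frequencies book-keep presence and coverage exactly", {
  # four copies of a donor/acceptor pair: bond broken in one structure,
  # second pair's partner residue deleted in two structures
  mk <- function(id, bond_ok, with_second) {
    rows <- rbind(
      atom_row("A", 1, "SER", "CB", "C", 0, 0, 1.5),
      atom_row("A", 1, "SER", "OG", "O", 0, 0, 0),
      atom_row("A", 5, "ASN", "CG", "C", if (bond_ok) 3.9 else 21,
               1.0, 0),
      atom_row("A", 5, "ASN", "OD1", "O", if (bond_ok) 2.9 else 20, 0, 0))
    if (with_second) {
      rows <- rbind(rows,
        atom_row("A", 9, "SER", "CB", "C", 0, 2.9 + 1.5 * cos(1), 1.5 * sin(1) - 8),
        atom_row("A", 9, "SER", "OG", "O", 0, 2.9, -8),
        atom_row("A", 13, "ASN", "CG", "C", 1.0, -1.0, -8),
        atom_row("A", 13, "ASN", "OD1", "O", 0, 0, -8))
    }
    structure_from_atoms(rows, id,
                         state = if (bond_ok) "active" else "inactive")
  }
  ens <- ensemble_frequency(list(mk("s1", TRUE, TRUE), mk("s2", TRUE, TRUE),
                                 mk("s3", TRUE, FALSE),
                                 mk("s4", FALSE, FALSE)),
                            positions = c(1, 9))
  tab <- ens$table
  first <- tab[tab$refpos_a == 1 & tab$refpos_b == 5 &
                 tab$kind == "hbond", ]
  expect_equal(first$n_present, 3)
  expect_equal(first$n_total, 4)
  expect_equal(first$frequency, 0.75)
  expect_equal(first$freq_active, 1)      # present in all three active
  expect_equal(first$freq_inactive, 0)
  second <- tab[tab$refpos_a == 9 & tab$refpos_b == 13 &
                  tab$kind == "hbond", ]
  # partner deleted in s3/s4: denominator 2, present in both remaining
  expect_equal(second$n_present, 2)
  expect_equal(second$n_total, 2)
  expect_equal(second$frequency, 1)
  cov <- ens$coverage
  expect_equal(sum(!cov$present[cov$refpos == 9]), 2)
  # single structure: every frequency 1
  ens1 <- ensemble_frequency(list(mk("only", TRUE, TRUE)))
  expect_true(all(ens1$table$frequency == 1))
  # numbering offsets map author residues into reference space
  ens_off <- ensemble_frequency(list(mk("s1", TRUE, FALSE)),
                                positions = 25,
                                seq_offsets = c(s1 = 24))
  expect_equal(unique(ens_off$table$refpos_a), 25)
  expect_equal(unique(ens_off$table$refpos_b), 29)
})

test_that("tether classification is a deterministic annotated join", {
  annot <- data.frame(refpos = c(791, 764, 997),
                      region = c("inter-lobe linker", "C-helix",
                                 "AP-2 helix"),
                      tether = c("NLT", "NLT", "AST"),
                      stringsAsFactors = FALSE)
  got <- classify_tethers(c(791, 997, 850), annot)
  expect_equal(got$tether[got$refpos == 791], "NLT")
  expect_equal(got$tether[got$refpos == 997], "AST")
  expect_equal(got$tether[got$refpos == 850], "none")  # unannotated
  expect_true(is.na(got$region[got$refpos == 850]))
  empty <- classify_tethers(integer(0), annot)
  expect_equal(nrow(empty), 0)
  # annotation file round-trip and validation
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(annot, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(read_region_annotation(f), annot)
  annot$tether[1] <- "XLT"
  utils::write.table(annot, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_region_annotation(f), "unknown tether")
})
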