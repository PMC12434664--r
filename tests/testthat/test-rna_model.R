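test_that("load_structure keeps the requested chain's nucleotides", {
  txt <- as_pdb_text(fx$rb)
  s <- load_structure(txt, "A")
  expect_equal(max(s$atoms$residue_index), 52L)
  expect_true(all(is.finite(s$atoms$x)))
  expect_error(load_structure(txt, "B"), "available chains.*A")
})

test_that("load_structure parses a minimal single-residue PDB", {
  lines <- c(
    "ATOM      1  P     G A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  C1'   G A   1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      3  N9    G A   1       2.000   0.000   0.000  1.00  0.00",
    "END")
  s <- load_structure(lines, "A")
  expect_equal(max(s$atoms$residue_index), 1L)
  expect_equal(nrow(s$atoms), 3L)
})

test_that("alternate locations are deduplicated to the first altloc", {
  lines <- c(
    "ATOM      1  P  A  G A   1       0.000   0.000   0.000  0.50  0.00",
    "ATOM      2  P  B  G A   1       9.000   0.000   0.000  0.50  0.00",
    "ATOM      3  C1'   G A   1       1.000   0.000   0.000  1.00  0.00",
    "END")
  s <- load_structure(lines, "A")
  expect_equal(sum(s$atoms$name == "P"), 1L)
  expect_equal(s$atoms$x[s$atoms$name == "P"], 0.0)
})

test_that("chains without nucleotides are rejected", {
  lines <- c(
    "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00",
    "END")
  expect_error(load_structure(lines, "A"), "no nucleotide")
})

test_that("coarse graining places beads at group centers of mass", {
  # two equal-mass phosphate-group oxygens at (0,0,0) and (2,0,0)
  atoms <- data.frame(
    name = c("P", "OP1", "C1'", "N1", "C2", "N3"),
    element = c("P", "O", "C", "N", "C", "N"),
    residue_index = 1L, residue_name = "U", chain_id = "A", resno_orig = 1L,
    x = c(0, 2, 5, 8, 8.5, 9), y = 0, z = 0)
  s <- structure(list(atoms = atoms, het = NULL, source_id = "fixture"),
                 class = "rna_structure")
  cg <- coarse_grain(s)
  # mass-weighted center of P (30.974) at 0 and OP1 (15.999) at 2
  expect_equal(cg$xyz[1, 1], 2 * 15.999 / (30.974 + 15.999),
               tolerance = 1e-12)
  expect_equal(cg$xyz[1, 2:3], c(0, 0))
  # equal-mass pair (5'-terminal group of two oxygens): centroid
  atoms2 <- atoms
  atoms2$name[1:2] <- c("O5'", "OP3")
  atoms2$element[1:2] <- "O"
  s2 <- structure(list(atoms = atoms2, het = NULL, source_id = "fixture"),
                  class = "rna_structure")
  expect_equal(coarse_grain(s2)$xyz[1, ], c(1, 0, 0))
})

test_that("52-residue input yields 156 beads, 3 roles per residue", {
  cg <- fx$cg_rb
  expect_equal(nrow(cg$xyz), 3L * 52L)
  for (r in c(1L, 28L, 52L)) {
    roles <- cg$role[cg$residue_index == r]
    expect_equal(sort(roles), c("B", "P", "S"))
  }
  expect_equal(cg$sequence[c(3, 28, 38)], c("G", "G", "U"))
})

test_that("coarse_grain rejects already-coarse-grained input", {
  expect_error(coarse_grain(fx$cg_rb), "already coarse-grained")
})

test_that("coarse_grain names the residue missing its base group", {
  atoms <- data.frame(
    name = c("P", "C1'"), element = c("P", "C"),
    residue_index = 1L, residue_name = "A", chain_id = "A", resno_orig = 1L,
    x = c(0, 1), y = 0, z = 0)
  s <- structure(list(atoms = atoms, het = NULL, source_id = "fixture"),
                 class = "rna_structure")
  expect_error(coarse_grain(s), "residue 1 .*B group")
})

test_that("native_contacts applies cutoff and separation filters", {
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0))
  cg <- make_cg(xyz, residue_index = c(1L, 4L), role = c("P", "P"))
  nc <- native_contacts(cg, cutoff = 6, min_sep = 0)
  expect_equal(nrow(nc$pairs), 1L)
  expect_equal(nc$pairs$r_native, 5)
  expect_equal(nrow(native_contacts(cg, cutoff = 6, min_sep = 4)$pairs), 0L)
})

test_that("native_contacts matches a brute-force enumeration", {
  set.seed(42)
  xyz <- matrix(runif(30, 0, 12), 10, 3)
  res <- rep(1:5, each = 2)
  cg <- make_cg(xyz, residue_index = res)
  nc <- native_contacts(cg, cutoff = 7, min_sep = 1)
  # independent O(N^2) loop
  exp_pairs <- NULL
  for (i in 1:9) for (j in (i + 1):10) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < 7 && abs(res[i] - res[j]) >= 1)
      exp_pairs <- rbind(exp_pairs, c(i, j, d))
  }
  expect_equal(nrow(nc$pairs), nrow(exp_pairs))
  expect_equal(nc$pairs$i, exp_pairs[, 1])
  expect_equal(nc$pairs$j, exp_pairs[, 2])
  expect_equal(nc$pairs$r_native, exp_pairs[, 3])
})

test_that("native_contacts is invariant under rigid motion", {
  set.seed(7)
  R <- random_rotation()
  cg2 <- fx$cg_rb
  cg2$xyz <- fx$cg_rb$xyz %*% t(R) + matrix(c(10, -4, 2), nrow(fx$cg_rb$xyz),
                                            3, byrow = TRUE)
  nc2 <- native_contacts(cg2)
  expect_equal(nc2$pairs$i, fx$nc_rb$pairs$i)
  expect_equal(nc2$pairs$j, fx$nc_rb$pairs$j)
  expect_equal(nc2$pairs$r_native, fx$nc_rb$pairs$r_native,
               tolerance = 1e-10)
})

test_that("the folded reference scores Q = 1 against its own contacts", {
  expect_identical(fraction_native(fx$cg_rb$xyz, fx$nc_rb), 1)
})

test_that("annotation lists validate indices and round-trip through TSV", {
  txt <- c("pair\t3\t29\tcWW", "pair\t4\t28\tcWW", "stack\t1\t2")
  ann <- read_annotations(text = txt, n_residues = 52)
  expect_equal(nrow(ann$base_pairs), 2L)
  expect_equal(ann$base_pairs$class, c("cWW", "cWW"))
  expect_equal(nrow(ann$stacks), 1L)
  expect_error(read_annotations(text = "pair\t1\t99", n_residues = 52),
               "exceeds")
  expect_error(read_annotations(text = "pair\t5\t5"), "self-pairs")
})

test_that("cg structures and contact sets round-trip through files", {
  td <- withr::local_tempdir()
  p1 <- file.path(td, "cg.pdb")
  write_cg_pdb(fx$cg_hp, p1)
  reread <- load_structure(readLines(p1), "A")
  expect_equal(max(reread$atoms$residue_index), 12L)
  p2 <- file.path(td, "contacts.tsv")
  write_contacts_tsv(fx$nc_hp, p2)
  nc2 <- read_contacts_tsv(p2)
  expect_equal(nc2$pairs$r_native, fx$nc_hp$pairs$r_native)
})
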