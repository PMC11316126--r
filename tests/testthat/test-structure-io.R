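# Structure I/O: cells, symmetry operators, PDB/mmCIF parsing and writing.

test_that("fractional/Cartesian conversion round-trips to 1e-9 A", {
  set.seed(7)
  for (k in 1:5) {
    cl <- random_cell()
    pts <- matrix(runif(3000, -3, 3), ncol = 3)
    back <- cart_to_frac(frac_to_cart(pts, cl), cl)
    expect_lt(max(abs(back - pts)), 1e-9)
  }
  expect_error(unit_cell(-1, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, alpha = 181), "angles")
})

test_that("space-group operator sets are closed under composition", {
  for (sym in c("P 21", "P 21 21 21", "C 2")) {
    ops <- space_group_ops(sym)
    set.seed(1)
    p <- runif(3)
    images <- lapply(ops, function(op) stericzipper:::apply_sym_op(op, p))
    for (i in seq_along(ops)) for (j in seq_along(ops)) {
      comp <- stericzipper:::compose_sym_ops(ops[[i]], ops[[j]])
      q <- stericzipper:::apply_sym_op(comp, p) %% 1
      hits <- vapply(images, function(im) {
        d <- (im - q) %% 1
        all(pmin(d, 1 - d) < 1e-9)
      }, logical(1))
      expect_true(any(hits))
    }
  }
  expect_error(space_group_ops("I 41 3 2"), "unsupported-spacegroup")
  expect_equal(length(space_group_ops("P2_1_2_1_2_1")), 4)
  expect_equal(length(space_group_ops("P 1 21 1")), 2)
})

test_that("a minimal one-atom PDB parses to one atom and the identity", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_lines(), tf)
  s <- parse_structure(tf)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(length(s$sym_ops), 1)
  expect_equal(s$cell$a, 10)
  expect_equal(s$atoms$x, 1)
})

test_that("parse errors name the failure mode", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_lines()[-1], tf) # no CRYST1
  expect_error(parse_structure(tf), "no-symmetry")
  writeLines(minimal_pdb_lines("CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 F 4 3 2      1"), tf)
  expect_error(parse_structure(tf), "unsupported-spacegroup")
  writeLines(minimal_pdb_lines()[c(1, 3)], tf) # zero atoms
  expect_error(parse_structure(tf), "zero atom")
})

test_that("hydrogens are dropped and one altloc conformer is kept", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   TYR A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA ATYR A   1       1.400   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA BTYR A   1       1.600   0.000   0.000  0.40 10.00           C",
    "ATOM      4  HA  TYR A   1       1.400   1.000   0.000  1.00 10.00           H",
    "END"), tf)
  s <- parse_structure(tf)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 1.4) # altloc A kept
  s2 <- parse_structure(tf, keep_altloc = "B")
  expect_equal(s2$atoms$x[s2$atoms$name == "CA"], 1.6)
  s3 <- parse_structure(tf, keep_altloc = "occupancy")
  expect_equal(s3$atoms$x[s3$atoms$name == "CA"], 1.4)
})

test_that("write/parse round trip preserves coordinates, cell and symmetry", {
  s <- synthetic_analogue("8QWV")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, tf)
  s2 <- parse_structure(tf)
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                    as.matrix(s$atoms[, c("x", "y", "z")]))), 1e-3 + 1e-9)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$resseq, s$atoms$resseq)
  expect_equal(length(s2$sym_ops), length(s$sym_ops))
  expect_equal(s2$cell$b, s$cell$b)
  # second write of the re-parsed structure is byte-stable
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s2, tf2)
  s3 <- parse_structure(tf2)
  tf3 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s3, tf3)
  expect_identical(readLines(tf2), readLines(tf3))
})

test_that("classification is unchanged by a write/parse round trip", {
  s <- fixture_lattice(1)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, tf)
  r1 <- zipper_analysis(s, energies = FALSE, geometry = FALSE,
                        rank_areas = FALSE)
  r2 <- zipper_analysis(parse_structure(tf), energies = FALSE,
                        geometry = FALSE, rank_areas = FALSE)
  expect_equal(r2$topology$overall$class_id, r1$topology$overall$class_id)
  expect_equal(length(r2$interfaces), length(r1$interfaces))
})

test_that("mmCIF input with explicit symmetry operators is read", {
  tf <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "_cell.length_a    4.840",
    "_cell.length_b    42.425",
    "_cell.length_c    22.256",
    "_cell.angle_alpha 90.00",
    "_cell.angle_beta  94.57",
    "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M 'P 1 21 1'",
    "loop_",
    "_symmetry_equiv.id",
    "_symmetry_equiv.pos_as_xyz",
    "1 'X,Y,Z'",
    "2 '-X,Y+1/2,-Z'",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id",
    "ATOM 1 N N . LEU A 1 0.000 0.000 0.000 1.00 15.0 1 A",
    "ATOM 2 C CA . LEU A 1 1.458 0.000 0.000 1.00 15.0 1 A",
    "#"), tf)
  s <- parse_structure(tf)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$cell$a, 4.840)
  expect_equal(s$cell$beta, 94.57)
  expect_equal(length(s$sym_ops), 2)
  # the explicit screw operator matches the internal P 21 table
  expect_equal(s$sym_ops[[2]]$R, space_group_ops("P 21")[[2]]$R)
  expect_equal(s$sym_ops[[2]]$t, space_group_ops("P 21")[[2]]$t)
})

test_that("explicit PDB REMARK 290 operators override the symbol table", {
  s <- synthetic_analogue("8QWU")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, tf)
  lines <- readLines(tf)
  smtry <- c(
    "REMARK 290   SMTRY1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 290   SMTRY2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 290   SMTRY3   1  0.000000  0.000000  1.000000        0.00000",
    "REMARK 290   SMTRY1   2 -1.000000  0.000000  0.000000        2.42400",
    "REMARK 290   SMTRY2   2  0.000000 -1.000000  0.000000        0.00000",
    "REMARK 290   SMTRY3   2  0.000000  0.000000  1.000000       21.32500")
  writeLines(c(lines[1], smtry, lines[-1]), tf)
  s2 <- parse_structure(tf)
  expect_equal(length(s2$sym_ops), 2) # explicit records win over the symbol
  expect_equal(s2$sym_ops[[2]]$R, diag(c(-1, -1, 1)))
  expect_equal(s2$sym_ops[[2]]$t, c(0.5, 0, 0.5))
})
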