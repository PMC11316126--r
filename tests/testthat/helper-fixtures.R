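# Shared fixtures, memoized so expensive lattices and analyses are built
# once per test run.

.fx <- new.env(parent = emptyenv())

fixture_lattice <- function(class_id, sequence = NULL, ...) {
  if (is.null(sequence)) {
    sequence <- if (class_id %in% 5:8) "LYIQWL" else "LYIQNL"
  }
  key <- paste0("lat_", class_id, "_", sequence)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- build_lattice(lattice_spec(class_id, sequence, ...))
  }
  .fx[[key]]
}

# classification-only analysis (no SASA)
fixture_classification <- function(class_id, sequence = NULL) {
  key <- paste0("cls_", class_id, "_", sequence %||% "default")
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- zipper_analysis(fixture_lattice(class_id, sequence),
                                  energies = FALSE, geometry = FALSE,
                                  rank_areas = FALSE)
  }
  .fx[[key]]
}

# full analysis of the monoclinic-form synthetic stand-in
fixture_class3_full <- function() {
  if (is.null(.fx$full3)) {
    .fx$full3 <- zipper_analysis(fixture_lattice(3))
  }
  .fx$full3
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rigid-body transform of a whole structure (rotation + translation)
rigid_transform <- function(s, angle = 0.7, axis = c(0, 0, 1),
                            shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, shift, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# translate one sheet of a double layer (breaks the interface when large)
shift_double_layer_sheet <- function(dl, dz = 100) {
  dl$sheets[[2]]$strands <- lapply(dl$sheets[[2]]$strands, function(st) {
    st$atoms$z <- st$atoms$z + dz
    st$xyz <- NULL; st$centroid <- NULL
    st
  })
  dl
}

# Monte-Carlo point-rejection SASA oracle (random, seeded): independent of
# the deterministic spiral-point implementation under test.
mc_sasa_total <- function(xyz, radii, probe = 1.4, n_total = 1e6, seed = 42) {
  set.seed(seed)
  n <- nrow(xyz)
  m <- ceiling(n_total / n)
  R <- radii + probe
  total <- 0
  for (i in seq_len(n)) {
    p <- matrix(stats::rnorm(3 * m), m, 3)
    p <- p / sqrt(rowSums(p^2))
    sp <- sweep(p * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, m)
    for (j in seq_len(n)[-i]) {
      d2 <- rowSums(sweep(sp, 2, xyz[j, ])^2)
      acc <- acc & d2 >= R[j]^2
    }
    total <- total + 4 * pi * R[i]^2 * mean(acc)
  }
  total
}

# minimal hand-written PDB contents
minimal_pdb_lines <- function(cryst = "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1           1") {
  c(cryst,
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 10.00           C",
    "END")
}

# a random but valid unit cell
random_cell <- function() {
  unit_cell(runif(1, 4, 50), runif(1, 4, 50), runif(1, 4, 50),
            runif(1, 70, 110), runif(1, 70, 110), runif(1, 70, 110))
}
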