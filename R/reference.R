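# Published unit cells of the hexapeptide crystals handled by this package,
# and synthetic analogue lattices carrying those cells.

#' Published unit cells of the LYIQNL / LYIQWL crystal forms
#'
#' The data-collection cell constants and space groups of the three deposited
#' hexapeptide crystal structures: the monoclinic (class 3) and orthorhombic
#' (class 4) forms of LYIQNL and the monoclinic class 4 form of LYIQWL.
#'
#' @return A data.frame with one row per structure: `id`, `sequence`,
#'   `class_overall`, cell constants and `space_group`.
#' @export
reference_cells <- function() {
  data.frame(
    id = c("8QWV", "8QWU", "8QWW"),
    sequence = c("LYIQNL", "LYIQNL", "LYIQWL"),
    class_overall = c(3L, 4L, 4L),
    a = c(4.840, 4.848, 4.874),
    b = c(42.425, 20.005, 42.270),
    c = c(22.256, 42.650, 21.442),
    alpha = c(90, 90, 90),
    beta = c(94.57, 90, 90),
    gamma = c(90, 90, 90),
    space_group = c("P 21", "P 21 21 21", "P 21"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic analogue of a deposited crystal form
#'
#' Builds an idealized stand-in for one of the deposited hexapeptide
#' crystals: ideal strands placed in the *published* unit cell and space
#' group so that the crystal symmetry generates the packing. These are
#' synthetic models (the deposited coordinates are not redistributed here);
#' they reproduce the lattice metric, symmetry and topology of the real
#' crystal forms, not their refined side-chain conformations.
#'
#' In the monoclinic LYIQNL form the 2(1) screw runs along the strand
#' direction (b), which is exactly the face-to-face relation of its two
#' zipper interfaces; the analogue therefore uses a two-chain asymmetric
#' unit (one strand per sheet) like the deposited form. The orthorhombic
#' form needs a single chain: its 2(1) axis along the sheet normal (b)
#' generates the face-to-back partner sheet.
#'
#' @param id `"8QWV"`, `"8QWU"` or `"8QWW"`.
#' @return A [crystal_structure()] with `source_id` marked `synthetic`.
#' @export
synthetic_analogue <- function(id = c("8QWV", "8QWU", "8QWW")) {
  id <- match.arg(id)
  ref <- reference_cells()
  r <- ref[ref$id == id, ]
  cell <- unit_cell(r$a, r$b, r$c, r$alpha, r$beta, r$gamma)
  strand <- build_ideal_strand(r$sequence, chain = "A")
  if (id %in% c("8QWV", "8QWW")) {
    # strand along b (the 2(1) axis), rise along a, sheet normal along c:
    # canonical (x,y,z) -> (y,x,-z) is a proper rotation doing that swap
    R <- matrix(c(0, 1, 0,
                  1, 0, 0,
                  0, 0, -1), 3, 3, byrow = TRUE)
    A <- .transform_atoms(strand, R)
    centre <- function(fx, fy, fz) frac_to_cart(c(fx, fy, fz), cell)
    A <- .shift_to(A, centre(0.25, 0.25, 0.25))
    if (id == "8QWV") {
      # second chain = partner sheet via rotation about the strand axis (b):
      # like surfaces meet (class 3)
      B <- .transform_atoms(A, diag(c(-1, 1, -1)))
    } else {
      # rotation about the sheet normal (c): unlike surfaces, opposite
      # direction (class 4)
      B <- .transform_atoms(A, diag(c(-1, -1, 1)))
    }
    B$chain <- "B"
    B <- .shift_to(B, centre(0.75, 0.25, 0.75))
    atoms <- rbind(A, B)
  } else {
    # orthorhombic: strand along c, rise along a, sheet normal along b;
    # canonical (x,y,z) -> (y,z,x) cyclic (proper)
    R <- matrix(c(0, 1, 0,
                  0, 0, 1,
                  1, 0, 0), 3, 3, byrow = TRUE)
    A <- .transform_atoms(strand, R)
    A <- .shift_to(A, frac_to_cart(c(0.25, 0.25, 0.25), cell))
    atoms <- A
  }
  atoms$serial <- seq_len(nrow(atoms))
  crystal_structure(atoms, cell, r$space_group,
                    source_id = paste0(id, "-synthetic-analogue"))
}

.shift_to <- function(atoms, target) {
  xyz <- atom_xyz(atoms)
  set_atom_xyz(atoms, sweep(xyz, 2, target - colMeans(xyz), "+"))
}
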