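# Generator of idealized cross-beta lattices for any topology class and
# sequence, so every pipeline stage is testable without external structure
# files.
#
# Canonical generator frame: strand N-to-C along +x, fibril (stacking) axis
# along +y with the ~4.8 A cross-beta rise, sheet normal along +z; the side
# chains of even-numbered residues point to +z ("face"). The second sheet is
# produced by the rigid operation that realizes the requested class's
# descriptors: parity-same classes flip the partner about an axis
# perpendicular to z (so like surfaces meet), direction-opposite classes
# reverse the strand direction.

#' Lattice specification
#'
#' Parameters of an idealized cross-beta crystal built by [build_lattice()].
#'
#' @param class_id Topology class 1-8. Classes 9 and 10 have no transcribed
#'   construction and are refused.
#' @param sequence One-letter peptide sequence, length 4-10.
#' @param rise Fibril-axis repeat in Angstrom (default 4.8; must lie in the
#'   4.3-5.3 cross-beta window).
#' @param sheet_spacing Backbone-plane separation of the two sheets in
#'   Angstrom (default 10).
#' @param conformation Backbone (phi, psi) in degrees (default ideal beta).
#' @param n_strands Strands per sheet intended for downstream stacks
#'   (metadata; the emitted P 1 cell regenerates any number by translation).
#' @param n_sheets Number of sheet positions emitted explicitly (default 2).
#' @param seed Seed reserved for side-chain jitter ([perturb_lattice()]).
#' @return A `lattice_spec` list.
#' @export
lattice_spec <- function(class_id, sequence, rise = 4.8, sheet_spacing = 10,
                         conformation = c(-139, 135), n_strands = 6,
                         n_sheets = 2, seed = 1L) {
  stopifnot(rise >= 4.3, rise <= 5.3, n_sheets >= 2)
  nc <- nchar(sequence)
  if (nc < 4 || nc > 10) stop("lattice_spec: sequence length must be 4-10")
  tab <- zipper_class_table()
  row <- tab[tab$class_id == class_id, , drop = FALSE]
  if (!nrow(row)) stop("lattice_spec: class ", class_id, " not in lookup table")
  if (row$extra_symmetry_flag[1] != "none") {
    stop("lattice_spec: class ", class_id,
         " is untranscribed (no published construction); refusing to improvise")
  }
  structure(
    list(class_id = class_id, sequence = toupper(sequence), rise = rise,
         sheet_spacing = sheet_spacing, conformation = conformation,
         n_strands = n_strands, n_sheets = n_sheets, seed = seed,
         descriptors = list(sheet_sense = row$sheet_sense[1],
                            surface_parity = row$surface_parity[1],
                            sheet_direction = row$sheet_direction[1])),
    class = "lattice_spec"
  )
}

# rigid orientations about the strand centre used to place the second sheet
.orient_ops <- list(
  I = diag(3),
  Rx = diag(c(1, -1, -1)),   # about the strand axis: flips parity
  Ry = diag(c(-1, 1, -1)),   # about the fibril axis: flips parity + direction
  Rz = diag(c(-1, -1, 1))    # about the sheet normal: flips direction
)

.orient_for_descriptors <- function(d) {
  parity_flip <- d$surface_parity == "same"   # like surfaces meet
  dir_flip <- d$sheet_direction == "opposite"
  if (parity_flip && !dir_flip) return(.orient_ops$Rx)
  if (parity_flip && dir_flip) return(.orient_ops$Ry)
  if (!parity_flip && !dir_flip) return(.orient_ops$I)
  .orient_ops$Rz
}

.transform_atoms <- function(atoms, R = diag(3), t = c(0, 0, 0)) {
  set_atom_xyz(atoms, sweep(atom_xyz(atoms) %*% t(R), 2, t, "+"))
}

# x-offset of the antiparallel partner strand maximizing the H-bond register
# (deterministic grid search).
.antiparallel_offset <- function(strand, rise) {
  flipped <- .transform_atoms(strand, .orient_ops$Rz)
  N0 <- atom_xyz(strand[strand$name == "N", , drop = FALSE])
  O0 <- atom_xyz(strand[strand$name == "O", , drop = FALSE])
  Nf <- atom_xyz(flipped[flipped$name == "N", , drop = FALSE])
  Of <- atom_xyz(flipped[flipped$name == "O", , drop = FALSE])
  score <- function(dx) {
    sh <- c(dx, rise, 0)
    m1 <- .min_cross_dist(sweep(Nf, 2, sh, "+"), O0)
    m2 <- .min_cross_dist(N0, sweep(Of, 2, sh, "+"))
    sh2 <- c(dx, -rise, 0)
    m3 <- .min_cross_dist(sweep(Nf, 2, sh2, "+"), O0)
    m4 <- .min_cross_dist(N0, sweep(Of, 2, sh2, "+"))
    (min(m1, m2) - 2.9)^2 + (min(m3, m4) - 2.9)^2
  }
  grid <- seq(-4, 4, by = 0.05)
  grid[which.min(vapply(grid, score, numeric(1)))]
}

#' Build an idealized cross-beta lattice
#'
#' Constructs a crystal of the requested topology class: sheet 1 is the
#' ideal strand repeated by the rise translation (parallel classes) or a
#' two-strand antiparallel repeat; sheet 2 is placed `sheet_spacing` away by
#' the rigid operation realizing the class descriptors. The structure is
#' emitted in P 1 with one translational repeat per sheet and a cell whose
#' b edge equals the fibril repeat and whose c edge equals twice the sheet
#' spacing, so the standard expand/sheets/interfaces path reconstructs the
#' full packing (including the alternating interface types of face-to-face
#' classes).
#'
#' @param spec A [lattice_spec()] (or a class id, with `...` passed to
#'   [lattice_spec()]).
#' @param ... Used when `spec` is a class id.
#' @return A [crystal_structure()].
#' @examples
#' s <- build_lattice(lattice_spec(3, "LYIQNL"))
#' @export
build_lattice <- function(spec, ...) {
  if (!inherits(spec, "lattice_spec")) spec <- lattice_spec(spec, ...)
  d <- spec$descriptors
  strand <- build_ideal_strand(spec$sequence, spec$conformation, chain = "A")
  parallel <- d$sheet_sense == "parallel"
  rise <- spec$rise
  repeat_b <- if (parallel) rise else 2 * rise
  # sheet 1 translational repeat
  sheet1 <- list(strand)
  if (!parallel) {
    dx <- .antiparallel_offset(strand, rise)
    partner <- .transform_atoms(strand, .orient_ops$Rz, c(dx, rise, 0))
    partner$chain <- "B"
    sheet1 <- c(sheet1, list(partner))
  }
  # sheet 2: class operation about the strand centre, then offset
  R <- .orient_for_descriptors(d)
  y_off <- if (parallel) rise / 2 else 0
  x_off <- if (parallel) 0 else 2.4
  chains2 <- c("C", "D")
  sheet2 <- lapply(seq_along(sheet1), function(k) {
    at <- .transform_atoms(sheet1[[k]], R,
                           c(x_off, y_off, spec$sheet_spacing))
    at$chain <- chains2[k]
    # keep the emitted motif inside one b-repeat
    yc <- mean(at$y)
    if (yc >= repeat_b) at$y <- at$y - repeat_b
    if (yc < -repeat_b / 2) at$y <- at$y + repeat_b
    at
  })
  # two explicit sheet positions suffice: the c = 2 * spacing lattice period
  # regenerates the alternating stacking (sheet 3 is sheet 1 shifted by c),
  # including both interface types of the face-to-face classes
  sheets <- c(sheet1, sheet2)
  atoms <- do.call(rbind, sheets)
  atoms$serial <- seq_len(nrow(atoms))
  xr <- range(atoms$x)
  a_len <- diff(xr) + 12
  cell <- unit_cell(a_len, repeat_b, 2 * spec$sheet_spacing)
  # place the motif inside the cell
  atoms$x <- atoms$x - xr[1] + 6
  atoms$z <- atoms$z + spec$sheet_spacing / 2
  atoms <- atoms[order(atoms$chain, atoms$resseq, atoms$serial), ]
  atoms$serial <- seq_len(nrow(atoms))
  crystal_structure(atoms, cell, "P 1",
                    source_id = sprintf("synthetic-class%d-%s",
                                        spec$class_id, spec$sequence))
}

#' Perturb side chains of a structure
#'
#' Adds seeded Gaussian jitter to side-chain atoms (backbone N, CA, C, O,
#' OXT fixed); deterministic for a fixed seed and leaves the input
#' untouched for `sigma = 0`.
#'
#' @param s A [crystal_structure()].
#' @param sigma Jitter standard deviation in Angstrom.
#' @param seed Integer seed.
#' @return A perturbed [crystal_structure()].
#' @export
perturb_lattice <- function(s, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(s)
  atoms <- s$atoms
  side <- !(atoms$name %in% .backbone_names)
  n <- sum(side)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  jit <- matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
  xyz <- atom_xyz(atoms)
  xyz[side, ] <- xyz[side, ] + jit
  s$atoms <- set_atom_xyz(atoms, xyz)
  s
}
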