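# Internal-coordinate construction of idealized all-heavy-atom peptides.
#
# Atoms are placed by the standard natural-extension-reference-frame rule:
# given three placed atoms a-b-c, atom d is set by bond length c-d, angle
# b-c-d and torsion a-b-c-d. Side chains use one fixed, common beta-sheet
# rotamer per residue type, so generated structures are fully deterministic.

place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# backbone geometry (Engh-Huber-style ideal values)
.bb <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.530,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, ang_n_ca_cb = 110.5,
  # improper torsion C'-N-CA-CB fixing the L configuration
  tor_cb = -122.6
)

# Side-chain templates: atom, reference triple (a, b, c), bond, angle,
# torsion. References may name backbone atoms (N, CA, C) or earlier
# side-chain atoms of the same residue.
.sc_templates <- list(
  GLY = list(),
  ALA = list(),
  VAL = list(
    c("CG1", "N", "CA", "CB", 1.52, 110.5, 175),
    c("CG2", "N", "CA", "CB", 1.52, 110.5, 53)
  ),
  LEU = list(
    c("CG", "N", "CA", "CB", 1.53, 116.3, -65),
    c("CD1", "CA", "CB", "CG", 1.52, 110.7, 175),
    c("CD2", "CA", "CB", "CG", 1.52, 110.7, 53)
  ),
  ILE = list(
    c("CG1", "N", "CA", "CB", 1.53, 110.4, -65),
    c("CG2", "N", "CA", "CB", 1.52, 110.5, 173),
    c("CD1", "CA", "CB", "CG1", 1.51, 113.8, 170)
  ),
  SER = list(c("OG", "N", "CA", "CB", 1.42, 111.1, -65)),
  THR = list(
    c("OG1", "N", "CA", "CB", 1.43, 109.6, -60),
    c("CG2", "N", "CA", "CB", 1.52, 110.5, 178)
  ),
  CYS = list(c("SG", "N", "CA", "CB", 1.81, 114.4, -65)),
  MET = list(
    c("CG", "N", "CA", "CB", 1.52, 114.1, -65),
    c("SD", "CA", "CB", "CG", 1.80, 112.7, 180),
    c("CE", "CB", "CG", "SD", 1.79, 100.8, 75)
  ),
  ASP = list(
    c("CG", "N", "CA", "CB", 1.52, 112.6, -70),
    c("OD1", "CA", "CB", "CG", 1.25, 118.4, -15),
    c("OD2", "CA", "CB", "CG", 1.25, 118.4, 165)
  ),
  GLU = list(
    c("CG", "N", "CA", "CB", 1.52, 114.1, -65),
    c("CD", "CA", "CB", "CG", 1.52, 112.6, 180),
    c("OE1", "CB", "CG", "CD", 1.25, 118.4, -10),
    c("OE2", "CB", "CG", "CD", 1.25, 118.4, 170)
  ),
  LYS = list(
    c("CG", "N", "CA", "CB", 1.52, 114.1, -65),
    c("CD", "CA", "CB", "CG", 1.52, 111.3, 180),
    c("CE", "CB", "CG", "CD", 1.52, 111.3, 180),
    c("NZ", "CG", "CD", "CE", 1.49, 111.9, 180)
  ),
  ARG = list(
    c("CG", "N", "CA", "CB", 1.52, 114.1, -65),
    c("CD", "CA", "CB", "CG", 1.52, 111.3, 180),
    c("NE", "CB", "CG", "CD", 1.46, 112.0, 180),
    c("CZ", "CG", "CD", "NE", 1.33, 124.2, 180),
    c("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
    c("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180)
  ),
  HIS = list(
    c("CG", "N", "CA", "CB", 1.50, 113.8, -65),
    c("ND1", "CA", "CB", "CG", 1.38, 122.7, -75),
    c("CD2", "CA", "CB", "CG", 1.36, 131.1, 105),
    c("CE1", "CB", "CG", "ND1", 1.32, 109.2, 180),
    c("NE2", "CB", "CG", "CD2", 1.37, 107.2, 180)
  ),
  ASN = list(
    c("CG", "N", "CA", "CB", 1.52, 112.6, -65),
    c("OD1", "CA", "CB", "CG", 1.23, 120.8, -60),
    c("ND2", "CA", "CB", "CG", 1.33, 116.4, 120)
  ),
  GLN = list(
    c("CG", "N", "CA", "CB", 1.52, 114.1, 180),
    c("CD", "CA", "CB", "CG", 1.52, 112.6, 180),
    c("OE1", "CB", "CG", "CD", 1.23, 120.8, 0),
    c("NE2", "CB", "CG", "CD", 1.33, 116.4, 180)
  ),
  PHE = list(
    c("CG", "N", "CA", "CB", 1.50, 113.8, 180),
    c("CD1", "CA", "CB", "CG", 1.39, 120.8, 80),
    c("CD2", "CA", "CB", "CG", 1.39, 120.8, -100),
    c("CE1", "CD2", "CG", "CD1", 1.39, 120.0, 0),
    c("CE2", "CD1", "CG", "CD2", 1.39, 120.0, 0),
    c("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0)
  ),
  TYR = list(
    c("CG", "N", "CA", "CB", 1.51, 113.8, 180),
    c("CD1", "CA", "CB", "CG", 1.39, 120.8, 80),
    c("CD2", "CA", "CB", "CG", 1.39, 120.8, -100),
    c("CE1", "CD2", "CG", "CD1", 1.39, 121.1, 0),
    c("CE2", "CD1", "CG", "CD2", 1.39, 121.1, 0),
    c("CZ", "CG", "CD1", "CE1", 1.38, 119.5, 0),
    c("OH", "CD1", "CE1", "CZ", 1.38, 119.8, 180)
  ),
  TRP = list(
    c("CG", "N", "CA", "CB", 1.50, 113.6, 180),
    c("CD1", "CA", "CB", "CG", 1.37, 126.9, 90),
    c("CD2", "CA", "CB", "CG", 1.43, 126.7, -90),
    c("NE1", "CD2", "CG", "CD1", 1.38, 110.2, 0),
    c("CE2", "CD1", "CG", "CD2", 1.41, 107.2, 0),
    c("CE3", "CD1", "CG", "CD2", 1.40, 133.9, 180),
    c("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 180),
    c("CZ3", "CG", "CD2", "CE3", 1.39, 118.6, 180),
    c("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0)
  )
)

.aa1to3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", S = "SER", T = "THR", W = "TRP", Y = "TYR",
  V = "VAL"
)

#' Build an idealized beta-strand
#'
#' Constructs an all-heavy-atom peptide in an ideal extended conformation
#' from standard bond geometry, with side chains in a single fixed common
#' rotamer per residue type. The strand is oriented with its N-to-C
#' direction along +x, mean backbone at the origin, and the side chains of
#' even-numbered residues pointing to +z ("face") and odd-numbered to -z
#' ("back"). A C-terminal OXT completes the carboxylate (the modelled
#' peptides are zwitterions).
#'
#' @param sequence One-letter peptide sequence (proline is not supported:
#'   its ring breaks the ideal extended backbone).
#' @param conformation Backbone `(phi, psi)` in degrees; default ideal
#'   beta-strand (-139, 135).
#' @param chain Chain identifier for the atom table.
#' @return Atom data.frame (see [crystal_structure()]).
#' @examples
#' st <- build_ideal_strand("LYIQNL")
#' nrow(st)
#' @export
build_ideal_strand <- function(sequence, conformation = c(-139, 135),
                               chain = "A") {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- !letters1 %in% names(.aa1to3)
  if (any(bad)) {
    stop("build_ideal_strand: unsupported residue letter(s): ",
         paste(unique(letters1[bad]), collapse = ", "))
  }
  res3 <- unname(.aa1to3[letters1])
  n_res <- length(res3)
  phi <- conformation[1]; psi <- conformation[2]
  coords <- list()
  # backbone
  N <- matrix(NA_real_, n_res + 1, 3)
  CA <- matrix(NA_real_, n_res + 1, 3)
  C <- matrix(NA_real_, n_res, 3)
  O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.bb$n_ca, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], .bb$ca_c, .bb$ang_n_ca_c, 0)
  for (i in seq_len(n_res)) {
    # next amide N via psi, then CA via omega (180), then next C via phi
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], .bb$c_n,
                             .bb$ang_ca_c_n, psi)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], .bb$c_o, .bb$ang_ca_c_o,
                         psi + 180)
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], .bb$n_ca,
                              .bb$ang_c_n_ca, 180)
    if (i < n_res) {
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], .bb$ca_c,
                               .bb$ang_n_ca_c, phi)
    }
  }
  rows <- list()
  serial <- 0L
  add <- function(name, xyz, resname, resseq) {
    serial <<- serial + 1L
    rows[[length(rows) + 1]] <<- data.frame(
      serial = serial, name = name, altloc = "", resname = resname,
      chain = chain, resseq = resseq, x = xyz[1], y = xyz[2], z = xyz[3],
      occ = 1, b = 0,
      element = substr(name, 1, 1), stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(n_res)) {
    rn <- res3[i]
    add("N", N[i, ], rn, i)
    add("CA", CA[i, ], rn, i)
    add("C", C[i, ], rn, i)
    add("O", O[i, ], rn, i)
    placed <- list(N = N[i, ], CA = CA[i, ], C = C[i, ])
    if (rn != "GLY") {
      placed$CB <- place_atom(placed$C, placed$N, placed$CA, .bb$ca_cb,
                              .bb$ang_n_ca_cb, .bb$tor_cb)
      add("CB", placed$CB, rn, i)
    }
    for (tmpl in .sc_templates[[rn]]) {
      nm <- tmpl[1]
      refs <- tmpl[2:4]
      xyz <- place_atom(placed[[refs[1]]], placed[[refs[2]]],
                        placed[[refs[3]]],
                        as.numeric(tmpl[5]), as.numeric(tmpl[6]),
                        as.numeric(tmpl[7]))
      placed[[nm]] <- xyz
      add(nm, xyz, rn, i)
    }
    if (i == n_res) {
      add("OXT", place_atom(N[i, ], CA[i, ], C[i, ], 1.25,
                            .bb$ang_ca_c_o, psi), rn, i)
    }
  }
  atoms <- do.call(rbind, rows)
  # orient: N-to-C along +x, centre at origin, even side chains to +z
  atoms <- .orient_strand(atoms)
  atoms
}

# Rigidly reorient a freshly built strand into the canonical frame.
.orient_strand <- function(atoms) {
  xyz <- atom_xyz(atoms)
  ca <- xyz[atoms$name == "CA", , drop = FALSE]
  # x: overall N->C direction from the CA trace
  xaxis <- ca[nrow(ca), ] - ca[1, ]
  xaxis <- xaxis / sqrt(sum(xaxis^2))
  # z: mean CA->CB vector of even residues, orthogonalized
  cb <- atoms[atoms$name == "CB" & atoms$resseq %% 2 == 0, , drop = FALSE]
  cax <- atoms[atoms$name == "CA", , drop = FALSE]
  if (nrow(cb)) {
    v <- colMeans(atom_xyz(cb) -
                  atom_xyz(cax[match(cb$resseq, cax$resseq), , drop = FALSE]))
  } else {
    cb1 <- atoms[atoms$name == "CB", , drop = FALSE]
    v <- -colMeans(atom_xyz(cb1) -
                   atom_xyz(cax[match(cb1$resseq, cax$resseq), , drop = FALSE]))
  }
  zaxis <- v - sum(v * xaxis) * xaxis
  zaxis <- zaxis / sqrt(sum(zaxis^2))
  yaxis <- .cross3(zaxis, xaxis)
  R <- rbind(xaxis, yaxis, zaxis)
  ctr <- colMeans(xyz)
  set_atom_xyz(atoms, sweep(xyz, 2, ctr) %*% t(R))
}
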