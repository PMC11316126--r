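# Interface geometry: aromatic pair geometry, side-chain ladder spacings,
# and end-to-end distances of (like-charged) chain termini.

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Dihedral angle
#'
#' Signed dihedral angle (degrees, in (-180, 180]) defined by four points.
#'
#' @param p1,p2,p3,p4 Cartesian points (length-3 numeric).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p1 - p2; b2 <- p3 - p2; b3 <- p4 - p3
  v <- b1 - sum(b1 * b2) / sum(b2 * b2) * b2
  w <- b3 - sum(b3 * b2) / sum(b2 * b2) * b2
  y <- sum(.cross3(b2 / sqrt(sum(b2^2)), v) * w)
  atan2(y, sum(v * w)) * 180 / pi
}

# Six-membered (or imidazole) ring atoms used for centroid/plane fits.
# For Trp the benzo ring is used, matching the displaced-stacking geometry
# measured for Tyr.
.ring_atom_names <- list(
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

.ring_coords <- function(res) {
  rn <- unique(res$resname)
  if (length(rn) != 1 || !rn %in% names(.ring_atom_names)) {
    stop("aromatic geometry: residue is not aromatic (Tyr/Trp/Phe/His)")
  }
  need <- .ring_atom_names[[rn]]
  sel <- res[match(need, res$name), , drop = FALSE]
  if (anyNA(sel$name)) {
    stop("incomplete-ring: residue ", rn, unique(res$resseq)[1],
         " lacks ring atoms ", paste(setdiff(need, res$name), collapse = ", "))
  }
  atom_xyz(sel)
}

.ring_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Aromatic ring pair geometry
#'
#' Centroid distance and acute interplanar angle of two aromatic side
#' chains. The centroid is the mean of the six-membered ring heavy atoms
#' (Tyr/Phe: CG, CD1, CD2, CE1, CE2, CZ; Trp: the benzo ring; His: the
#' imidazole); the ring plane is the best-fit plane (smallest principal
#' direction as normal) and the angle is folded to [0, 90] degrees.
#'
#' @param res_a,res_b Atom tables of single aromatic residues.
#' @return List of class `aromatic_pair_geometry` with `centroid_distance`
#'   (Angstrom), `interplanar_angle` (degrees), `residue_a`, `residue_b`.
#' @export
aromatic_pair_geometry <- function(res_a, res_b) {
  pa <- .ring_plane(.ring_coords(res_a))
  pb <- .ring_plane(.ring_coords(res_b))
  d <- sqrt(sum((pa$centroid - pb$centroid)^2))
  cosang <- abs(sum(pa$normal * pb$normal))
  ang <- acos(pmin(1, cosang)) * 180 / pi
  structure(
    list(residue_a = paste0(unique(res_a$resname), unique(res_a$resseq)[1]),
         residue_b = paste0(unique(res_b$resname), unique(res_b$resseq)[1]),
         centroid_distance = d, interplanar_angle = ang),
    class = "aromatic_pair_geometry"
  )
}

#' @export
print.aromatic_pair_geometry <- function(x, ...) {
  cat(sprintf("%s - %s: centroid distance %.2f A, interplanar angle %.1f deg\n",
              x$residue_a, x$residue_b, x$centroid_distance,
              x$interplanar_angle))
  invisible(x)
}

#' Interplanar (normal-projected) distance of two aromatic rings
#'
#' The centroid-to-centroid vector projected on the mean ring normal: the
#' separation of the two ring planes, reported alongside the interplanar
#' angle so stacked-versus-distant calls are auditable.
#'
#' @param res_a,res_b Atom tables of single aromatic residues.
#' @return Distance in Angstrom.
#' @export
interplanar_distance <- function(res_a, res_b) {
  pa <- .ring_plane(.ring_coords(res_a))
  pb <- .ring_plane(.ring_coords(res_b))
  nb <- if (sum(pa$normal * pb$normal) < 0) -pb$normal else pb$normal
  nm <- pa$normal + nb
  nm <- nm / sqrt(sum(nm^2))
  abs(sum((pb$centroid - pa$centroid) * nm))
}

#' Side-chain ladder spacing along the fibril axis
#'
#' In parallel sheets every strand repeats by the fibril-axis translation,
#' so identical side chains stack into ladders spaced by the cross-beta
#' rise. The spacing is the fibril-axis translation between adjacent
#' equivalent residues; antiparallel sheets report the two-strand repeat
#' distance with `two_strand_repeat = TRUE`.
#'
#' @param sheet A sheet assembly.
#' @param residue_type 3-letter residue code (e.g. `"TYR"`).
#' @return List of class `ladder_report`: `residue_type`, `spacing`
#'   (Angstrom), `n_rungs_observed`, `two_strand_repeat`.
#' @export
ladder_spacing <- function(sheet, residue_type) {
  step <- sheet$repeat_len
  strands <- sheet$strands
  hit <- vapply(strands, function(st) residue_type %in% st$atoms$resname,
                logical(1))
  if (!any(hit)) stop("ladder_spacing: residue type ", residue_type,
                      " absent from sheet")
  idx <- which(hit)
  idx <- idx[seq(1, length(idx))]
  # adjacent equivalent strands are `step` apart in the stacking order
  pos <- vapply(strands[idx], function(st) {
    a <- st$atoms
    sel <- a$resname == residue_type
    colMeans(atom_xyz(a[sel, , drop = FALSE]))
  }, numeric(3))
  keep <- seq(1, length(idx), by = step)
  pos <- pos[, keep, drop = FALSE]
  if (ncol(pos) < 2) stop("ladder_spacing: need at least two equivalent strands")
  d <- sqrt(colSums((pos[, -1, drop = FALSE] - pos[, -ncol(pos), drop = FALSE])^2))
  structure(
    list(residue_type = residue_type, spacing = mean(d),
         n_rungs_observed = ncol(pos),
         two_strand_repeat = step == 2L),
    class = "ladder_report"
  )
}

#' @export
print.ladder_report <- function(x, ...) {
  cat(sprintf("%s ladder: spacing %.3f A over %d rungs%s\n", x$residue_type,
              x$spacing, x$n_rungs_observed,
              if (x$two_strand_repeat) " (two-strand repeat)" else ""))
  invisible(x)
}

#' End-to-end distances of chain termini across an interface
#'
#' Distances between like (charged) termini of the strands facing each other
#' across a zipper interface: backbone N of residue 1 against its nearest
#' symmetry copies on the other side (N-N), and the terminal carboxyl C
#' analogously (C-C). Larger values relieve the electrostatic repulsion of
#' like-charged chain ends in all-parallel topologies.
#'
#' @param iface A `zipper_interface`.
#' @param n_report Number of smallest distances to keep per pair type.
#' @return List of class `termini_report` with sorted distance vectors
#'   `NN` and `CC` (Angstrom) and the interface label.
#' @export
termini_distances <- function(iface, n_report = 10) {
  term <- function(sheet, which_end) {
    t(vapply(sheet$strands, function(st) {
      a <- st$atoms
      if (which_end == "N") {
        sel <- a$name == "N" & a$resseq == min(a$resseq)
      } else {
        sel <- a$name == "C" & a$resseq == max(a$resseq)
      }
      if (!any(sel)) return(c(NA_real_, NA_real_, NA_real_))
      as.numeric(a[which(sel)[1], c("x", "y", "z")])
    }, numeric(3)))
  }
  dists <- function(which_end) {
    A <- term(iface$sheet_a, which_end)
    B <- term(iface$sheet_b, which_end)
    A <- A[stats::complete.cases(A), , drop = FALSE]
    B <- B[stats::complete.cases(B), , drop = FALSE]
    if (!nrow(A) || !nrow(B)) {
      warning("termini_distances: unresolved ", which_end, " termini")
      return(numeric())
    }
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sort(sqrt(pmax(as.numeric(d2), 0)))[seq_len(min(n_report, length(d2)))]
  }
  structure(
    list(interface_label = iface$label, NN = dists("N"), CC = dists("C")),
    class = "termini_report"
  )
}

#' @export
print.termini_report <- function(x, ...) {
  cat(sprintf("termini distances across %s: min N-N %.2f A, min C-C %.2f A\n",
              if (is.na(x$interface_label)) "interface" else x$interface_label,
              if (length(x$NN)) min(x$NN) else NA, if (length(x$CC)) min(x$CC) else NA))
  invisible(x)
}

#' Extract one residue's atoms
#'
#' @param x A `crystal_structure`, strand instance, or atom data.frame.
#' @param resseq Residue number.
#' @param chain Optional chain id.
#' @return Atom data.frame of that residue.
#' @export
residue_atoms <- function(x, resseq, chain = NULL) {
  atoms <- if (inherits(x, "crystal_structure")) x$atoms
           else if (inherits(x, "strand_instance")) x$atoms
           else x
  sel <- atoms$resseq == resseq
  if (!is.null(chain)) sel <- sel & atoms$chain == chain
  atoms[sel, , drop = FALSE]
}
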