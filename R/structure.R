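#' Crystal structure container
#'
#' The canonical in-memory model consumed by every pipeline stage: an atom
#' table, a [unit_cell()], the space-group symbol and its symmetry operators.
#'
#' @param atoms A data.frame with columns `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resseq`, `x`, `y`, `z`, `occ`, `b`, `element`.
#'   Coordinates are Cartesian Angstrom; residue numbering is 1-based as
#'   deposited.
#' @param cell A [unit_cell()].
#' @param space_group Hermann-Mauguin symbol (see [space_group_ops()]).
#' @param sym_ops Optional list of [sym_op()]; derived from `space_group`
#'   when omitted. Explicit operators, when given (e.g. read from a file),
#'   take precedence over the symbol table.
#' @param source_id Identifier string (e.g. a PDB code or file name).
#'
#' @return An object of class `crystal_structure`.
#' @export
crystal_structure <- function(atoms, cell, space_group = "P 1",
                              sym_ops = NULL, source_id = "unknown") {
  req <- c("serial", "name", "altloc", "resname", "chain", "resseq",
           "x", "y", "z", "occ", "b", "element")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("crystal_structure: atom table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("crystal_structure: empty atom table")
  if (any(!nzchar(atoms$element))) stop("crystal_structure: atoms with empty element")
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("crystal_structure: occupancy outside [0,1]")
  if (is.null(sym_ops)) sym_ops <- space_group_ops(space_group)
  if (!.has_identity_op(sym_ops)) stop("crystal_structure: sym_ops lack the identity")
  # residues of each chain must be ordered
  for (ch in unique(atoms$chain)) {
    rs <- atoms$resseq[atoms$chain == ch]
    if (is.unsorted(rs)) stop("crystal_structure: residues of chain ", ch,
                              " not ordered by resseq")
  }
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, cell = cell, space_group = space_group,
         sym_ops = sym_ops, source_id = source_id),
    class = "crystal_structure"
  )
}

.has_identity_op <- function(ops) {
  any(vapply(ops, function(op) {
    max(abs(op$R - diag(3))) < 1e-9 && max(abs(op$t %% 1)) < 1e-9
  }, logical(1)))
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal_structure '%s': %d atoms, %d chain(s), space group %s\n",
              x$source_id, nrow(x$atoms), length(unique(x$atoms$chain)),
              x$space_group))
  print(x$cell)
  invisible(x)
}

# coordinate matrix helper
atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

set_atom_xyz <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# The 20 standard residues (3-letter) recognised as peptide.
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Peptide atoms of a structure
#'
#' Subset an atom table (or a `crystal_structure`) to standard amino-acid
#' residues, dropping waters, ions and co-solvent molecules.
#'
#' @param x A `crystal_structure` or atom data.frame.
#' @return Atom data.frame restricted to the 20 standard residues.
#' @export
peptide_atoms <- function(x) {
  atoms <- if (inherits(x, "crystal_structure")) x$atoms else x
  atoms[atoms$resname %in% .aa3, , drop = FALSE]
}
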