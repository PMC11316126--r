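# Lattice expansion, beta-sheet detection and steric-zipper interface
# enumeration.

#' Detect the fibril axis of an amyloid-like crystal
#'
#' Amyloid-like peptide crystals stack beta-strands along one short cell axis
#' whose length equals the cross-beta rise of about 4.8 Angstrom. The axis is
#' identified as the unique cell edge in the window 4.3-5.3 Angstrom. If no
#' edge falls in that window, a doubled window (8.6-10.6 Angstrom) is tried,
#' corresponding to lattices whose translational repeat along the fibril axis
#' is a two-strand antiparallel unit; such an axis is reported with
#' `repeat_len = 2`.
#'
#' @param s A [crystal_structure()].
#' @param override Optional axis name (`"a"`, `"b"` or `"c"`) forcing the
#'   choice instead of erroring on ambiguity.
#' @return List with `axis` (name), `vector` (Cartesian unit 3-vector),
#'   `length` (Angstrom) and `repeat_len` (1 or 2).
#' @export
detect_fibril_axis <- function(s, override = NULL) {
  cell <- s$cell
  lens <- c(a = cell$a, b = cell$b, c = cell$c)
  pick <- function(name, rep_len) {
    v <- cell$orth[, match(name, c("a", "b", "c"))]
    list(axis = name, vector = v / sqrt(sum(v^2)),
         length = unname(lens[name]), repeat_len = rep_len)
  }
  if (!is.null(override)) {
    stopifnot(override %in% c("a", "b", "c"))
    rl <- if (lens[override] > 8) 2L else 1L
    return(pick(override, rl))
  }
  cand <- names(lens)[lens >= 4.3 & lens <= 5.3]
  if (length(cand) == 1) return(pick(cand, 1L))
  if (length(cand) == 0) {
    cand2 <- names(lens)[lens >= 8.6 & lens <= 10.6]
    if (length(cand2) == 1) return(pick(cand2, 2L))
  }
  stop("ambiguous-fibril-axis: zero or multiple candidate cell axes in the ",
       "4.3-5.3 Angstrom window (override with the axis name to force one)")
}

#' Expand the asymmetric unit into a lattice neighbourhood
#'
#' Generates all symmetry- and lattice-translated copies of each peptide
#' chain whose centroid lies within `radius` of the asymmetric unit's
#' centroid. Each copy is tagged with the generating operator index and
#' integer lattice shift; every copy is a rigid transform of its source
#' chain.
#'
#' @param s A [crystal_structure()].
#' @param radius Neighbourhood radius in Angstrom (default 30).
#' @return List of strand instances. Each is a list with `source_chain`,
#'   `op_index` (1-based index into `s$sym_ops`), `lattice_shift` (integer
#'   3-vector), `atoms` (transformed peptide atom table) and `direction`
#'   (unit N-to-C vector).
#' @export
expand_lattice <- function(s, radius = 30) {
  stopifnot(radius > 0)
  pep <- peptide_atoms(s)
  if (nrow(pep) == 0) stop("expand_lattice: no peptide atoms")
  cell <- s$cell
  centroid0 <- colMeans(atom_xyz(pep))
  # generous integer shift ranges per axis
  nmax <- pmin(ceiling(radius / c(cell$a, cell$b, cell$c)) + 1L, 12L)
  shifts <- as.matrix(expand.grid(n1 = -nmax[1]:nmax[1],
                                  n2 = -nmax[2]:nmax[2],
                                  n3 = -nmax[3]:nmax[3]))
  chains <- split(pep, pep$chain)
  strands <- list()
  for (ch_name in names(chains)) {
    ch <- chains[[ch_name]]
    xf <- cart_to_frac(atom_xyz(ch), cell)
    for (k in seq_along(s$sym_ops)) {
      base <- apply_sym_op(s$sym_ops[[k]], xf)
      base_centroid <- colMeans(base)
      for (si in seq_len(nrow(shifts))) {
        sh <- shifts[si, ]
        cart_centroid <- frac_to_cart(base_centroid + sh, cell)
        if (sqrt(sum((cart_centroid - centroid0)^2)) > radius) next
        xyz <- frac_to_cart(sweep(base, 2, sh, "+"), cell)
        strands[[length(strands) + 1]] <- .make_strand(
          set_atom_xyz(ch, xyz), ch_name, k, unname(sh)
        )
      }
    }
  }
  if (!length(strands)) warning("expand_lattice: radius yields no copies")
  strands
}

.make_strand <- function(atoms, source_chain, op_index, lattice_shift) {
  nterm <- atoms[atoms$name == "N", , drop = FALSE]
  cterm <- atoms[atoms$name == "C", , drop = FALSE]
  if (!nrow(nterm) || !nrow(cterm)) stop("strand lacks backbone N/C atoms")
  p1 <- as.numeric(nterm[which.min(nterm$resseq), c("x", "y", "z")])
  p2 <- as.numeric(cterm[which.max(cterm$resseq), c("x", "y", "z")])
  d <- p2 - p1
  xyz <- atom_xyz(atoms)
  structure(
    list(source_chain = source_chain, op_index = op_index,
         lattice_shift = as.integer(lattice_shift), atoms = atoms,
         xyz = xyz, centroid = colMeans(xyz),
         direction = d / sqrt(sum(d^2))),
    class = "strand_instance"
  )
}

strand_centroid <- function(st) {
  if (!is.null(st$centroid)) st$centroid else colMeans(atom_xyz(st$atoms))
}

strand_xyz <- function(st) {
  if (!is.null(st$xyz)) st$xyz else atom_xyz(st$atoms)
}

sheet_xyz <- function(sheet, idx = seq_along(sheet$strands)) {
  do.call(rbind, lapply(sheet$strands[idx], strand_xyz))
}

# squared cross-distance matrix between two coordinate sets
.cross_dist2 <- function(A, B) {
  outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
}

strand_id <- function(st) {
  paste0(st$source_chain, "/", st$op_index, "/",
         paste(st$lattice_shift, collapse = ","))
}

#' Group strands into beta-sheets
#'
#' Strands are grouped into sheets by backbone hydrogen-bond adjacency:
#' two strands are sheet neighbours when some backbone amide N of one lies
#' within `hbond_cutoff` of a backbone carbonyl O of the other. Connected
#' components with at least three strands are returned as sheet assemblies,
#' strands ordered by their projection on the fibril axis.
#'
#' @param strands List of strand instances from [expand_lattice()].
#' @param axis Fibril axis (list from [detect_fibril_axis()] or unit vector).
#' @param hbond_cutoff N...O adjacency cutoff in Angstrom (default 3.5).
#' @return List of sheet assemblies: each has `strands` (ordered), `fibril_axis`,
#'   `sense` (`"parallel"`/`"antiparallel"`) and `repeat_len` (1 or 2).
#' @export
build_sheets <- function(strands, axis, hbond_cutoff = 3.5) {
  if (is.list(axis) && !is.null(axis$vector)) axis <- axis$vector
  n <- length(strands)
  if (n == 0) stop("no-cross-beta: no strands supplied")
  cent <- t(vapply(strands, strand_centroid, numeric(3)))
  # adjacency by backbone H-bond criterion (with centroid prefilter)
  adj <- vector("list", n)
  NO <- lapply(strands, function(st) {
    x <- strand_xyz(st)
    list(N = x[st$atoms$name == "N", , drop = FALSE],
         O = x[st$atoms$name == "O", , drop = FALSE])
  })
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sum((cent[i, ] - cent[j, ])^2) > 49) next
      if (.min_cross_dist(NO[[i]]$N, NO[[j]]$O) <= hbond_cutoff ||
          .min_cross_dist(NO[[j]]$N, NO[[i]]$O) <= hbond_cutoff) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  comp <- .components(adj, n)
  sheets <- list()
  for (members in comp) {
    if (length(members) < 3) next
    proj <- cent[members, , drop = FALSE] %*% axis
    ord <- members[order(proj)]
    dirs <- t(vapply(strands[ord], function(s) s$direction, numeric(3)))
    dots <- dirs[-nrow(dirs), , drop = FALSE] * dirs[-1, , drop = FALSE]
    adjacent_dots <- rowSums(dots)
    sense <- if (all(adjacent_dots > 0.9)) "parallel"
             else if (all(adjacent_dots < -0.9)) "antiparallel"
             else "mixed"
    if (sense == "mixed") next
    sheets[[length(sheets) + 1]] <- structure(
      list(strands = strands[ord], fibril_axis = axis, sense = sense,
           repeat_len = if (sense == "parallel") 1L else 2L),
      class = "sheet_assembly"
    )
  }
  if (!length(sheets)) stop("no-cross-beta: no sheet with >= 3 strands found")
  sheets
}

.min_cross_dist <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(Inf)
  sqrt(max(min(.cross_dist2(A, B)), 0))
}

.components <- function(adj, n) {
  seen <- rep(FALSE, n)
  out <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    stack <- i; members <- integer()
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      members <- c(members, v)
      stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
    }
    out[[length(out) + 1]] <- sort(members)
  }
  out
}

sheet_atoms <- function(sheet, idx = seq_along(sheet$strands)) {
  do.call(rbind, lapply(sheet$strands[idx], function(s) s$atoms))
}

#' @export
print.sheet_assembly <- function(x, ...) {
  cat(sprintf("beta-sheet: %d strands, %s (repeat %d)\n",
              length(x$strands), x$sense, x$repeat_len))
  invisible(x)
}

#' Enumerate steric-zipper interfaces between sheets
#'
#' Finds every distinct pair of sheets in contact (at least `min_contacts`
#' heavy-atom pairs within `cutoff`), deduplicates symmetry-equivalent
#' contact patches, and labels the survivors S1, S2, ... by descending
#' buried surface area per strand.
#'
#' @param sheets List of sheet assemblies from [build_sheets()].
#' @param cutoff Heavy-atom contact distance cutoff in Angstrom (default 5).
#' @param min_contacts Minimum number of contact pairs (default 5).
#' @param config A [zipper_config()]; supplies the SASA settings used for
#'   the buried-area ranking.
#' @param rank_areas Compute buried areas for the S-label ranking (default).
#'   With `FALSE` (classification-only runs) labels follow contact count and
#'   operator order and `buried_area_per_strand` is `NA`.
#' @return List of `zipper_interface` objects (may be empty, with a warning,
#'   when no sheets touch). Each carries the two sheets, the contact pairs,
#'   per-side surface parity (`face`/`back`), buried area per strand and the
#'   S-label.
#' @export
enumerate_interfaces <- function(sheets, cutoff = 5, min_contacts = 5,
                                 config = zipper_config(), rank_areas = TRUE) {
  if (length(sheets) < 2) {
    warning("enumerate_interfaces: fewer than two sheets")
    return(list())
  }
  cand <- list()
  for (i in seq_len(length(sheets) - 1)) {
    for (j in (i + 1):length(sheets)) {
      cp <- .contact_pairs(sheets[[i]], sheets[[j]], cutoff)
      if (is.null(cp) || nrow(cp) < min_contacts) next
      iface <- structure(
        list(sheet_a = sheets[[i]], sheet_b = sheets[[j]],
             contact_pairs = cp, label = NA_character_),
        class = "zipper_interface"
      )
      iface$face_a <- .side_face(iface, "a")
      iface$face_b <- .side_face(iface, "b")
      cand[[length(cand) + 1]] <- iface
    }
  }
  if (!length(cand)) {
    warning("enumerate_interfaces: no sheet-sheet contacts within cutoff")
    return(list())
  }
  keys <- vapply(cand, .interface_key, character(1))
  keep <- !duplicated(keys)
  # among symmetry-equivalent patches the first (operator-ordered) survives
  uniq <- cand[keep]
  areas <- if (rank_areas) {
    vapply(uniq, function(ifc) buried_area_per_strand(ifc, config), numeric(1))
  } else {
    vapply(uniq, function(ifc) as.numeric(nrow(ifc$contact_pairs)), numeric(1))
  }
  opmin <- vapply(uniq, function(ifc) {
    min(vapply(c(ifc$sheet_a$strands, ifc$sheet_b$strands),
               function(s) s$op_index, numeric(1)))
  }, numeric(1))
  ord <- order(-areas, opmin)
  uniq <- uniq[ord]
  for (k in seq_along(uniq)) {
    uniq[[k]]$label <- paste0("S", k)
    uniq[[k]]$buried_area_per_strand <-
      if (rank_areas) areas[ord][k] else NA_real_
  }
  uniq
}

.contact_pairs <- function(sa, sb, cutoff) {
  A <- sheet_atoms(sa); B <- sheet_atoms(sb)
  Ax <- sheet_xyz(sa); Bx <- sheet_xyz(sb)
  # cheap bounding prefilter before the full distance matrix
  if (any(apply(Ax, 2, min) > apply(Bx, 2, max) + cutoff) ||
      any(apply(Bx, 2, min) > apply(Ax, 2, max) + cutoff)) {
    return(NULL)
  }
  d2 <- .cross_dist2(Ax, Bx)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  ia <- hit[, 1]; ib <- hit[, 2]
  # map atom row back to its strand
  na <- vapply(sa$strands, function(s) nrow(s$atoms), integer(1))
  nb <- vapply(sb$strands, function(s) nrow(s$atoms), integer(1))
  data.frame(
    strand_a = findInterval(ia - 1L, cumsum(c(0L, na)), rightmost.closed = FALSE),
    strand_b = findInterval(ib - 1L, cumsum(c(0L, nb)), rightmost.closed = FALSE),
    name_a = A$name[ia], resname_a = A$resname[ia], resseq_a = A$resseq[ia],
    name_b = B$name[ib], resname_b = B$resname[ib], resseq_b = B$resseq[ib],
    xa = Ax[ia, 1], ya = Ax[ia, 2], za = Ax[ia, 3],
    xb = Bx[ib, 1], yb = Bx[ib, 2], zb = Bx[ib, 3],
    dist = sqrt(pmax(d2[hit], 0)),
    stringsAsFactors = FALSE
  )
}

# Symmetry-equivalence key of an interface: sheet sense, unordered
# face-parity pair and the unordered residue-level contact-pair multiset.
.interface_key <- function(iface) {
  cp <- iface$contact_pairs
  pairs <- unique(apply(cbind(
    paste0(cp$resname_a, cp$resseq_a),
    paste0(cp$resname_b, cp$resseq_b)
  ), 1, function(r) paste(sort(r), collapse = ":")))
  paste(iface$sheet_a$sense,
        paste(sort(c(iface$face_a, iface$face_b)), collapse = "|"),
        paste(sort(pairs), collapse = ";"),
        sep = "||")
}

#' Interface contact residues
#'
#' Residues contributing side-chain contacts on each side of an interface.
#'
#' @param iface A `zipper_interface`.
#' @return List with character vectors `side_a` and `side_b` (e.g. `"LEU1"`).
#' @export
interface_residues <- function(iface) {
  cp <- iface$contact_pairs
  sc <- !(cp$name_a %in% .backbone_names) | !(cp$name_b %in% .backbone_names)
  cps <- cp[sc, , drop = FALSE]
  if (!nrow(cps)) cps <- cp
  list(
    side_a = sort(unique(paste0(cps$resname_a, cps$resseq_a)[
      !(cps$name_a %in% .backbone_names)])),
    side_b = sort(unique(paste0(cps$resname_b, cps$resseq_b)[
      !(cps$name_b %in% .backbone_names)]))
  )
}

.backbone_names <- c("N", "CA", "C", "O", "OXT")

#' @export
print.zipper_interface <- function(x, ...) {
  res <- interface_residues(x)
  cat(sprintf("zipper interface %s: %s sheets, %s/%s, %d contacts\n",
              if (is.na(x$label)) "(unlabelled)" else x$label,
              x$sheet_a$sense, x$face_a, x$face_b, nrow(x$contact_pairs)))
  cat("  side a:", paste(res$side_a, collapse = " "), "\n")
  cat("  side b:", paste(res$side_b, collapse = " "), "\n")
  invisible(x)
}

#' Build the double layer of an interface
#'
#' Extracts the 2 x 3 (parallel) or 2 x 6 (antiparallel) double-layer system
#' used for the formation-energy estimates: `n` consecutive strands from each
#' sheet centred on the contact patch, with the translational-repeat strands
#' at the stack centre marked as central.
#'
#' @param iface A `zipper_interface`.
#' @param n_per_sheet Strands per sheet; defaults to 3 for parallel and 6 for
#'   antiparallel sheets. Must be odd (parallel) or even (antiparallel) so a
#'   central repeat exists.
#' @return A `double_layer`: list with `sheets` (two trimmed sheet
#'   assemblies), `n_per_sheet`, and `central` (per-sheet indices of the
#'   central repeat strands).
#' @export
build_double_layer <- function(iface, n_per_sheet = NULL) {
  sa <- iface$sheet_a; sb <- iface$sheet_b
  if (!identical(sa$sense, sb$sense)) {
    stop("inconsistent-sense: the two sheets of the interface differ in sense")
  }
  sense <- sa$sense
  if (is.null(n_per_sheet)) n_per_sheet <- if (sense == "parallel") 3L else 6L
  if (sense == "parallel" && n_per_sheet %% 2 == 0) {
    stop("build_double_layer: parallel stacks need an odd strand count")
  }
  if (sense == "antiparallel" && n_per_sheet %% 2 == 1) {
    stop("build_double_layer: antiparallel stacks need an even strand count")
  }
  cp_centroid <- .contact_centroid(iface)
  trim <- function(sheet) {
    ns <- length(sheet$strands)
    if (ns < n_per_sheet) {
      stop("build_double_layer: sheet has only ", ns, " strands, need ",
           n_per_sheet)
    }
    proj <- vapply(sheet$strands, function(s) {
      sum(strand_centroid(s) * sheet$fibril_axis)
    }, numeric(1))
    target <- sum(cp_centroid * sheet$fibril_axis)
    mid <- which.min(abs(proj - target))
    lo <- mid - (n_per_sheet - 1L) %/% 2L
    lo <- max(1L, min(lo, ns - n_per_sheet + 1L))
    # keep the two-strand repeat phase for antiparallel sheets
    if (sheet$repeat_len == 2L && lo %% 2L == 0L) lo <- max(1L, lo - 1L)
    idx <- lo:(lo + n_per_sheet - 1L)
    out <- sheet
    out$strands <- sheet$strands[idx]
    out
  }
  ta <- trim(sa); tb <- trim(sb)
  central <- function(sheet) {
    n <- length(sheet$strands)
    if (sheet$repeat_len == 1L) (n + 1L) %/% 2L else c(n %/% 2L, n %/% 2L + 1L)
  }
  structure(
    list(sheets = list(ta, tb), n_per_sheet = n_per_sheet,
         central = list(central(ta), central(tb)),
         sense = sense, label = iface$label),
    class = "double_layer"
  )
}

.contact_centroid <- function(iface) {
  cp <- iface$contact_pairs
  colMeans(rbind(as.matrix(cp[, c("xa", "ya", "za")]),
                 as.matrix(cp[, c("xb", "yb", "zb")])))
}

#' @export
print.double_layer <- function(x, ...) {
  cat(sprintf("double layer: 2 x %d strands (%s), %d central strand(s)/sheet\n",
              x$n_per_sheet, x$sense, length(x$central[[1]])))
  invisible(x)
}
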