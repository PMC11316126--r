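# Topology classification of steric-zipper interfaces.
#
# Three binary descriptors determine the class of an interface between two
# cross-beta sheets: the sheet sense (parallel/antiparallel strands within a
# sheet), the surface parity (whether like or unlike side-chain surfaces
# meet: even-numbered residues form the "face", odd-numbered the "back"),
# and the relative sheet direction (whether the facing strands of the two
# sheets run the same way). The descriptor-to-class table ships as a
# versioned plain-text resource.

.class_table_env <- new.env(parent = emptyenv())

#' The descriptor-to-class lookup table
#'
#' Loads (and caches) the versioned table mapping interface descriptors to
#' the ten topology classes. Classes 9 and 10 have no published operational
#' criterion and are marked untranscribed: they are never emitted by the
#' classifier and are refused by the lattice generator.
#'
#' @param path Optional path to an alternative table resource.
#' @return A data.frame with attribute `lookup_version`.
#' @export
zipper_class_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.class_table_env$table)) return(.class_table_env$table)
    path <- system.file("extdata", "zipper_classes.tsv",
                        package = "stericzipper", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  lines <- readLines(path, warn = FALSE)
  vline <- grep("lookup_version:", lines, value = TRUE)
  version <- if (length(vline)) trimws(sub(".*lookup_version:", "", vline[1])) else "unversioned"
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  need <- c("sheet_sense", "surface_parity", "sheet_direction",
            "extra_symmetry_flag", "class_id")
  if (!all(need %in% names(tab))) {
    stop("zipper_class_table: malformed table resource ", path)
  }
  attr(tab, "lookup_version") <- version
  if (cache) .class_table_env$table <- tab
  tab
}

#' Surface parity of a strand at an interface
#'
#' Decides which side-chain surface of a strand is presented to the partner
#' sheet: `"face"` when the majority of its interface-contacting side-chain
#' atoms belong to even-numbered residues, `"back"` otherwise. Ties (and
#' strands with no side-chain contacts) fall back to a C-beta projection
#' test: the parity whose CA-to-CB vectors point toward the partner sheet.
#'
#' @param strand A strand instance participating in `iface`.
#' @param iface A `zipper_interface`.
#' @return `"face"` or `"back"`.
#' @export
assign_faces <- function(strand, iface) {
  side <- .locate_strand_side(strand, iface)
  cp <- iface$contact_pairs
  idx <- cp[[paste0("strand_", side)]] ==
    .strand_index_in_sheet(strand, iface[[paste0("sheet_", side)]])
  .face_from_contacts(cp[idx, , drop = FALSE], side,
                      list(strand), iface, restrict_strand = TRUE)
}

.locate_strand_side <- function(strand, iface) {
  id <- strand_id(strand)
  in_a <- any(vapply(iface$sheet_a$strands,
                     function(s) identical(strand_id(s), id), logical(1)))
  if (in_a) return("a")
  in_b <- any(vapply(iface$sheet_b$strands,
                     function(s) identical(strand_id(s), id), logical(1)))
  if (in_b) return("b")
  stop("assign_faces: strand does not participate in the interface")
}

.strand_index_in_sheet <- function(strand, sheet) {
  id <- strand_id(strand)
  which(vapply(sheet$strands, function(s) identical(strand_id(s), id),
               logical(1)))[1]
}

# Majority parity of contacting side-chain atoms of one interface side.
.face_from_contacts <- function(cp, side, strands, iface,
                                restrict_strand = FALSE) {
  nm <- cp[[paste0("name_", side)]]
  rs <- cp[[paste0("resseq_", side)]]
  sc <- !(nm %in% .backbone_names)
  n_even <- sum(sc & rs %% 2 == 0)
  n_odd <- sum(sc & rs %% 2 == 1)
  if (n_even > n_odd) return("face")
  if (n_odd > n_even) return("back")
  .cbeta_face_fallback(strands, iface, side)
}

# Which parity's CB vectors point toward the partner sheet?
.cbeta_face_fallback <- function(strands, iface, side) {
  partner <- if (side == "a") iface$sheet_b else iface$sheet_a
  own <- if (side == "a") iface$sheet_a else iface$sheet_b
  target <- colMeans(atom_xyz(sheet_atoms(partner))) -
    colMeans(atom_xyz(sheet_atoms(own)))
  target <- target / sqrt(sum(target^2))
  score <- c(even = 0, odd = 0)
  cnt <- c(even = 0, odd = 0)
  for (st in strands) {
    a <- st$atoms
    for (r in unique(a$resseq)) {
      ca <- a[a$resseq == r & a$name == "CA", c("x", "y", "z")]
      cb <- a[a$resseq == r & a$name == "CB", c("x", "y", "z")]
      if (!nrow(ca) || !nrow(cb)) next
      v <- as.numeric(cb) - as.numeric(ca)
      p <- if (r %% 2 == 0) "even" else "odd"
      score[p] <- score[p] + sum(v * target) / sqrt(sum(v^2))
      cnt[p] <- cnt[p] + 1
    }
  }
  if (all(cnt > 0)) {
    m <- score / cnt
    if (abs(m["even"] - m["odd"]) > 0.1) {
      return(if (m["even"] > m["odd"]) "face" else "back")
    }
  }
  stop("ambiguous-face: no side-chain contacts and C-beta projection is ambiguous")
}

.side_face <- function(iface, side) {
  sheet <- iface[[paste0("sheet_", side)]]
  .face_from_contacts(iface$contact_pairs, side, sheet$strands, iface)
}

#' Interface descriptors
#'
#' Computes the three binary descriptors of a zipper interface: sheet sense,
#' surface parity (`same` when like surfaces meet, i.e. face-to-face or
#' back-to-back; `opposite` for face-to-back) and relative sheet direction
#' (`same` = N-to-N / up-up; `opposite` = N-to-C / up-down). For parallel
#' sheets the direction compares the common strand direction of the two
#' sheets; for antiparallel sheets it compares the nearest facing strand
#' pair across the interface. Descriptors are invariant under swapping the
#' two sheets.
#'
#' @param iface A `zipper_interface`.
#' @return List with `sheet_sense`, `surface_parity`, `sheet_direction`.
#' @export
compute_descriptors <- function(iface) {
  sa <- iface$sheet_a; sb <- iface$sheet_b
  if (!identical(sa$sense, sb$sense)) {
    stop("inconsistent-sense: sheets of one interface differ in sense")
  }
  sense <- sa$sense
  parity <- if (identical(iface$face_a, iface$face_b)) "same" else "opposite"
  if (sense == "parallel") {
    da <- colMeans(t(vapply(sa$strands, function(s) s$direction, numeric(3))))
    db <- colMeans(t(vapply(sb$strands, function(s) s$direction, numeric(3))))
    dt <- sum(da * db) / sqrt(sum(da^2) * sum(db^2))
  } else {
    pair <- .facing_strand_pair(iface)
    dt <- sum(pair[[1]]$direction * pair[[2]]$direction)
  }
  direction <- if (dt > 0.3) "same" else if (dt < -0.3) "opposite" else {
    stop("oblique-interface: facing strand directions nearly orthogonal (dot = ",
         sprintf("%.2f", dt), ")")
  }
  list(sheet_sense = sense, surface_parity = parity, sheet_direction = direction)
}

# Nearest facing contacting strands across an antiparallel interface,
# measured along the fibril axis.
.facing_strand_pair <- function(iface) {
  cp <- iface$contact_pairs
  axis <- iface$sheet_a$fibril_axis
  tab_a <- table(cp$strand_a)
  ia <- as.integer(names(tab_a))[which.max(tab_a)]
  sa <- iface$sheet_a$strands[[ia]]
  pa <- sum(strand_centroid(sa) * axis)
  cand_b <- unique(cp$strand_b)
  pb <- vapply(cand_b, function(k) {
    sum(strand_centroid(iface$sheet_b$strands[[k]]) * axis)
  }, numeric(1))
  sb <- iface$sheet_b$strands[[cand_b[which.min(abs(pb - pa))]]]
  list(sa, sb)
}

#' Classify one interface
#'
#' Deterministic lookup of the topology class from the three descriptors.
#' Descriptor combinations absent from the table yield
#' `class_id = "unclassified"` with the descriptors attached.
#'
#' @param d Descriptor list from [compute_descriptors()].
#' @param table Lookup table from [zipper_class_table()].
#' @return A `zipper_class`: list with `class_id` (integer or
#'   `"unclassified"`), `basis` (the descriptors) and `lookup_version`.
#' @export
classify_interface <- function(d, table = zipper_class_table()) {
  hit <- table$sheet_sense == d$sheet_sense &
    table$surface_parity == d$surface_parity &
    table$sheet_direction == d$sheet_direction &
    table$extra_symmetry_flag == "none"
  hit[is.na(hit)] <- FALSE
  class_id <- if (any(hit)) table$class_id[which(hit)[1]] else "unclassified"
  structure(
    list(class_id = class_id, basis = d,
         lookup_version = attr(table, "lookup_version")),
    class = "zipper_class"
  )
}

#' @export
print.zipper_class <- function(x, ...) {
  cat(sprintf("topology class %s (%s, parity %s, direction %s; lookup %s)\n",
              x$class_id, x$basis$sheet_sense, x$basis$surface_parity,
              x$basis$sheet_direction, x$lookup_version))
  invisible(x)
}

#' Overall crystal topology
#'
#' The crystal's topology is the class of its dominant (largest buried
#' area per strand) interface; the full per-interface map is retained.
#'
#' @param classes Named list (S-label -> `zipper_class`).
#' @param areas Named numeric vector (S-label -> buried area per strand).
#' @return A `crystal_topology`: list with `per_interface` and `overall`.
#' @export
overall_topology <- function(classes, areas) {
  if (!length(classes)) stop("overall_topology: empty interface map")
  if (!setequal(names(classes), names(areas))) {
    stop("overall_topology: class and area maps must share keys")
  }
  dominant <- names(areas)[which.max(areas[names(classes)])]
  structure(
    list(per_interface = classes, overall = classes[[dominant]],
         dominant_label = dominant, areas = areas),
    class = "crystal_topology"
  )
}

#' @export
print.crystal_topology <- function(x, ...) {
  cat(sprintf("overall topology: class %s (dominant interface %s)\n",
              x$overall$class_id, x$dominant_label))
  for (lb in names(x$per_interface)) {
    cat(sprintf("  %s: class %s (buried %.1f A^2/strand)\n", lb,
                x$per_interface[[lb]]$class_id, x$areas[[lb]]))
  }
  invisible(x)
}
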