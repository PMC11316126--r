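# Formation energetics of zipper double layers from atomic-solvation-
# parameter weighted changes in solvent-accessible surface area.

#' Atomic solvation parameter set
#'
#' Loads a tabular atomic-solvation-parameter resource: one row per atom
#' class (element plus chemical context) with its solvation parameter in
#' kcal mol^-1 A^-2 and its united-atom radius in Angstrom. The shipped
#' default transcribes the classic Eisenberg-McLachlan parameters with
#' Chothia-style united-atom radii. The sign convention is such that burying
#' apolar (carbon, sulfur) surface is favourable (negative formation energy)
#' and burying charged surface is penalized.
#'
#' @param path Optional path to an alternative parameter file (tab-separated,
#'   columns `atom_class`, `asp_kcal_per_A2`, `radius_A`; `#` comment header
#'   may carry `source:` and `probe_radius:` entries).
#' @return An object of class `solvation_params`: list with `entries`
#'   (data.frame), `probe_radius` and `source`.
#' @export
solvation_params <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.class_table_env$params)) return(.class_table_env$params)
    path <- system.file("extdata", "solvation_params.tsv",
                        package = "stericzipper", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  src <- hdr[grepl("source:", hdr)]
  src <- if (length(src)) trimws(sub("^#\\s*source:\\s*", "", src[1])) else basename(path)
  pr <- hdr[grepl("probe_radius:", hdr)]
  pr <- if (length(pr)) as.numeric(sub(".*probe_radius:", "", pr[1])) else 1.4
  if (!is.finite(pr) || pr <= 0) stop("solvation_params: invalid probe radius")
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  need <- c("atom_class", "asp_kcal_per_A2", "radius_A")
  if (!all(need %in% names(tab))) stop("solvation_params: malformed file ", path)
  out <- structure(list(entries = tab, probe_radius = pr, source = src),
                   class = "solvation_params")
  if (cache) .class_table_env$params <- out
  out
}

#' @export
print.solvation_params <- function(x, ...) {
  cat("atomic solvation parameters (", x$source, ")\n", sep = "")
  print(x$entries, row.names = FALSE)
  invisible(x)
}

# Aromatic ring carbons per residue type.
.aromatic_carbons <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# Side-chain carbonyl / carboxyl / guanidinium carbons.
.sp2_side_carbons <- list(
  ASN = "CG", GLN = "CD", ASP = "CG", GLU = "CD", ARG = "CZ"
)

#' Atom-class assignment
#'
#' Maps every atom to exactly one solvation atom class. Chain termini are
#' treated as charged (the crystallized peptides are zwitterions): the
#' backbone N of each chain's first residue and the carboxylate oxygens of
#' its last residue, as well as Asp/Glu carboxylates and Lys/Arg side-chain
#' nitrogens. Elements without a specific context rule fall back to their
#' element class; atoms whose element has no entry at all raise a
#' parameterization error naming them.
#'
#' @param atoms Atom data.frame.
#' @param params A [solvation_params()].
#' @return Character vector of atom classes (one per atom).
#' @export
atom_classes <- function(atoms, params = solvation_params()) {
  n <- nrow(atoms)
  cls <- rep(NA_character_, n)
  first_res <- stats::ave(atoms$resseq, atoms$chain, FUN = min)
  last_res <- stats::ave(atoms$resseq, atoms$chain, FUN = max)
  for (i in seq_len(n)) {
    el <- atoms$element[i]; nm <- atoms$name[i]; rn <- atoms$resname[i]
    cls[i] <- switch(el,
      C = {
        if (nm == "C" || identical(nm, .sp2_side_carbons[[rn]])) "C_carbonyl"
        else if (!is.null(.aromatic_carbons[[rn]]) &&
                 nm %in% .aromatic_carbons[[rn]]) "C_aromatic"
        else "C_aliphatic"
      },
      N = {
        if ((nm == "N" && atoms$resseq[i] == first_res[i]) ||
            (rn == "LYS" && nm == "NZ") ||
            (rn == "ARG" && nm %in% c("NE", "NH1", "NH2"))) "N_charged"
        else "N_polar"
      },
      O = {
        if ((nm %in% c("O", "OXT") && atoms$resseq[i] == last_res[i]) ||
            (rn == "ASP" && nm %in% c("OD1", "OD2")) ||
            (rn == "GLU" && nm %in% c("OE1", "OE2"))) "O_charged"
        else "O_polar"
      },
      S = "S",
      NA_character_
    )
  }
  bad <- is.na(cls)
  if (any(bad)) {
    stop("parameterization error: no atom class for atoms: ",
         paste(unique(paste0(atoms$resname[bad], "/", atoms$name[bad])),
               collapse = ", "))
  }
  known <- cls %in% params$entries$atom_class
  if (!all(known)) {
    stop("parameterization error: classes missing from parameter set: ",
         paste(unique(cls[!known]), collapse = ", "))
  }
  cls
}

#' @rdname atom_classes
#' @export
atom_radii <- function(atoms, params = solvation_params()) {
  cls <- atom_classes(atoms, params)
  params$entries$radius_A[match(cls, params$entries$atom_class)]
}

atom_asp <- function(atoms, params) {
  cls <- atom_classes(atoms, params)
  params$entries$asp_kcal_per_A2[match(cls, params$entries$atom_class)]
}

# Rows of the central strands inside the concatenated double-layer table,
# together with the per-system tables used by the energy routines.
.dl_systems <- function(dl) {
  sheets <- dl$sheets
  tab_a <- sheet_atoms(sheets[[1]])
  tab_b <- sheet_atoms(sheets[[2]])
  na <- vapply(sheets[[1]]$strands, function(s) nrow(s$atoms), integer(1))
  nb <- vapply(sheets[[2]]$strands, function(s) nrow(s$atoms), integer(1))
  row_of <- function(sizes, idx) {
    off <- cumsum(c(0L, sizes))
    unlist(lapply(idx, function(k) (off[k] + 1L):off[k + 1L]))
  }
  ca <- row_of(na, dl$central[[1]])
  cb <- row_of(nb, dl$central[[2]])
  list(
    all = rbind(tab_a, tab_b),
    sheet_a = tab_a, sheet_b = tab_b,
    central_all = c(ca, nrow(tab_a) + cb),
    central_a = ca, central_b = cb,
    n_central = length(dl$central[[1]]) + length(dl$central[[2]])
  )
}

#' Formation energy of a double layer from its two sheets
#'
#' Per-atom solvent-accessible areas are computed in the assembled double
#' layer and in each isolated sheet; the per-atom change on assembly,
#' restricted to the central (translational-repeat) strands of both sheets,
#' is weighted by the atomic solvation parameters, summed, and divided by
#' the number of strands summed. Burial of apolar surface gives a negative
#' (favourable) energy.
#'
#' @param dl A [build_double_layer()] result.
#' @param params A [solvation_params()].
#' @param n_points SASA sphere points (default 960).
#' @param divisor `"central"` (default: the central strands actually summed)
#'   or `"total"` (all strands of the system).
#' @param solvent Optional atom table of solvent molecules to include in the
#'   SASA systems (never summed); by default energies are peptide-only.
#' @return Energy in kcal mol^-1 per strand.
#' @export
formation_energy_from_sheets <- function(dl, params = solvation_params(),
                                         n_points = 960,
                                         divisor = c("central", "total"),
                                         solvent = NULL) {
  divisor <- match.arg(divisor)
  sys <- .dl_systems(dl)
  add <- function(tab) if (is.null(solvent)) tab else rbind(tab, solvent)
  asa_all <- compute_sasa(add(sys$all), params, n_points)$per_atom
  asa_a <- compute_sasa(add(sys$sheet_a), params, n_points)$per_atom
  asa_b <- compute_sasa(add(sys$sheet_b), params, n_points)$per_atom
  asp_a <- atom_asp(sys$sheet_a, params)
  asp_b <- atom_asp(sys$sheet_b, params)
  na <- nrow(sys$sheet_a)
  d_a <- (asa_all[sys$central_a] - asa_a[sys$central_a]) * asp_a[sys$central_a]
  d_b <- (asa_all[na + sys$central_b] - asa_b[sys$central_b]) * asp_b[sys$central_b]
  div <- if (divisor == "central") sys$n_central else 2L * dl$n_per_sheet
  sum(d_a, d_b) / div
}

#' Formation energy of a double layer from monomeric strands
#'
#' Same ASA-weighting scheme as [formation_energy_from_sheets()], but the
#' reference state is each central strand isolated in its deposited
#' conformation, so the value also includes the surface buried on sheet
#' formation itself.
#'
#' @inheritParams formation_energy_from_sheets
#' @return Energy in kcal mol^-1 per strand.
#' @export
formation_energy_from_monomers <- function(dl, params = solvation_params(),
                                           n_points = 960,
                                           divisor = c("central", "total"),
                                           solvent = NULL) {
  divisor <- match.arg(divisor)
  sys <- .dl_systems(dl)
  add <- function(tab) if (is.null(solvent)) tab else rbind(tab, solvent)
  asa_all <- compute_sasa(add(sys$all), params, n_points)$per_atom
  strands <- c(dl$sheets[[1]]$strands[dl$central[[1]]],
               dl$sheets[[2]]$strands[dl$central[[2]]])
  asa_mono <- unlist(lapply(strands, function(st) {
    compute_sasa(st$atoms, params, n_points)$per_atom
  }))
  central_tab <- do.call(rbind, lapply(strands, function(st) st$atoms))
  asp <- atom_asp(central_tab, params)
  delta <- asa_all[sys$central_all] - asa_mono
  div <- if (divisor == "central") sys$n_central else 2L * dl$n_per_sheet
  sum(delta * asp) / div
}

#' Both formation energies of one interface
#'
#' Convenience wrapper returning an `energy_result` mirroring one row of the
#' energy report: both per-strand formation energies plus bookkeeping
#' (strands summed, atom count, parameter provenance).
#'
#' @inheritParams formation_energy_from_sheets
#' @return An `energy_result` list.
#' @export
formation_energies <- function(dl, params = solvation_params(),
                               n_points = 960,
                               divisor = c("central", "total"),
                               solvent = NULL) {
  divisor <- match.arg(divisor)
  sys <- .dl_systems(dl)
  structure(
    list(
      interface_label = dl$label,
      e_form_sheets = formation_energy_from_sheets(dl, params, n_points,
                                                   divisor, solvent),
      e_form_monomers = formation_energy_from_monomers(dl, params, n_points,
                                                       divisor, solvent),
      n_strands_summed = sys$n_central,
      atoms_used = nrow(sys$all),
      divisor = divisor,
      params_source = params$source
    ),
    class = "energy_result"
  )
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf(
    "interface %s: E_form %.2f (from sheets), %.2f (from monomers) kcal/mol/strand\n",
    if (is.null(x$interface_label) || is.na(x$interface_label)) "?" else x$interface_label,
    x$e_form_sheets, x$e_form_monomers))
  cat(sprintf("  (%d central strands summed, %d atoms, params: %s)\n",
              x$n_strands_summed, x$atoms_used, x$params_source))
  invisible(x)
}

#' Reference stability medians
#'
#' Literature medians of the sheet-to-double-layer formation energy for
#' stable steric zippers (-1.417 kcal mol^-1 per strand) and for weakly
#' bound kinked LARKS interfaces (-0.443 kcal mol^-1 per strand), used only
#' to annotate reports.
#'
#' @return Named list with `stable_zipper_median` and `larks_median`.
#' @export
stability_thresholds <- function() {
  list(stable_zipper_median = -1.417, larks_median = -0.443)
}

#' Stability annotation of a formation energy
#'
#' Tags an energy by its position between the reference medians: values in
#' the third of the gap nearest each median are tagged `zipper-like` or
#' `LARKS-like`; the middle third is `intermediate`. Values beyond either
#' median take that median's tag. The annotation never alters the numbers.
#'
#' @param e An `energy_result` or a numeric energy (kcal mol^-1 per strand).
#' @param thresholds See [stability_thresholds()].
#' @return Character tag with attribute `distances` (to both medians).
#' @export
annotate_stability <- function(e, thresholds = stability_thresholds()) {
  v <- if (inherits(e, "energy_result")) e$e_form_sheets else as.numeric(e)
  z <- thresholds$stable_zipper_median
  l <- thresholds$larks_median
  third <- (l - z) / 3
  tag <- if (v <= z + third) "zipper-like"
         else if (v >= l - third) "LARKS-like"
         else "intermediate"
  structure(tag, distances = c(to_zipper_median = abs(v - z),
                               to_larks_median = abs(v - l)))
}

#' Buried interface area per strand
#'
#' Surface area buried on double-layer formation, per central strand:
#' computed with the same SASA engine as the energetics (probe 1.4 A),
#' restricted to the central strands of a minimal double layer built across
#' the interface.
#'
#' @param iface A `zipper_interface`.
#' @param config A [zipper_config()].
#' @return Buried area in Angstrom^2 per strand.
#' @export
buried_area_per_strand <- function(iface, config = zipper_config()) {
  dl <- build_double_layer(iface)
  params <- config$params
  sys <- .dl_systems(dl)
  np <- config$sasa_points
  asa_all <- compute_sasa(sys$all, params, np)$per_atom
  asa_a <- compute_sasa(sys$sheet_a, params, np)$per_atom
  asa_b <- compute_sasa(sys$sheet_b, params, np)$per_atom
  na <- nrow(sys$sheet_a)
  buried <- sum(asa_a[sys$central_a] - asa_all[sys$central_a]) +
    sum(asa_b[sys$central_b] - asa_all[na + sys$central_b])
  buried / sys$n_central
}
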