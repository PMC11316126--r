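Package: stericzipper
Title: Topology Classification and Solvation Energetics of Amyloid-Like
    Peptide Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural analysis of amyloid-like crystals of
    short aggregation-prone peptides. Reads peptide crystal structures with
    full unit-cell and space-group metadata (PDB and mmCIF), expands the
    asymmetric unit into cross-beta lattices, groups strands into beta-sheets,
    enumerates steric-zipper interfaces, and assigns each interface to one of
    the ten Eisenberg-style topology classes. Estimates per-strand formation
    energies of double-layer assemblies from solvent-accessible surface-area
    changes weighted by atomic solvation parameters, and quantifies interface
    geometry (aromatic ring pair geometry, side-chain ladder spacings,
    end-to-end distances of charged termini). Includes a generator of
    idealized cross-beta lattices for any topology class and sequence, so the
    whole pipeline is testable without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
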