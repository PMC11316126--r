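---
title: "Topology and energetics of amyloid-like peptide crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology and energetics of amyloid-like peptide crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stericzipper)
```

## The system

Short aggregation-prone peptides (APRs) of 4-10 residues crystallize as
amyloid-like lattices: extended beta-strands stack along one short cell axis
(the fibril axis, rise about 4.8 Angstrom) into beta-sheets, and pairs of
sheets interdigitate their side chains across dry "steric zipper"
interfaces. Because a beta-strand presents two distinct side-chain surfaces
- even-numbered residues on one side (the *face*), odd-numbered on the other
(the *back*) - and because sheets can be parallel or antiparallel and can
run in either relative direction, the possible zipper arrangements fall into
ten symmetry classes. `stericzipper` determines, for any such crystal, which
classes its interfaces belong to, how strongly each interface holds a
hypothetical double layer together, and the geometric descriptors
(aromatic-ring pair geometry, side-chain ladder spacings, end-to-end
distances of the charged termini) that characterize the packing.

## Pipeline

Every analysis runs the same stages, exposed both as individual functions
and through `zipper_analysis()`:

1. **Parse** (`parse_structure()`): PDB or mmCIF with the unit cell and
   space group. Explicit symmetry-operator records (PDB `REMARK 290 SMTRY`,
   mmCIF symop loops) take precedence over the Hermann-Mauguin symbol;
   otherwise the operators come from an internal generator table covering
   P 1, P 2~1~, P 2~1~2~1~2~1~ and C 2 - the groups amyloid-like peptide
   crystals actually use. Any other symbol raises an
   `unsupported-spacegroup` error rather than silently assuming P 1.
   Hydrogens are dropped (the supported crystal models are heavy-atom-only
   and the solvation radii are united-atom); for alternate locations one
   conformer is kept (altloc `A` by default, configurable to another letter
   or to the highest-occupancy conformer).
2. **Fibril axis** (`detect_fibril_axis()`): the unique cell edge in the
   window 4.3-5.3 Angstrom. When no edge qualifies, a doubled window
   (8.6-10.6 Angstrom) is tried and flagged as a two-strand repeat; this
   admits P 1 descriptions of antiparallel lattices, whose true translational
   repeat along the fibril axis is two strands. An override naming the axis
   is available for pathological cells.
3. **Expansion** (`expand_lattice()`): all symmetry/lattice copies of each
   peptide chain whose centroid lies within a radius (default 30 Angstrom,
   enough for six-strand stacks plus both neighbour sheets in hexapeptide
   cells) of the asymmetric unit.
4. **Sheets** (`build_sheets()`): strands are sheet neighbours when a
   backbone amide N of one lies within 3.5 Angstrom of a carbonyl O of the
   other; connected components with at least three strands become sheet
   assemblies, ordered along the axis, with sense (parallel/antiparallel)
   from the strand-direction dot products.
5. **Interfaces** (`enumerate_interfaces()`): sheet pairs with at least 5
   heavy-atom contacts within 5 Angstrom. Symmetry-equivalent patches are
   reported once; equivalence is judged by sheet sense, the unordered
   face-parity pair, and the unordered residue-level contact-pair multiset.
   Surviving interfaces are labelled S1, S2, ... by descending buried
   surface area per strand (computed with the same SASA engine as the
   energetics), ties broken by symmetry-operator order.
6. **Classification** (`compute_descriptors()`, `classify_interface()`):
   three binary descriptors - sheet sense, surface parity, relative sheet
   direction - looked up in a versioned table (see below). The overall
   crystal topology is the class of the largest interface
   (`overall_topology()`).
7. **Energetics and geometry** (below).

## The descriptor-to-class table

The table ships as a plain-text, versioned resource
(`zipper_class_table()`, `lookup_version` 1.0). The anchoring facts are:
classes 1-4 (and the never-observed 9-10) are parallel, 5-8 antiparallel;
class 3 has identical residues facing each other across both of its zipper
interfaces with sheets running the same direction both along and
perpendicular to the fibril axis; class 2 shares the strand direction but
pairs chemically different surfaces; class 4 pairs opposite surfaces of
sheets running opposite directions (realized by a 2-fold about the sheet
normal, as in the orthorhombic P 2~1~2~1~2~1~ form); class 1 is the
remaining face-to-face parallel combination (realized by a 2~1~ screw along
the fibril axis, the classic packing of parallel zipper crystals); and among
the antiparallel classes 7 is up-up and 8 up-down. This fixes:

| class | sense | surface parity | sheet direction |
|---|---|---|---|
| 1 | parallel | same (face-to-face/back-to-back) | opposite |
| 2 | parallel | opposite (face-to-back) | same |
| 3 | parallel | same | same |
| 4 | parallel | opposite | opposite |
| 5 | antiparallel | same | same (up-up) |
| 6 | antiparallel | same | opposite |
| 7 | antiparallel | opposite | same (up-up) |
| 8 | antiparallel | opposite | opposite (up-down) |

Classes 9 and 10 have no published operational criterion (no structure has
ever been observed); they are listed as *untranscribed*: the classifier can
never emit them and the lattice generator refuses to build them rather than
improvise a geometry. Descriptor combinations missing from a (user-supplied)
table yield an explicit `"unclassified"`, never the nearest class.

Two numerical choices guard the descriptors. Direction dot products must
exceed 0.3 in magnitude; anything in the dead zone raises an
`oblique-interface` error instead of a silent call, because the linear
cross-beta regime the classification assumes has broken down. Surface parity
is decided per side by the even/odd majority of interface-contacting
side-chain atoms, with a C-beta projection fall-back on ties (which parity's
CA-to-CB vectors point toward the partner sheet); a still-ambiguous side is
an `ambiguous-face` error.

## Energy model

The formation energy of a double layer follows the atomic-solvation-
parameter protocol: solvent-accessible surface areas are computed per atom
in the assembled 2 x 3 (parallel) or 2 x 6 (antiparallel) double layer and
in the reference state, the per-atom change is multiplied by the atom's
solvation parameter, summed over the *central* (translational-repeat)
strands of both sheets, and divided by the number of strands summed. Two
reference states give the two reported numbers: the two isolated sheets
(`formation_energy_from_sheets()`) and the isolated strands in their
deposited conformation (`formation_energy_from_monomers()`). Restricting
the sum to central strands removes stack edge effects - extending a parallel
stack from 3 to 5 strands per sheet moves the energy by well under
0.05 kcal/mol/strand (this is asserted in the test suite).

Choices a user should know:

* **Parameters.** The shipped set (`solvation_params()`) transcribes the
  Eisenberg-McLachlan atom-class parameters (carbon +16, sulfur +21,
  neutral N/O -6, charged O -24, charged N -50 cal/mol/Angstrom^2) with
  Chothia-style united-atom radii; the provenance string travels into every
  report. The file is a documented, editable two-column resource, so a
  different transcription is one `--params`-style argument away.
* **Sign convention.** Burying apolar surface is favourable (negative);
  burying charged surface is penalized. Stable zipper interfaces land near
  the literature median of -1.417 kcal/mol/strand, weak LARKS-like ones
  near -0.443; `annotate_stability()` tags energies by these medians with
  an explicit intermediate band (the middle third of the gap). The tag
  annotates reports and never alters numbers.
* **Charges.** The peptides are zwitterions: the backbone N of residue 1
  and the C-terminal carboxylate oxygens are classed as charged, as are
  Asp/Glu carboxylates and Lys/Arg side-chain nitrogens.
* **Divisor.** "Divided by the number of strands" is ambiguous between the
  central strands actually summed (2 for parallel, 4 for antiparallel) and
  all strands of the system (6 or 12). The default divides by the central
  strands, since only their atoms enter the sum; the convention is a config
  key (`divisor_convention`) printed in every report, and the alternative
  is a single flag flip (the two differ by an exact factor).
* **Solvent.** Crystallographic solvent (water, ethanol, trifluoroacetate)
  is excluded from the energy systems by default - the method operates on
  the beta-sheet assembly and the parameters are water-optimized - with
  `include_solvent_in_energy = TRUE` to include solvent molecules within
  4.5 Angstrom of the double layer.
* **SASA.** Shrake-Rupley-style numerical areas over a deterministic
  generalized-spiral point set (default 960 points/atom, probe 1.4
  Angstrom). Determinism was chosen over random sampling so that identical
  inputs give byte-identical reports without a seed. At 960 points an
  isolated sphere is within 1% of its analytic area and a packed cluster
  within 2% of a 10^6-sample Monte-Carlo rejection oracle; the discretization
  error falls with the point count (asserted against the closed-form
  two-intersecting-sphere area).

## Geometry descriptors

`aromatic_pair_geometry()` reports the centroid distance and acute
interplanar angle of two aromatic side chains. The centroid and best-fit
plane use the six-membered ring carbons only (for Tyr: CG, CD1, CD2, CE1,
CE2, CZ - the hydroxyl would bias the centroid; for Trp the benzo ring); the
plane normal is the smallest principal direction, and the angle is folded to
[0, 90] degrees because ring normals carry a sign ambiguity.
`interplanar_distance()` projects the centroid separation on the mean ring
normal and is reported alongside the angle so "stacked versus merely near"
calls are auditable. `ladder_spacing()` measures the fibril-axis translation
between adjacent equivalent side chains - exactly the cross-beta rise for
translational parallel sheets, and the (flagged) two-strand repeat for
antiparallel ones. `termini_distances()` lists sorted cross-interface
distances between like (charged) chain ends, the quantity that relieves
electrostatic repulsion in the all-parallel topologies; because the
published comparison is graphical only, the package reports full sorted
lists rather than targeting a printed value.

## The synthetic lattice generator

`build_lattice()` turns a `lattice_spec()` (class, sequence, rise, sheet
spacing, backbone conformation, seed) into an idealized crystal: an
all-heavy-atom strand built from standard bond geometry by
natural-extension-reference-frame placement (default phi/psi of -139/+135
degrees; one fixed, common rotamer per residue type for determinism), a
sheet generated by the pure rise translation (or a two-strand antiparallel
repeat whose register offset is found by a deterministic grid search on the
N...O distances), and a partner sheet placed by the rigid operation that
realizes the class descriptors - rotation about the strand axis, fibril
axis, or sheet normal, or pure translation. Defaults are the study
conditions of the hexapeptide crystals the package targets: one strand per
sheet repeat, 4.8 Angstrom rise, 10 Angstrom sheet spacing. Structures are
emitted as true P 1 crystals with one translational repeat per sheet and a
cell of b = repeat and c = twice the sheet spacing, so the ordinary
expansion path regenerates the full packing, including the two alternating
interface types (odd-odd and even-even) of the face-to-face classes. A
second emission mode, `synthetic_analogue()`, places ideal strands in the
*published* cells and space groups of the deposited LYIQNL/LYIQWL forms, so
the true screw-operator expansion path is exercised end to end; these are
labelled synthetic and reproduce lattice metric, symmetry and topology, not
refined coordinates.

What the generator deliberately does **not** emulate: refined side-chain
rotamer diversity and alternate conformations, bound solvent, missing
(disordered) atoms, kinked LARKS-like backbones, and sub-Angstrom
relaxations of real zippers. Passing round-trip and jitter tests on
generated lattices therefore demonstrates that the measurement chain -
expansion, sheet detection, face parity, direction, lookup - is correct and
robust to 0.2 Angstrom side-chain noise (`perturb_lattice()`, backbone
fixed, seeded and reproducible); it does not by itself demonstrate recovery
of refined experimental coordinates, which is what the deposited-structure
acceptance checks are for when those files are supplied.

## Determinism, problem sizes, degenerate inputs

Every stage is deterministic: the SASA point set is fixed, S-labels order by
buried area with explicit tie-breaks, and reports carry no timestamps or
paths, so identical inputs render byte-identical TSV/JSON. The test suite
runs on hexapeptide lattices (2 x 3 and 2 x 6 double layers, expansion
radius 30 Angstrom, 960-point SASA, 20 jitter seeds per class), sizes at
which the full property suite completes in minutes on one CPU while the
energies are already edge-effect-free. Degenerate inputs fail loudly and
specifically: missing cells (`no-symmetry`), unknown symbols
(`unsupported-spacegroup`), no H-bonded stacks (`no-cross-beta`), mixed
sheet senses at one interface (`inconsistent-sense`), near-orthogonal sheet
directions (`oblique-interface`), unresolvable parities (`ambiguous-face`),
and atoms without a solvation class (a parameterization error naming the
atoms).

## Known limitations

* Space-group coverage is the small set amyloid peptide crystals use;
  exotic groups require explicit operator records in the input file.
* Classes 9 and 10 remain untranscribed by design until an operational
  geometric criterion is published.
* The energy model is a buried-surface estimate: no electrostatics beyond
  the charged-atom classes, no force field, no entropy; its purpose is
  ranking interfaces and comparing polymorphs on the published scale.
* The monomer-referenced energy uses the deposited strand conformation as
  its reference state; a protocol using an idealized extended reference
  would shift that column systematically.
* Heterotypic (two-sequence) zippers and kinked LARKS interfaces are out of
  scope.

## A worked example

```{r example, eval = FALSE}
spec <- lattice_spec(3, "LYIQNL")   # the class realized by monoclinic LYIQNL
lat <- build_lattice(spec)
res <- zipper_analysis(lat)
print(res)
topology_report(res)
energy_report(res)
geometry_report(res)
```
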