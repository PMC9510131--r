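---
title: "dimerforge: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dimerforge: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerforge)
```

`dimerforge` analyses ensembles of predicted structures of multidomain
protein complexes in which domains compete for mutually exclusive
partners. This vignette records the scientific model behind each module,
the tunable parameters with their defaults and units, what the synthetic
generator does and does not emulate, and the places where a design choice
was genuinely open.

## 1. Structures and conventions

All geometry flows through the `structure_model` atom table. Conventions,
applied uniformly:

* **Numbering** is author numbering, 1-based, with inclusive ranges
  (`domain_spec("P450d", "A", 2, 458)` selects 457 residues). Erasures
  (`erase_region`) never renumber survivors — the gap stays visible,
  which the linker-feasibility bookkeeping depends on.
* **Alternate locations** are resolved on read to a single conformer:
  highest occupancy first, alphabetical alt-loc id on ties. Downstream
  geometry assumes one position per atom.
* **Hydrogens** are kept in the table but excluded from all contact,
  clash and SASA computations (heavy-atom convention, matching the
  predictors and the clash criterion). Waters are always excluded from
  those computations; other heteroatoms are excluded by default and
  includable by flag.
* **Multi-model files**: model 1 only.

The PDB and mmCIF readers/writers are minimal by design (ATOM/HETATM
and the `atom_site` loop); PDB coordinate fields quantise at 0.001 Å,
which bounds round-trip error at 5e-4 Å.

## 2. Contact-based binding free energy

The interface score is the published linear contact model: interfacial
contacts (IC) are residue pairs across the two chain groups with any
heavy-atom pair within **5.5 Å** (`cutoff`), classified by residue
character, plus two non-interacting-surface (NIS) composition terms:

$$\Delta G = -0.09459\,IC_{cc} - 0.10007\,IC_{ca} + 0.19577\,IC_{pp}
 - 0.22671\,IC_{pa} + 0.18681\,\%NIS_{apolar} + 0.13810\,\%NIS_{charged}
 - 15.9433$$

in kcal/mol, negative favourable. Conventions and their provenance:

* **Character classes** (one table for both contacts and NIS): charged
  D, E, K, R, H; polar N, Q, S, T, Y; apolar the rest including C, G, P,
  W. The upstream predictor's source could not be consulted offline;
  this table is the one documented deviation risk for absolute ΔG on
  real sequences, and the first thing to recheck against the upstream
  code. None of the package's tests depend on it: the synthetic
  fixtures control their own compositions.
* **SASA** is Shrake–Rupley with probe 1.4 Å and a deterministic
  golden-spiral point lattice (default `n_points = 240`; the test oracle
  runs at 960). Relative SASA divides by the Tien et al. theoretical
  residue maxima; surface residues are those with relative SASA > 5 %
  *computed on the complex*, so residues buried by complexation drop out
  of the NIS without an explicit interface subtraction.
* A consequence of the Tien normalisation worth stating: an *isolated*
  residue exceeds relative SASA 1.0, because the maxima are defined in a
  tripeptide context. The package therefore tests exposure on isolated
  atoms against the analytic sphere area and treats "relative SASA ≈ 1"
  as a statement about residues in chain context.
* **No-complex rule**: $|\Delta G| < 3$ kcal/mol (threshold
  `dg_threshold`, boundary inclusive on the complex side). The magnitude
  reading resolves the sign ambiguity of "binding energy lower than 3":
  with the model's intercept and typical surface compositions, genuinely
  separated chains land near −1 to −2 kcal/mol, so a signed reading
  would classify them identically; the magnitude form also behaves
  correctly for the rare positive predictions.
* `relaxed` is a bookkeeping flag only: side-chain relaxation markedly
  changes contact counts and hence ΔG, but relaxation itself is out of
  scope, so the flag records provenance without altering arithmetic.

## 3. Arbitration

Given one predicted model per run:

1. **Overlap artifacts**: predictors signal "no defined complex" by
   interpenetrating the partners. A member is `artifact_overlap` when
   more than `overlap_fraction = 0.1` of the residues of the two groups
   sit in cross-group steric clash.
2. **No-complex**: remaining members are scored with the ΔG model and
   classified by the 3 kcal/mol rule.
3. **Geometry clustering**: similarity between two complex-status
   members is the fraction of common residue–residue interface contacts
   (fcc). The package uses the Jaccard form $|A \cap B| / |A \cup B|$
   rather than the more common min-denominator form: a geometry whose
   interface strictly extends another's (extra contacts on a shared
   core — exactly the relation between the fixtures' crossed and closed
   geometries, which share the FADd–FADd interface) would be absorbed by
   min-normalisation. Single-linkage components at `fcc >= 0.5` define
   geometries. For homodimers the chain labels are arbitrary, so each
   pair is evaluated under both chain mappings and the better one kept.
4. **Frequencies** divide by *all* runs, not complex-status runs,
   matching the "at least 20 % of runs" significance rule
   (`min_frequency = 0.2`). Singleton clusters are flagged inconsistent
   and are never significant.
5. **Representative**: most negative ΔG, ties to the lowest run id.
   Predictor confidence (pTM) is carried as metadata and never used —
   its ranks are not reliably consistent with computed affinities.

The verdict is `no_complex` (nothing significant), `single_geometry`, or
`alternate_geometries`.

**Topology labels.** Each chain of a two-chain model carries one mobile
domain (FMNd by default) and partner domains; each mobile domain is
assigned the partner with the largest residue-contact count. Both
same-chain: intrachain (`closed` for FAD-class partners, `cis` for
P450-class); both opposite-chain: interchain (`crossed` / `trans`);
mixed or contact-free: `undetermined`.

## 4. Assembly

* **Axis detection** superposes monomer A onto monomer B over
  sequence-matched Cα pairs (Kabsch, proper rotations only). The angle
  comes from an atan2 form (full precision near 180°, where the acos
  form loses half its digits), the direction from the rotation's fixed
  vector (with a symmetrised (R+I) column extraction near 180°), the
  point from the screw-axis pseudo-inverse. Deviations beyond 10° from
  180° warn; near-identity rotations are an error, not an axis.
* **Axis alignment** maps the mobile part's axis onto the reference
  axis with the minimal rotation; a two-fold axis has no preferred sign,
  so the orientation needing the smaller rotation is chosen. Only the
  perpendicular offset is removed, preserving the axial position.
* **Clash criterion**: heavy-atom distance < Bondi vdW sum − 0.4 Å
  (`tolerance`), the common interactive-graphics default; the source
  material says only "structural clashes".
* **Separation** (`step = 0.1` Å) scans the axial barycenter distance
  *inward from a guaranteed clash-free start* (sum of bounding radii
  + 5 Å) and stops at the first clash; this deliberately returns the
  outermost clash-free boundary and cannot be trapped in clash-free
  pockets inside interpenetrating configurations. Barycenters are
  geometric centroids of heavy atoms (the source never specifies
  mass-weighting; geometric is the simpler convention and is stated in
  the docs).
* **Dihedral** (`angular_step = 1°`) evaluates clash feasibility on a
  circular grid for *every* supplied conformational variant (e.g. the
  open and the closed placement of the mobile domains); the feasible set
  is the intersection, the chosen angle the midpoint of the largest
  contiguous arc (180° by convention for a fully feasible circle). An
  empty intersection is an error carrying the per-variant arcs for
  diagnosis. Midpoint-of-arc is this package's tie-break; density-map
  optimisation is out of scope and was reported to give equivalent
  answers within error.
* **Hybrid composition** superposes the open model onto the closed one
  restricted to Cα of the conserved domains and takes one full monomer
  from each — the asymmetric closed/open dimer used to discuss the
  catalytic cycle.

All assembly operations are rigid; tests assert intra-part pairwise
distances to 1e-6 Å through the whole pipeline.

## 5. Grafting and linkers

Cofactors are transferred by superposing the reference protein domain on
the target (Cα pairs matched by author numbering plus an explicit
offset — sequence alignment is deliberately out of scope) and applying
the same rigid transform to the cofactor atoms, which land on a reserved
hetero chain with fresh numbering. Pre-existing atoms are never touched;
a post-graft clash report against the protein is attached.

Linker feasibility is a *length* check only: the gap between the
backbone C of the upstream anchor and the N of the downstream anchor
must not exceed `(n_missing + 1) × per_residue_reach`, with the
trans Cα–Cα step **3.8 Å** as the extended-chain bound (3.5 Å
conservative mode behind the flag). The bound is the package's own
criterion, labelled as such in reports: it asserts that a connection is
geometrically possible, not that any particular loop conformation
exists.

## 6. Sequence retro-engineering

Edits are motif-anchored and verified before anything changes: the
anchor must occur, a stated author position must match an occurrence,
and multiple occurrences without a position are an ambiguity error —
protecting against off-by-one readings of published superscript
numbering. Deletion, insertion-after-a-submotif and substitution all
report `n_removed` / `n_inserted` / `length_delta` with the bookkeeping
invariant `length_delta = n_inserted − n_removed` enforced by tests.
Downstream author numbers are conceptually preserved (renumbering is a
separate explicit step), so edited sequences remain citable against
published positions. Chimeras stitch author-numbered segments that must
tile contiguously; per-residue provenance is returned rather than
trusted.

## 7. The synthetic generator: what it emulates, what it does not

The generator exists to make every geometric and energetic contract
testable with known ground truth; it emulates *predicted-model
pathologies*, not protein physics:

* **Domains** are parametric helices, straight "strand" chains (3.8 Å
  rise, one Cβ pseudo-atom per residue), or Gaussian blobs. Two facing
  strands form a contact ladder whose spacing is exact by construction
  (facing Cβ rows meet at separation − 3.06 Å), so interfaces sit at
  ~4.4–5.2 Å with a ≥1.4 Å clash margin — robust to the 0.3 Å default
  member jitter.
* **The C2 monomer is L-shaped** (two perpendicular helix arms). A
  single straight helix is effectively one-dimensional: rotation about
  its own line is unobservable under coordinate noise, and with it the
  recovered symmetry angle. This is an information-content requirement
  on any test of axis recovery, not a modelling convenience.
* **Composition**: the default 20-residue sequence cycle is 60 %
  apolar / 25 % charged / 15 % polar — a typical protein surface — so
  that two *separated* chains score ΔG ≈ −1.3 kcal/mol (no-complex, as
  for real proteins, whose NIS terms nearly cancel the intercept).
  Charged and polar residues occupy the first half of the cycle so the
  palindromic ladder pairing of facing strands produces
  charged/apolar and polar/apolar contacts, the classes the model
  weights; genuine interfaces then score −3.6 to −17 kcal/mol. These
  choices were made once, from the model's structure, and are not
  tuned.
* **Ensembles** draw geometry labels by largest-remainder rounding of
  the requested proportions (so planted 0.8/0.2 in 10 runs is exactly
  8/2), add per-member isotropic Gaussian jitter (`noise_sigma`,
  default 0.3 Å for ensembles) seeded from the ensemble seed and run
  id, and can plant `none` (chains 100 Å apart) and `overlap`
  (co-centred chains) members to exercise the artifact paths.
* **Not emulated**: real side chains and rotamers, realistic secondary
  structure packing, predictor confidence statistics (pTM is a seeded
  uniform number, metadata only), linker connectivity between domains
  of one chain, and any relationship between the planted noise and real
  predictor error. A green test therefore establishes that the
  *algorithms* recover planted truth under controlled noise — not that
  the energetics are accurate for real proteins (that claim rests on
  the published model being reimplemented faithfully, see §2).

Determinism: every generator takes a seed, uses a private RNG stream and
restores the caller's RNG state; identical specs give bit-identical
coordinates.

## 8. Numerical choices and degenerate inputs

* Superposition excludes reflections (determinant-corrected SVD).
* Axis detection needs ≥ 3 matched Cα pairs; fewer is an error.
* PDB round trips quantise at 1e-3 Å; all geometric identities in tests
  use 1e-6 Å on in-memory objects.
* `min_separation` is monotone in the clash tolerance (stricter never
  smaller), property-tested.
* Contact and clash scans are blocked O(N·M) distance evaluations;
  brute-force O(N²) oracles in the test suite arbitrate them exactly.
* The dihedral grid treats arcs circularly (wrap-around runs merged);
  the fully feasible circle reports the conventional 180° midpoint of
  `[0°, 360°)`.

## 9. Known limitations

* Absolute ΔG on real structures depends on the residue-class table
  discussed in §2 and on unrelaxed coordinates; the two
  crystal-structure reference values can only be checked with network
  access (see `scripts/acceptance.R`).
* No loop modelling: erased linkers are checked for reachability, never
  rebuilt. No flexible refinement, density-map handling, or
  conformational intermediates.
* mmCIF support covers the `atom_site` loop (the coordinate payload),
  not the full dictionary.
* Sequence matching for superposition is by residue numbering with an
  explicit offset; there is no alignment fallback.
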