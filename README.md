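# dimerforge

Arbitration, interface energetics, and rigid-body assembly of predicted
multidomain protein dimer models.

## The problem

Structure predictors (AlphaFold-class tools) run repeatedly on the same
multidomain complex do not always return one answer. For modular enzymes
whose domains can form *mutually exclusive* complexes — the canonical case
being a homodimeric P450–diflavin-reductase fusion (CYP102A1 / P450 BM3),
where each FMN-binding domain must alternately dock onto a FAD domain and
a heme domain during catalysis — repeated runs produce genuinely different
geometries, and their relative frequencies carry information about the
underlying conformational competition. `dimerforge` turns that behaviour
into a measurement pipeline:

* **score** every predicted model's interchain interface with a
  contact-based binding free energy;
* **arbitrate** among alternate conformations: discard non-complexes and
  overlap artifacts, cluster the rest by interface similarity, report
  per-geometry frequencies and the energetically best representative;
* **classify** dimer domain topologies (crossed vs closed FMNd–FADd,
  cis vs trans FMNd–P450d);
* **assemble** full-length C2 homodimer models from partial dimer models
  (detect the two-fold axis, align axes, find the smallest clash-free
  axial separation, choose a dihedral angle compatible with all supplied
  conformational variants);
* **graft** heme/FMN/FAD cofactors from reference crystal structures and
  **check** that erased linkers can still bridge their anchors;
* **retro-engineer** sequences with motif-anchored, position-verified
  edits (deletions, insertions, substitutions, chimeras).

A synthetic-structure generator (`make_c2_dimer`, `make_topology_dimer`,
`make_ensemble`) provides dimers and prediction ensembles with known
ground truth, so the entire toolkit installs and tests offline.

## The statistics and models at the core

**Binding energy.** For two chain groups, every residue pair with any
heavy-atom pair within 5.5 Å is an interfacial contact (IC), classified by
residue character (charged / polar / apolar). With NIS the percentage
composition of solvent-exposed residues of the complex (relative SASA >
5 %, Shrake–Rupley, Tien-maxima normalisation), the predicted affinity is
the published linear contact model

```
ΔG = −0.09459·IC_cc − 0.10007·IC_ca + 0.19577·IC_pp − 0.22671·IC_pa
     + 0.18681·%NIS_apolar + 0.13810·%NIS_charged − 15.9433   [kcal/mol]
```

A model with |ΔG| < 3 kcal/mol is treated as *no complex*.

**Arbitration.** Pose similarity is the fraction of common residue–residue
interface contacts (fcc, Jaccard form); single-linkage clustering at
fcc ≥ 0.5 defines geometries; a geometry is *significant* when predicted
in ≥ 20 % of all runs (singletons never are). Within a geometry the
retained model is the one with the best (most negative) ΔG — predictor
confidence scores are deliberately ignored.

**Assembly.** The C2 axis is the screw axis of the least-squares
(Kabsch) superposition of one monomer onto the other; clashes are
heavy-atom pairs closer than the Bondi vdW sum minus 0.4 Å; the axial
separation is scanned inward from a guaranteed clash-free distance; the
dihedral angle is the midpoint of the largest arc feasible for *every*
supplied conformational variant.

## Worked example

```r
library(dimerforge)

## a synthetic 10-run prediction ensemble: 8 runs planted in the crossed
## (interchain FMNd–FADd) geometry, 2 in the closed (intrachain) one
ens <- make_ensemble(ensemble_spec(10, c(crossed = 0.8, closed = 0.2),
                                   seed = 42))
rep <- arbitrate(ens$members, "A", "B")
rep
#> <arbitration_report> 10 runs, 2 geometries, verdict: alternate_geometries
#>   cluster 1: freq 0.80, rep run 3 [significant]
#>   cluster 2: freq 0.20, rep run 9 [significant]
```

Both geometries are significant under the 20 % rule; the frequencies
recover the planted 0.8/0.2 exactly. The representative of the dominant
cluster is its affinity optimum:

```r
ids <- vapply(rep$members, `[[`, 1L, "run_id")
rep$members[[match(rep$clusters[[1]]$representative, ids)]]$dg
#> <binding_energy> dG = -17.01 kcal/mol (A vs B)
```

Topology labelling and symmetry detection close the loop on planted
ground truth:

```r
td <- make_topology_dimer("crossed", fixture_spec(seed = 42))
classify_topology(td$model, td$domains)
#> [1] "crossed"

fx <- make_c2_dimer(fixture_spec(noise_sigma = 0.2, seed = 7))
detect_c2_axis(fx$model)
#> <symmetry_axis> angle 179.515 deg, direction (0.0001, -0.0022, 1.0000), residual 0.518 A
```

(0.2 Å coordinate noise moves the recovered axis 0.13° off the planted
z-axis and the angle 0.5° off 180°.)

Sequence retro-engineering, anchored and verified before editing:

```r
s <- make_motif_sequence("VDSAADM", 648, 1049, id = "bm3_like", seed = 1)
r <- apply_edit(s, edit_op("insert_after", "VDSAADM", 648,
                           payload = "GSGGSG", target = "VDSA"))
r
#> <edit_report> anchor at 648: -0/+6 residues (delta +6), 1055 aa result
substr(r$edited$residues, 646, 662)
#> [1] "PGVDSAGSGGSGADMIN"
```

## Command line

Every operation is exposed through one entry point (`exec/cma`, or
`cma_main()` from R):

```sh
cma simulate --kind ensemble --seed 1 --out runs/ --truth truth.json
cma arbitrate --models 'runs/*.pdb' --groups A:B --report arbitration.json
cma dg --in complex.pdb --groups A:B --report dg.json --contacts contacts.tsv
cma assemble --part1 p450d_dimer.pdb --part2 fadd_dimer.pdb --out full.pdb
cma extract --in model.pdb --chain A --range 2:458 --out p450d.pdb
cma edit --in seqs.fasta --script edits.json --out variants.fasta
```

Exit codes: 0 success, 1 domain error (infeasible assembly, anchor not
found), 2 usage error. Reports are JSON and embed the resolved
configuration.

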