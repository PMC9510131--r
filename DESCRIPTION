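Package: dimerforge
Title: Arbitration, Interface Energetics, and Rigid-Body Assembly of
    Predicted Multidomain Protein Dimer Models
Version: 0.1.0
Authors@R:
    person("Philippe", "Vernet", email = "pvernet@posteo.net",
           role = c("aut", "cre"))
Description: Tools for working with ensembles of predicted multidomain
    protein complex structures. Reads and writes PDB/mmCIF coordinates,
    scores interchain interfaces with a contact-based binding free energy
    model, arbitrates among alternate predicted conformations by contact
    similarity clustering and frequency, classifies dimer domain
    topologies (crossed/closed, cis/trans), reconstructs full-length C2
    homodimer models from partial dimer models by symmetry-axis alignment
    and clash-minimal rigid-body placement, grafts cofactors from
    reference crystal structures, checks linker length feasibility across
    assembly seams, and performs motif-anchored sequence retro-engineering
    of domain linkers. A synthetic-structure generator provides dimers
    and ensembles with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
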