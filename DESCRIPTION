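Package: interolog3d
Title: Template-Based Inference of Protein-Protein Interactions Across
    Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers physical protein-protein interactions across species by
    3D-domain interolog mapping: candidate protein pairs drawn from the
    homolog families of a solved heterodimer template are aligned to the
    template chains and scored with a four-term knowledge-based energy
    function (sidechain van der Waals, special-bond, interface-similarity
    and couple-conserved terms), calibrated by a randomized-interface Z
    statistic and filtered by a per-species top-rank rule. Includes
    derivation of the 20x20 contact scoring matrices from a training
    library of dimer structures, profile-to-sequence alignment, per-residue
    binding-affinity (alanine-scan) scoring, and interface-evolution
    reports across interologs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
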