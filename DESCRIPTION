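Package: pbflex
Title: Protein Block Flexibility Analysis of Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Local-backbone flexibility analysis of molecular-dynamics
    conformational ensembles using the 16-letter Protein Blocks (PB)
    structural alphabet. Assigns a PB to every residue of every frame from
    its five-residue backbone dihedral window, summarises per-position PB
    frequency profiles, the equivalent number of PBs (Neq, the exponential
    of the Shannon entropy of the profile), and the L1 profile divergence
    (dPB) between two systems, and combines these with Calpha RMSF and
    B-factor tracks to compare a wild-type and a missense variant and flag
    long-range (allosteric) conformational effects. Includes a synthetic
    ensemble generator (PB-string, dihedral and backbone-coordinate modes)
    for ground-truth testing, multi-model PDB input/output, PB-fasta
    serialisation, and a region registry for the integrin alphaIIb leg
    domains (Thigh, Calf-1, Calf-2) in which many Glanzmann thrombasthenia
    variants fall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
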