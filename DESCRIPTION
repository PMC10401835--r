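Package: prostat
Title: Protein Structure Superposition, Accessibility and Parameter Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained workbench for protein coordinate and sequence
    analysis: fixed-column PDB reading and writing, global pairwise sequence
    alignment (Needleman-Wunsch with affine gaps), alignment-guided rigid-body
    superposition by the Kabsch algorithm scored with RMSD and GDT_TS,
    Shrake-Rupley solvent-accessible surface area with relative-accessibility
    normalisation against per-residue theoretical maxima, backbone dihedral
    and Ramachandran-region analysis, the classical sequence-derived
    physicochemical parameters (molecular weight, GRAVY hydropathy,
    instability index, isoelectric point), and a six-axis radar profile
    combining them.  Includes a deterministic synthetic-peptide generator
    used throughout the test suite and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    Biostrings,
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
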