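# prostat

Structural bioinformatics in plain R: rigid-body superposition of protein
structures with RMSD and GDT_TS scores, solvent accessibility, Ramachandran
analysis, the classical sequence-derived physicochemical parameters, and a
six-axis "function-to-form" radar profile that summarises them — everything
computed locally from a PDB file or a sequence string, with no network
services involved.

It is written for structural biologists and protein engineers who want the
numbers a typical protein-analysis web stack reports (superposition quality,
relative accessibility, model quality, instability, hydropathy, pI), but as
a scriptable, testable library and command-line tool.

## What it computes

**Superposition.** Two chains are aligned globally (Needleman–Wunsch,
BLOSUM62, affine gaps), the alpha-carbons of corresponding residues are
paired, and the Kabsch algorithm finds the rigid rotation R and translation
t minimising

    RMSD(v, w) = sqrt( (1/n) * sum_i |v_i - (R w_i + t)|^2 )

over the n pairs. The same superposed coordinates give the global distance
test scores

    GDT_PN = 100 * #{ i : |v_i - w_i| <= N angstrom } / n,   N in {1, 2, 4, 8}
    GDT_TS = (GDT_P1 + GDT_P2 + GDT_P4 + GDT_P8) / 4

By default only columns with *identical* residues are paired
(`mode = "all"` pairs every aligned column).

**Accessibility.** A Shrake–Rupley implementation (probe 1.4 Å, 960
deterministic lattice points per atom) gives per-atom and per-residue
accessible surface area; relative accessibility is

    RSA = 100 * sum(ASA_residue) / sum(MaxASA_residue)

with the per-residue theoretical maxima (ALA 129 … TRP 285 Å²) shipped as a
packaged table.

**Ramachandran.** Backbone φ/ψ torsions (IUPAC convention), region
classification on a packaged 2°-grid (general / Gly / Pro classes), and a
model-quality score `100 * favored / scored`.

**Sequence parameters.** Molecular weight (kDa), GRAVY (Kyte–Doolittle,
−4.5…+4.5), instability index (Guruprasad dipeptide weights), and the
isoelectric point (Henderson–Hasselbalch net charge, bisection; EMBOSS or
Bjellqvist pKa sets).

**F2F profile.** The six axes — Size, RC.Score, Accessibility, Instability,
Hydrophobicity, Isoelectric — each normalised linearly onto [0, 1] and
exportable as JSON, CSV or an SVG radar polygon.

A deterministic peptide generator (`build_peptide()`) builds ideal-geometry
helices, strands and random-torsion backbones; it powers the whole test
suite, so the package needs no downloaded structures.

## Worked example

```r
library(prostat)

ref <- build_peptide(60, "helix", sequence = "ACDEFGHIKLMNPQRSTVWY")
mob <- rigid_transform(perturb(ref, 0.5, seed = 2), random_rotation(3), c(12, -7, 5))

superpose_structures(ref, mob)
#> <superposition: 60 pairs (identical), RMSD 0.9163 A,
#>  GDT_TS 90.8 [P1 63.3 P2 100.0 P4 100.0 P8 100.0]>

rc_score(ref)
#> [1] 100

suppressWarnings(relative_accessibility(ref))
#> <accessibility: ASA 3244.3 A^2 / MaxASA 12120.0 A^2 = 26.77%>

compute_parameters("ACDEFGHIKLMNPQRSTVWY")
#> <params: MW 2.396 kDa, instability 84.7, GRAVY -0.490, pI 7.36>

build_profile(ref)   # profile of the 60-residue structure (20-mer repeated)
#> <f2f profile 'helix60'>
#>   Size           raw      7.151  ->  0.072
#>   RC.Score       raw    100.000  ->  1.000
#>   Accessibility  raw     26.768  ->  0.268
#>   Instability    raw     92.967  ->  0.930
#>   Hydrophobicity raw     -0.490  ->  0.446
#>   Isoelectric    raw      7.439  ->  0.531
```

Reading the numbers: the noisy copy superposes at RMSD ≈ 0.92 Å — close to
the √3 × 0.5 Å expected from 0.5 Å-per-coordinate noise — and 63% of pairs
still sit within 1 Å, so GDT_TS stays high at 90.8. The ideal helix has all
residues in the favored α basin (score 100), about 27% of its theoretical
maximal surface exposed, and a mildly hydrophilic, near-neutral sequence
profile.

The same workflows are scriptable from a shell:

```sh
inst/bin/prostat fixture helix --n 20 --out helix.pdb
inst/bin/prostat analyze helix.pdb --out report.json
inst/bin/prostat superpose ref.pdb model.pdb --pairs all --out-json scores.json
inst/bin/prostat params sequences.fasta
```

## Layout

- `R/` — structure I/O, alignment, superposition, surface, sequence
  parameters, Ramachandran, F2F, fixtures, CLI
- `inst/extdata/` — packaged constant tables (BLOSUM62, MaxASA, dipeptide
  instability weights)
- `inst/bin/prostat` — command-line entry point
- `vignettes/prostat-methods.Rmd` — models, conventions and design choices
- `tests/testthat/` — unit, property and end-to-end suites
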