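---
title: "Methods and design choices in prostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in prostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostat)
```

`prostat` computes, locally and deterministically, the quantities a protein
analyst usually collects from several different services: superposition
quality (RMSD, GDT_TS), solvent accessibility, Ramachandran statistics, the
classical sequence parameters, and a six-axis summary profile. This
vignette records the models behind each number, the parameters that matter,
and the places where the design was genuinely open and a choice had to be
made.

## Structure model and PDB handling

Coordinates are held in a flat atom table (one row per atom, fixed-column
PDB semantics) wrapped in a `prostat_structure`; chains and residues are
derived views. Conventions:

* Coordinates stay in ångströms as written; PDB residue numbers are
  preserved verbatim (they may be non-contiguous), while internal residue
  indexing is 0-based file order.
* Alternate locations: for each atom the highest-occupancy conformer is
  kept; ties go to the alphabetically first altloc. This matches common
  practice; no occupancy-weighted averaging is attempted.
* `TER` closes a chain, so a reused chain letter afterwards is a distinct
  chain; only the first `MODEL` of a multi-model file is read.
* `HETATM` records are parsed but excluded from sequence, Cα,
  accessibility and Ramachandran computations unless explicitly included
  (`het = TRUE`), so waters and ligands never leak into per-protein sums.
* Multi-chain files: every per-protein quantity can be computed on a
  selected chain (`get_chain()`); the default is all protein chains
  together, which is the least surprising behaviour for single-model
  analysis.

## Alignment

Residue correspondence comes from global Needleman–Wunsch alignment with
affine gap penalties (gap of length $k$ costs `gap_open` + $k$ ·
`gap_extend`). Defaults: BLOSUM62, `gap_open = 10`, `gap_extend = 0.5` —
standard protein-alignment settings; nothing in the problem fixes them, so
all three are configurable, and matrices can be loaded from NCBI-format
files. The nonstandard letter `X` scores 0 against everything, making
unknown residues alignment-neutral. Traceback ties are broken
deterministically (diagonal, then gap in the second sequence, then gap in
the first) so identical inputs always give identical alignments.

## Superposition and scores

The Kabsch algorithm (SVD of the coordinate cross-covariance, determinant
sign correction) gives the RMSD-optimal rigid transform; reflections are
never returned, so a mirror-image model superposes as well as a proper
rotation allows rather than spuriously perfectly. Degenerate pair sets
(fewer than 3 pairs, or collinear/coincident points, detected by a vanishing
second singular value) are errors rather than silently arbitrary rotations.

Two pairing modes exist because the correspondence definition is genuinely
ambiguous: `identical` (default) pairs only columns whose residues match,
`all` pairs every residue-vs-residue column. Distant homologues can leave
fewer than 3 identical pairs; the error message then points at
`mode = "all"`.

GDT_PN is the percentage of pairs within N Å **after the single
RMSD-optimal superposition**, cutoffs inclusive, N ∈ {1, 2, 4, 8}, and
GDT_TS is their mean. This deliberately diverges from the CASP convention,
which searches a maximal subset per cutoff; the single-superposition
variant is cheaper, deterministic, and consistent with computing GDT from
the same coordinates the RMSD uses. The percentage denominator is the pair
count by default; `denominator = "reference-length"` penalises
alignment-dropped residues instead.

## Solvent accessibility

Shrake–Rupley: each heavy atom's probe-expanded sphere (r_vdw + 1.4 Å) is
sampled on a deterministic golden-spiral lattice of 960 points; a point is
exposed if outside every neighbour's expanded sphere. 960 points keep the
quadrature error well under 1% of total ASA (the suite checks 960 vs 3840)
while keeping a 60-residue analysis interactive. Van der Waals radii:
C 1.70, N 1.55, O 1.52, S 1.80 Å; hydrogens are ignored (heavy-atom PDB
inputs), unknown elements are an error unless a fallback radius is given.
The neighbour search bins atoms on a grid with cell size equal to the
largest interaction distance, so cost stays near-linear in atom count.

Relative accessibility follows the sum-over-residues definition: RSA = 100
· ΣASA / ΣMaxASA, with the packaged per-residue theoretical maxima (Gly
104, Trp 285 Å², tripeptide-context values). Residues absent from the
table leave **both** sums and are reported, so the ratio stays internally
consistent. Because the maxima assume a tripeptide context, a sparse or
single-residue input can legitimately exceed 100%; the value is reported
with a warning rather than clamped — clamping happens only at profile
normalisation. Note the whole-chain sum is a global exposure measure; no
attempt is made to restrict it to active-site residues, which would require
an annotation the coordinate file does not carry.

## Ramachandran analysis

Torsions use the IUPAC sign convention (an ideal α-helix reads φ ≈ −57°,
ψ ≈ −47°); under this convention a torsion is *invariant* when the four
points are traversed in reverse order, which the suite checks along with
rigid-motion invariance and agreement with an independent implementation.
φ/ψ are not computed across chain breaks, detected as a peptide C–N
distance above 2.5 Å (configurable); residues missing a backbone atom lose
the affected angles and are flagged.

Classification uses a 2° × 2° grid with three classes (general, Gly, Pro),
generated in code from analytic ellipse/box approximations of the classic
favored/allowed basins (α, β/PPII, left-handed α; symmetric variants for
glycine; the restricted φ range for proline). This grid is **synthetic**:
no curated empirical density (e.g. a Top8000-derived table) ships with the
package, so the score — 100 · favored / scored — is comparable between
structures analysed here but is *not* numerically comparable with
PROCHECK/SAVES-style percentages. That caveat is the price of a fully
self-contained package.

## Sequence parameters

* **Molecular weight**: sum of average free-residue masses minus one water
  (18.0153 Da) per peptide bond, reported in kDa. `X` is an error by
  default; optionally it contributes the mean residue mass.
* **GRAVY**: mean Kyte–Doolittle hydropathy; `X` is excluded from both sum
  and count. The scale bounds ±4.5 are attained exactly by poly-Ile /
  poly-Arg.
* **Instability index**: (10/L) · Σ DIWV over the L−1 dipeptides, using
  the published Guruprasad weights (shipped as a packaged CSV); dipeptides
  containing `X` contribute weight 1. The raw value is unclamped — it can
  exceed 100 — and is clamped only on the profile axis.
* **Isoelectric point**: the unique root of the Henderson–Hasselbalch net
  charge (N/C termini plus D, E, C, Y, H, K, R side chains), found by
  bisection on pH 0–14. The loop refines until both the pH interval is
  below tolerance (default 10⁻³) *and* the charge magnitude is below 10⁻⁴
  — interval width alone is insufficient for long sequences, whose charge
  curves are steep near the root. pKa sets: EMBOSS by default, Bjellqvist
  selectable; the two can differ by a few tenths of a pH unit, which is an
  irreducible convention difference, not an accuracy statement.

## The six-axis profile

Each axis is normalised linearly onto [0, 1] and clamped: Size against a
configurable cap (default 100 kDa — the scale has a natural zero but no
natural maximum, so the cap is an explicit, documented choice), RC.Score /
Accessibility / Instability against 0–100, Hydrophobicity against ±4.5,
Isoelectric against pH 0–14. No composite scalar is derived from the six
axes; the profile is a visual/comparative device and any weighting of axes
would be arbitrary. Export formats: JSON (lossless round trip), CSV, and
an SVG polygon with vertex k at angle 2πk/6.

## The synthetic generator, and what the tests do and do not show

`build_peptide()` constructs N/CA/C/O backbones by natural-extension
placement with ideal geometry (N–CA 1.46, CA–C 1.52, C–N 1.33, C–O 1.23 Å,
ω = 180°) and prescribed torsions; `perturb()` adds seeded i.i.d. Gaussian
coordinate noise; `rigid_transform()` applies exact rigid motions. The
generator emulates what the analysis pipeline needs — correct topology,
exact known torsions, controllable noise — and deliberately not what it
does not: no side chains beyond the backbone, no realistic B-factors,
packing, solvent, or experimental error structure. Consequently the tests
demonstrate algorithmic correctness (exact-recovery, closed-form,
invariance and oracle-equivalence properties) on idealised inputs; they do
not certify accuracy claims on experimental structures, where altloc
density, missing atoms and non-ideal geometry are the norm (the parser's
handling of those is tested separately on constructed records).

Problem sizes used by the suite and the acceptance script — chains of 3–200
residues, pair sets up to 500, 960-point ASA lattices — were chosen as the
smallest sizes at which every property is non-trivially exercised.

## Known limitations

* Sequence-independent (structure-based) alignment, flexible superposition
  and TM-score are out of scope; superposition quality therefore depends
  on the sequence alignment being meaningful.
* GDT_TS is not CASP-comparable (single superposition, see above).
* The Ramachandran grid is analytic, not empirical; scores are internally
  consistent but not PROCHECK-comparable.
* ASA uses a fixed element-radius table and ignores hydrogens; values are
  close to, but not bit-identical with, DSSP or other implementations
  (the suite pins agreement with an independent implementation to 3%).
* mmCIF input, hydrogen addition and assembly generation are not
  supported.
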