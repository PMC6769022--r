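---
title: "Methods: interface, geometry and sequence analysis for tandem EC repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface, geometry and sequence analysis for tandem EC repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadint)
```

## Scope and model

`cadint` analyzes adhesive dimers of tandem extracellular cadherin (EC)
repeats: roughly 100-residue Greek-key β-sandwich domains joined by
calcium-binding linkers, which in protocadherins form antiparallel *trans*
dimers overlapping several repeats. The package takes deposited heavy-atom
coordinates (PDB or mmCIF, author residue numbering throughout), a
user-supplied table of repeat boundaries, and optionally a multiple
sequence alignment, and derives the quantities with which such an interface
is customarily characterized: buried surface area and its per-repeat-pair
decomposition, interface residues, composition, salt bridges, a
biological-versus-crystal-contact call, inter-repeat azimuthal geometry,
and residue conservation. Repeat boundaries are deliberately configuration,
not code: domain-boundary conventions differ between depositions and
papers, and hard-coding one convention would silently bias per-repeat
areas.

## Solvent-accessible surface area

SASA uses Shrake–Rupley sphere sampling. Each heavy atom is inflated by the
probe radius (default 1.4 Å, a water molecule) and covered with a
deterministic golden-angle spiral of `n_points` sample points (default
960). A point is accessible if it lies outside every neighboring inflated
sphere; the atom's area is the accessible fraction times its inflated
sphere area. Two numerical choices matter:

* **Deterministic spiral points, not random sampling.** Identical inputs
  give bit-identical areas, which makes regression tests meaningful. The
  discretization error of the spiral at 960 points is well under 1% for an
  isolated sphere and under 2% against the closed-form two-intersecting-
  spheres value, which is what the test suite asserts.
* **A declared radius table.** C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å
  (plus halogens and selenium), configurable per call. Published
  interface-area servers do not document their radii; results are only
  reproducible under a stated table, so unknown elements are a hard error
  unless a fallback radius is explicitly supplied (and its use is flagged
  in the result).

Neighbor search uses spatial binning with bin width
`2·max(radius) + 2·probe`, so cost grows with atoms times local neighbors;
a ~3,000-atom dimer evaluates in seconds. Waters are always excluded;
other hetero atoms (ions, glycans) are excluded by default with an opt-in
flag, since interface areas concern the protein protomers.

## Buried surface and its decomposition

`buried_surface()` performs three SASA evaluations — protomer A alone,
protomer B alone, the complex — and reports per-residue
`bsa = asa_free − asa_complex`. Sampling noise can make `bsa` a tiny
negative number; it is clipped to zero on report. The interface area is the
PISA convention, half the total SASA both protomers lose, so for a
symmetric dimer it equals one protomer's loss.

Per-repeat-pair attribution assigns each buried residue to the repeat of
the nearest partner-protomer heavy atom (ties broken toward the smaller
residue number), with the pair key ordered from protomer A's side. The
alternative — re-evaluating SASA on repeat subsets — does not conserve the
total; nearest-partner attribution conserves it by construction, which the
suite checks to 10⁻³ Å². Burial against residues outside every annotated
repeat is reported under `other` rather than dropped.

Interface residues use the buried-fraction criterion `bsa / asa_free ≥ 0.2`
by default; residues with zero free-state accessibility never qualify.
Composition fractions weight residues by buried area under a declared
three-class map (charged: Asp, Glu, Lys, Arg; hydrophobic: Ala, Val, Leu,
Ile, Met, Phe, Trp, Pro, Gly, Cys; hydrophilic: Ser, Thr, Asn, Gln, Tyr,
His). The map is a calibration starting point: composition conventions
vary, so the map travels with the configuration rather than being fixed.
Salt bridges pair basic side-chain nitrogens (Lys NZ, Arg NE/NH1/NH2)
with acidic side-chain oxygens (Asp OD1/OD2, Glu OE1/OE2) across protomers
within 4 Å; histidine is excluded by default because its protonation is
pH-dependent, with an opt-in flag. The biological-versus-crystal call uses
the empirical 856 Å² cutoff with a strict inequality, so a boundary value
is conservatively called crystal-contact-scale.

## Crystallographic symmetry

Many adhesion dimers are crystallographic: the deposited asymmetric unit
holds one protomer and the partner is a symmetry mate.
`apply_symmetry()` fractionalizes coordinates with the standard PDB
orthogonalization (a along x, b in the xy plane), applies the chosen
operator plus an integer lattice shift, and re-orthogonalizes. Operators
are read from mmCIF symmetry categories or PDB REMARK 290 records (which
are Cartesian and handled as such); when neither is present the package
refuses and asks for a pre-assembled two-chain file rather than guessing a
space group.

## Superposition and azimuthal geometry

Cα superposition uses the Kabsch algorithm with the proper-rotation
correction, pairing residues by shared author numbers by default — the
intersection of residues with a modeled Cα in both chains — because real
structure pairs differ in their missing loops. Fewer than three pairs or a
collinear point set is a hard error, since the rotation is then
under-determined.

A repeat's long axis is the largest-eigenvalue eigenvector of the
unweighted Cα covariance, with the sign fixed from the N-terminal-half
centroid toward the C-terminal-half centroid. Mass weighting is
deliberately omitted: the Cα-only unweighted convention is fully
declared and testable. If the top two eigenvalues agree within 1% the
cloud has no unique long axis and the result carries a degeneracy flag.

The azimuthal profile builds a frame where one reference repeat's axis is
+z and a second repeat's projected axis is +x (φ = 0). For each
consecutive pair along the chain, the N-terminal repeat is superposed onto
the z-reference and the azimuth of the C-terminal repeat's projected axis
is reported, counterclockwise about +z viewed from +z, in (−180°, 180°].
Both an external reference (two repeats of another structure, as when a
well-characterized cadherin defines the frame) and an internal reference
(the first two repeats of the analyzed chain, in which case the first
entry is 0 by construction) are supported; the frame is recorded in the
output. Projected axes shorter than 0.05 (tilt below ~3°) leave φ
undefined and flagged rather than numerically unstable.

## Conservation and motifs

The per-column conservation score is `1 − H/ln 20` with H the Shannon
entropy of gap-excluded residue frequencies: 1 for an invariant column, 0
for a column uniform over the 20 amino acids. This is a deliberate,
documented surrogate for evolutionary-rate methods (ConSurf-style models
weight the phylogeny; this score does not), chosen because it is exact,
dependency-free, and sufficient for ranking interface residues by
conservation. Columns with gap fraction above 0.5 are masked. The nine
bins are equal-width partitions of [0, 1] — not quantiles — so a column's
bin does not depend on the rest of the alignment. Structure mapping goes
through author numbering (reference-row ungapped position k ↔ residue
k + offset), tolerates unmodeled residues, and aborts beyond a configurable
mismatch count (default 5) to catch numbering-convention errors early.

Identity excludes double-gap columns and counts a gap-versus-residue
column as a difference; similarity additionally counts substitutions
within declared groups ({ILVM}, {FWY}, {KRH}, {DE}, {ST}, {NQ}, {AG}, {C},
{P} by default). Sequon scanning implements the necessary-condition rules
N-X(≠P)-[S/T] (overlaps allowed) and W-X-X-W; calcium-motif scanning
matches DXNDN, DXD, DRE and DYE exactly, suppressing DXD hits inside a
DXNDN (the longer motif subsumes them). The position-dependent XEX/XDX
linker motifs, where X is unconstrained, are not globally scannable and
are intentionally not scanned.

## Assay quantification

Melting temperature: the trace is min–max normalized over its full range
and Tm is the first upward crossing of 0.5, linearly interpolated. This
makes Tm invariant under affine rescaling of the fluorescence axis and
matches the instrument convention of reading the normalized-signal
midpoint. Multi-transition curves are out of scope; the first crossing is
reported.

Bead aggregates: the image is binarized (`intensity > threshold`, with
Otsu's histogram method as the deterministic automatic option), connected
components are labeled under 8-connectivity (the blob-area convention of
the common image-analysis tools), components below `min_size` pixels are
discarded, and per-particle areas plus their mean are reported. Replicate
images are summarized as mean ± SEM of the per-image mean areas.

## What the synthetic data does and does not show

The generator emits every fixture class the pipeline needs, written in the
same standard formats the analysis functions read, with ground truth
computed from the construction:

* sphere clusters with closed-form SASA (isolated and pairwise-cap);
* tandem-repeat rods of identical prolate Cα clouds in which repeat k+1 is
  placed by rotating repeat k's frame by the prescribed twist, so the
  recovered azimuth equals the twist exactly up to coordinate rounding,
  alongside a two-repeat reference defining the frame;
* antiparallel toy dimers whose contacting residues and repeat pairs
  follow from a distance check at the SASA contact radius;
* alignments with prescribed invariant columns; logistic melt curves with
  known midpoints; disc images with exact pixel areas.

All randomness flows through one seed recorded in the bundle manifest, and
same-seed runs are byte-identical. These fixtures validate the
bookkeeping, the numerics, and the conventions — they are not miniature
proteins. Real EC repeats have side chains, irregular surfaces, glycans
and ions; passing tests therefore demonstrate correctness of the method,
while agreement with published interface areas for deposited structures
additionally depends on radius tables and parameters that published
servers do not document (a ≤10% tolerance is the realistic expectation
there, and structure downloads are outside the test surface by design).

Problem sizes were chosen so the whole suite exercises every path at desk
scale: 80-atom toy dimers for three-way SASA, six-repeat rods (24 Cα per
repeat) for twist recovery, 100-seed melt-curve ensembles at 1% noise,
160×160-pixel bead images, and 200-sequence alignments for sampling
bounds.

## Known limitations

* SASA is numeric only; no analytic (Lee–Richards or Gauss–Bonnet)
  surfaces, and no molecular (Connolly) surface.
* No free-energy estimates, hydrogen-bond networks, or assembly
  enumeration beyond the single-interface analysis.
* Superposition is rigid; no outlier rejection or flexible fitting.
* The conservation score ignores phylogenetic correlation between
  sequences; closely related over-represented taxa inflate apparent
  conservation.
* Sequence-to-structure mapping assumes author numbering indexes the
  reference sequence up to a constant offset; renumbered depositions need
  the offset argument.
* Watershed splitting of touching bead aggregates is not attempted; a
  merged pair counts as one particle, as in simple threshold-and-label
  workflows.
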