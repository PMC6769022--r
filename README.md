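# cadint

Structural and sequence analysis of adhesive interfaces formed by tandem
extracellular cadherin (EC) repeats.

Protocadherins and other non-classical cadherins mediate cell–cell adhesion
through antiparallel *trans* dimers in which several EC repeats of one
molecule overlap the same repeats of a partner molecule from the opposing
cell. Characterizing such an interface from crystal coordinates means
answering a linked set of questions: how much solvent-accessible surface is
buried on complexation and by which repeat pairs; which residues are at the
interface and which of them form salt bridges; whether the buried area is
large enough to be a biological interface rather than a crystal contact;
how consecutive repeats twist about the molecular axis; and how conserved
the interface residues are across orthologs. `cadint` implements this whole
workflow for structural biologists working on cadherin-family adhesion,
together with quantification of the two standard wet-lab readouts used to
validate candidate interfaces (differential scanning fluorimetry and
bead-aggregation imaging) and a synthetic-data generator that makes every
stage testable against analytic ground truth without any PDB downloads.

## Methods at the core

* **SASA** — Shrake–Rupley sphere sampling: each atom inflated by the probe
  radius r_p (default 1.4 Å) is sampled with a deterministic golden-spiral
  point set (default 960 points); the accessible fraction times
  4π(r_vdw + r_p)² is the atom's area.
* **Buried surface** — per residue, BSA = ASA(free protomer) −
  ASA(complex), from three SASA evaluations. The interface area is the PISA
  convention ½·ΣBSA over both protomers. A residue is an *interface
  residue* when BSA ≥ 20% of its free-state ASA. Per-repeat-pair areas
  attribute each residue's burial to the repeat of the nearest partner
  atom, so the decomposition conserves the total exactly.
* **Classification** — interfaces larger than an empirical 856 Å² cutoff
  are called plausibly biological (strict inequality).
* **Salt bridges** — Lys NZ / Arg NE,NH1,NH2 (optionally His) nitrogen
  within 4 Å of Asp OD1,OD2 / Glu OE1,OE2 oxygen across protomers.
* **Geometry** — Kabsch least-squares superposition of shared Cα atoms
  (proper rotation enforced) and an azimuthal ladder for tandem repeats:
  with a reference repeat's long axis defining +z and a second repeat's
  projected axis defining φ = 0, each consecutive repeat pair is superposed
  into the frame and the C-terminal repeat's projected principal axis gives
  its azimuth φ ∈ (−180°, 180°].
* **Conservation** — per-column score 1 − H/ln 20 (H = Shannon entropy of
  gap-excluded residue frequencies), binned into nine equal-width bins,
  mappable onto structure residues and paintable into the B-factor column.
  Percent identity/similarity, insertion detection, N-glycosylation sequon
  (N-X(≠P)-[S/T]) and calcium-binding motif (DXNDN, DXD, DRE/DYE) scans.
* **Assays** — melting temperature as the first upward 0.5 crossing of the
  min–max-normalized fluorescence trace; bead aggregates as 8-connected
  components of the thresholded image (Otsu or fixed threshold).

## Worked example

Build a fully overlapped antiparallel four-repeat toy dimer (the geometry
of an EC1–4 adhesion complex) and analyze its interface:

```r
library(cadint)

fx  <- make_toy_dimer("fix", n_repeats = 4, residues_per_repeat = 10, gap = 5)
s   <- read_structure(fx$paths$dimer)
ann <- read_repeat_annotation(s, fx$paths$annotations)
bs  <- buried_surface(s, "A", "B", sasa_params(), ann)

interface_area(bs)
#> [1] 460.9114
repeat_pair_areas(bs)
#>      pair  area
#> 1 EC3:EC2 124.2
#> 2 EC1:EC4 122.3
#> 3 EC4:EC1 108.1
#> 4 EC2:EC3 106.3
classify_interface(interface_area(bs))
#> [1] "crystal-contact-scale"
nrow(interface_residues(bs, 0.20))
#> [1] 16
```

The 460.9 Å² interface decomposes exactly into the four antiparallel repeat
pairs EC1:EC4, EC2:EC3, EC3:EC2, EC4:EC1 — repeat i of protomer A against
repeat n+1−i of protomer B, as the antiparallel construction dictates — and
falls below the 856 Å² biological cutoff, as expected for a thin synthetic
contact. Sixteen residues bury at least 20% of their free accessible area.

For a real structure, `run_report(analysis_config(...))` orchestrates the
full analysis (symmetry-mate generation from the crystal's operators,
buried surface, composition, salt bridges, azimuthal profile, conservation
painting) and writes a JSON report plus CSVs with every parameter echoed in
a log.

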