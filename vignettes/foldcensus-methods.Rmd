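---
title: "Scoring protein folds for conformational heterogeneity against a single predicted reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein folds for conformational heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Structure-prediction models return one conformation per sequence, while many
proteins function through several. When a protein has tens or hundreds of
experimentally solved structures, the spread of those structures around the
predicted model is a direct, experimentally grounded measure of how much
conformational heterogeneity the prediction leaves unrepresented — and that
spread is a property of the *fold*, not just the protein. `foldcensus`
implements the full chain of analysis: harmonize experimental structures,
extract the matching domain from a full-length predicted model, superpose,
aggregate per fold, and ask which biological processes use the heterogeneous
folds.

## The procedure and its assumptions

**Domain extraction and mapping.** Domains are defined by CATH-style
four-level codes plus residue segments in author numbering. Each domain
instance's sequence is aligned to the protein's reference sequence with an
affine-gap alignment that is *global in the domain* and has *free end gaps
in the reference* (BLOSUM62, gap open 10, gap extension 0.2, gap of length
$k$ costing $10 + 0.2k$). The one-on-one matched columns define the residue
map through which the corresponding predicted-structure domain is cut out
of the full-length model, residue for residue. The glocal form is the only
reading under which every extracted predicted domain aligns one-on-one with
a CATH window: the domain must be wholly explained, the full-length protein
merely contributes a window. The unknown residue `X` scores 0 against
everything so engineered or modified positions neither help nor hurt.

**Curation.** The analysis set keeps instances from proteins with at least
10 distinct experimental structures, longer than 10 residues, with sequence
identity to the reference of at least 99% (computed over matched columns
only — gaps are ignored), resolution no worse than 3 Å, and without
extended terminal arms. Rejection reasons are assigned in that fixed order,
so funnel summaries are reproducible. Predicted models are additionally
screened by confidence: at least 90% of residues must have pLDDT above 80
(pLDDT rides in the B-factor column, the convention of the public model
databases).

**Superposition and normalization.** Comparisons use CA atoms of the mapped
residue intersection (CA-only is robust to side-chain noise and matches
fold-level claims; unresolved residues are handled by intersecting the
maps). The Kabsch least-squares fit is computed by singular value
decomposition with the determinant correction, so a reflection is never
returned. Because RMSD grows with domain length at fixed relative accuracy,
the census also reports
$\mathrm{RMSD100} = \mathrm{RMSD} / (1 + \ln\sqrt{n/100})$, the value
rescaled to a 100-residue domain. For $n \le 13$ the denominator is not
positive and the value is reported as missing rather than extrapolated.

**Geometry metrics.** Solvent-accessible surface area is Shrake–Rupley with
a 1.4 Å probe and a deterministic 960-point golden-spiral lattice; volume is
the union of van der Waals spheres counted on a 0.5 Å voxel grid (both in
compiled code). A residue is buried when its relative SASA — observed over
the residue type's theoretical maximum — falls below 0.25. The two
compactness summaries are the area-to-volume ratio and the
buried-to-exposed residue ratio. Residues contacting heteroatom groups
within 4 Å are counted once per category, metals identified by element and
waters excluded throughout.

**Secondary structure.** Assignment follows the hydrogen-bond formulation:
amide hydrogens are rebuilt along the preceding carbonyl direction, bonds
are accepted below −0.5 kcal/mol under the classical electrostatic model,
helices are runs of at least four residues covered by consecutive
i→i+4 bonds, and strands are bridge-paired runs of at least two residues.
The per-instance quantity fed to the census is the signed count difference
(prediction minus experiment) of helix-plus-strand residues over mapped
positions.

**Grouping.** Instances are first clustered greedily at 95% sequence
identity (longest first, ties by identifier; identity is identical matched
columns over the shorter length — the short-word convention, configurable
to alignment-length). Each cluster is then split into sub-clusters by
topology code and, within a topology, by single linkage on resolved-window
overlap at a 0.9 agreement fraction. Single linkage with this cut is chosen
because it reproduces the two splitting rules the census requires — one
sub-cluster per topology when a region carries several annotations, and
separate sub-clusters for disjoint resolved windows — while remaining
order-independent.

**Census.** Per group (sub-cluster, topology, or class) the census reports
n, median/min/max RMSD, the MAD scaled by 1.4826 (so it estimates a robust
standard deviation; the raw MAD is available), the interquartile range,
tier fractions at 2.5 and 5 Å, and medians of the geometry metrics over the
instances where they are defined. Group medians are per-instance by
default; a per-sub-cluster-median mode exists for heavily redundant folds.

**Downstream analyses.** The region-wise analysis computes, per instance,
the RMSD of two user-specified regions (switch-I/switch-II style) under the
*global* superposition — no refit, so an open switch can stand many Å from
a well-fitted core. Conformations are clustered in that 2D plane by Ward
linkage with automatic k by maximal mean silhouette over 2–10. The
enrichment analysis takes proteins owning a group with median RMSD above
2.5 Å (heterogeneous) versus proteins owning a group in the lowest decile
of group medians (consistent; ties at the boundary included, heterogeneous
membership taking precedence), and tests each annotation term by the
one-sided hypergeometric tail in both directions, with Benjamini–Hochberg
adjusted values alongside the raw ones.

## The synthetic-data generator

Real multi-conformer ensembles cannot ship with the package, so every stage
is exercised on generated data with known ground truth. Templates are
ideal-geometry backbones (helix φ −57°/ψ −47°, strand φ −119°/ψ 113°, full
N/CA/C/O plus CB) assembled into helix-bundle, sheet-sandwich, mixed, or
extended architectures with seeded random sequences over the 18
non-Gly/Pro residues. Conformers apply a hinge rotation — the tail beyond a
chosen loop rotating about the CA–CA axis at the hinge, by an angle drawn
from Normal(0, σ) — plus iid Gaussian displacement on every atom. The
"predicted" reference either copies one random conformer (`pick_one`, a
prediction locked to one state) or averages coordinates (`average`, a
blended prediction); mock pLDDT is written as 90 minus eight times the
local ensemble fluctuation, clipped to [50, 99].

Default study conditions are ten folds with hinge σ evenly spaced from 0°
to 30°, twelve conformers each, and 0.2 Å thermal noise — noise at the
scale of crystallographic coordinate uncertainty — on 60-residue
helix-bundle templates with the hinge at the second inter-helix loop. The
switch analysis generator plants six archetype patterns (pairs of flap
rotations of two interior regions) with 2° jitter and 0.1 Å noise.

What the generator does *not* emulate: side chains beyond CB, realistic
packing or force-field energetics, crystal contacts, missing-density
patterns, or B-factor structure. Passing tests therefore demonstrate that
the pipeline recovers planted geometric signal through the full
file-format round trip — not that any biological claim about real folds is
reproduced at desk scale.

## Design choices made where the design was open

* **Terminus filter vs terminal hinges.** The extended-terminus rule
  (flag when more than 5 consecutive terminal residues deviate beyond 5 Å
  after a core fit; a deterministic two-pass trim) targets construct
  artifacts such as expression tags. A purely deviation-based rule cannot
  distinguish an artifact arm from genuine hinge motion of a terminal
  element, and under the generator's conditions the hinge arm *is* the
  signal: with σ up to 30° about one conformer in eight trips the filter,
  selectively deleting the most informative conformers and visibly biasing
  the per-fold dispersion. The rule therefore stays default-on for
  real-data curation but is exposed as a pipeline switch
  (`terminus_filter`), and the parameter-recovery analyses run with it
  off. Window and deviation thresholds are configurable.
* **Alignment traceback.** Scores are checked against exhaustive
  enumeration; the traceback follows the alignment engine's deterministic
  convention, which in rare exact-tie cases may pick a different but
  equally optimal path than a hand-specified tie order.
* **Region RMSD without refit** is the default (an alternative core-only
  fit is available through `fit_positions`), since refitting on a mobile
  region would hide exactly the displacement being measured.
* **Identity denominator** is the shorter sequence; **MAD scaling** is
  1.4826; **silhouette-selected k** is capped at 10; all configurable.
* **Pipeline caching.** Stage outputs are written once per run, stamped
  with a hash of the configuration; reruns are deterministic, which is
  verified by test rather than by an intermediate-cache mechanism.

## Problem sizes and statistical behaviour

The shipped analyses use 10 folds × 12 conformers × 60 residues (120
structures) for the census and 6 archetypes × 7 conformers for the switch
analysis — sizes at which every stage, including SASA, volume and
secondary structure for all instances, completes in well under a minute.

One statistical caveat is worth stating explicitly. With twelve conformers
per fold the sample MAD carries roughly 25% relative sampling error, while
adjacent folds on the even 0–30° amplitude grid differ by about 12% in true
dispersion, so rank inversions between neighbouring folds are expected and
the Spearman correlation between planted amplitude and census MAD
typically lands near 0.85–0.9 rather than above it. The maximum RMSD per
fold, a deeper order statistic of the hinge distribution, tracks amplitude
more reliably. Larger ensembles sharpen both; the package reports what the
data support.

## Known limitations

* mmCIF reading relies on a minimal subset of `atom_site`; exotic files
  (multi-entity auth/label divergence) should be converted to PDB first.
* NMR multi-model files contribute only their first model.
* Alternate locations keep the highest-occupancy atom only.
* The hypergeometric enrichment treats annotation terms independently; no
  ontology propagation is performed, by design.
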