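---
title: "Methods: structural accessibility of phosphosites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural accessibility of phosphosites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phosphoconform)
```

## The question and the model

A kinase transfers a phosphate onto a serine, threonine or tyrosine it
can physically reach, so solvent accessibility of the site is a
necessary condition for an enzymatic phosphorylation event. Given a
table of reported phosphosites and protein structures, the package
classifies each site by the accessibility of the octapeptide that
surrounds it (positions *i−3 … i+4*, phosphoresidue fourth) and then
asks, for buried sites, whether a documented conformational mechanism —
oligomer dissociation, an alternate conformation, kinase recruitment by
a consensus motif, or intrinsic low-frequency dynamics — could expose
them in the cell.

The key quantity is **rSASA**, the mean over the eight window residues
of %SASA, where a residue's %SASA is its solvent accessible surface
area in the folded structure divided by its area in an extended
(φ = −120°, ψ = +120°) Gly-X-Gly tripeptide built with the same atom
conventions. Normalising per residue removes size effects; averaging
over the window captures that a kinase active-site cleft engages the
flanking residues, not just the phosphoacceptor.

### Classification and rescue

Sites with rSASA ≥ 0.2 lie in the *allowed region of
phosphoconformation*; below 0.2 they are *disallowed*. The boundary
value 0.2 is treated as allowed: the underlying evidence separates
"less than 0.2" from the rest, and a configurable stringent variant at
0.3 is provided. Rescue rules only ever move sites from disallowed to
allowed:

1. **Interface**: if the structure is an oligomer, rSASA is recomputed
   on the isolated chain; phosphorylation must have occurred on the
   monomer if the site is accessible there.
2. **Alternate structure**: with several structures per protein the
   maximum rSASA is carried forward, so burial in one crystal form is
   overruled by exposure in another.
3. **Dynamics**: conformers sampled along low-frequency normal modes
   (below) can transiently expose a site.
4. **Consensus motif**: a buried site matching S/T-P-X-K/R (the
   cyclin-dependent kinase consensus, anchored at the phosphosite) is
   assumed reachable in an alternate cellular conformation.

When several rules would fire we report the first in the order
interface > alternate > dynamics > motif; the rules are cumulative in
spirit and the order only affects the label, not the final class.

Sites that cannot be scored are partitioned exactly: *terminal* (fewer
than 3 residues before or 4 after the site — the window cannot be
formed), *disordered* (the octapeptide matches the sequence but one or
more residues lack coordinates), *mutated* (no exact match, but the
8 × 19 single-substitution scan finds matches at exactly one window
position), *unmatched* (no or ambiguous substitution matches),
*low-coverage* (structure covers < 70% of the primary sequence,
boundary inclusive), *no-structure*.

## SASA engine

SASA uses Shrake–Rupley sampling: each atom is inflated by the probe
radius (1.4 Å, water) and covered with a deterministic generalized
spiral of `n_sphere_points` points (default 960); points inside any
neighbouring inflated sphere are occluded and the accessible fraction
times the sphere area is the atom's SASA. Van der Waals radii follow
Bondi (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20 Å). %SASA is not
clamped at 1 — the reference state is a convention and the thresholds
act on raw ratios.

Numerical behaviour worth knowing:

* The spiral lattice is fixed in the laboratory frame, so translations
  leave areas bit-identical while rotations re-sample occlusion;
  per-residue areas agree to ~1–2% at 960 points (and converge as the
  lattice is refined). Every fixed-lattice implementation shares this
  property; tests assert translation invariance exactly and rotation
  invariance at sampling resolution.
* Reference tripeptide areas are computed once per parameter set and
  cached; Gly flanks are the default, Ala is available.
* **Residue depth** is the mean distance of a residue's atoms to the
  nearest retained (solvent-accessible) sample point, minus the atom's
  own solvent-contact radius, so exposed residues score ≈ 0 and buried
  residues the distance below the surface. This approximates
  water-placement depth programs well enough for ordinal use; the
  agreement statistic between depth and rSASA classifications is
  therefore tested ordinally, and the depth cutoff is configurable
  (the conventional value 30 belongs to the scale of real, full-atom
  proteins; synthetic fixtures a few tens of residues across use a
  fixture-scale cutoff of ~2 Å in tests).

### Coarse model for conformers

Elastic-network conformers carry only Cα positions, so their SASA uses
one sphere per residue, with radius chosen so the sphere volume equals
the residue's mean volume (e.g. Gly 2.43 Å, Trp 3.79 Å before probe
inflation). Coarse %SASA is normalised by coarse reference values from
a three-sphere extended trace at 3.8 Å spacing. Coarse and all-atom
per-residue accessibilities correlate well on globular fixtures (rank
correlation > 0.7 in tests) but are not numerically interchangeable —
the dynamics stage therefore compares coarse conformer values against
the same threshold rather than mixing scales.

## Cα elastic network and conformer ensembles

Each residue is a node at its Cα; pairs within R_C = 10 Å are joined by
identical harmonic springs at their input-structure distance, giving
E = ½k Σ (d_ij − d⁰_ij)². Masses are uniform and k = 1 (arbitrary
units): only mode shapes and orderings matter. The 3N × 3N Hessian at
the minimum has exactly 6 zero eigenvalues for a connected network
(rigid-body motions); more indicate disconnection and the structure is
rejected. Short interior gaps (≤ 2 consecutive unobserved residues) are
bridged by linear interpolation of Cα positions; longer gaps make the
chain ineligible rather than inviting speculative modelling.

Conformers are generated by displacing the structure along each of the
20 lowest-frequency vibrational modes at 20 evenly spaced amplitudes
spanning both signs (zero excluded), plus the input structure:
20 × 20 + 1 = 401 conformers. The amplitude scale is set so the largest
single-residue displacement of the extreme conformer is `max_amp`
(default 2.0 Å) — large enough to expose sites held under mobile
elements, small enough that the harmonic approximation holds (conformer
energies match ½λa² within a few percent in tests). Both the sign
convention and the amplitude are exposed as parameters since the
choice of "small intervals" along a mode is not canonical.

## Whole-protein flexibility (A_rel)

For monomeric structures with at most 5 unobserved residues, the
observed total SASA is divided by the empirical prediction
4.44·M^0.77 Å² (M = protein mass in Da, from average residue masses
plus one water). A_rel > 1 indicates a more extended or flexible
conformation than a compact globular protein of that mass.

## What the synthetic generator emulates — and what it does not

The generator provides every input class the pipeline distinguishes,
with ground truth enforced at generation time by rejection sampling
(SASA checks are asserted; packing is jittered and rebuilt on failure):

* **Globules**: a helical core octapeptide (rSASA < 0.1 by
  construction) wrapped in a six-helix shell with end caps, plus an
  exposed surface segment (rSASA > 0.4) in a polyproline-II-like
  conformation — open enough to be fully accessible, compact enough
  that every residue keeps ≥ 3 network contacts (a fully extended tail
  would leave chain-end nodes with 2 contacts, i.e. spurious
  zero-frequency mechanisms).
* **Homo-tetramers** whose central chain carries a mid-helix site:
  accessible on the monomer (≥ 0.3), buried in the assembly (< 0.2).
* **Rigid cage / mobile flap** fixtures for the dynamics stage: the
  cage's core stays below coarse rSASA 0.1 in all 401 conformers; the
  flap holds its site under covering strands at the mouth of a hinged
  clamp (all-atom rSASA 0.17, coarse 0.15) and scissor-like
  low-frequency modes swing it above 0.2.
* **Cohorts**: one protein and one planted site per record, with
  categories apportioned by largest remainder from the requested rates
  and all sequences drawn from a seeded RNG (the global RNG state is
  saved and restored). Default rates (35% exposed, 20% buried, 8%
  interface, 7% motif, 15% disordered, 5% each mutated / terminal /
  low-coverage) echo the accounting of large phosphoproteome-to-PDB
  matching studies: most testable sites accessible, a striking buried
  minority, and sizeable losses to disorder and termini.

Generated structures are backbone + Cβ only, with reference areas
computed under the same reduced-atom convention so %SASA stays
calibrated. They are architectural cartoons, not folded proteins: no
side-chain packing, no physical chain connectivity between segments,
no crystallographic artefacts. Passing the planted-truth tests
demonstrates that the bookkeeping, thresholds and rescue logic are
exact, and that the geometric machinery orders buried versus exposed
correctly; it does not validate %SASA against full-atom proteins —
that is what the cross-implementation oracle tests (agreement within
5% per residue with an independent Shrake–Rupley implementation on the
same coordinates and radii) are for.

## Numerical choices and edge cases

* Boundary semantics: rSASA threshold inclusive (0.2 → allowed);
  coverage threshold inclusive (0.70 retained); dynamics rescue strict
  (conformer must exceed the threshold).
* Octapeptide location uses exact substring search anchored within ±2
  of the expected offset, absorbing isoform numbering drift while
  rejecting distant repeats; several anchored matches (possible for
  tandem repeats, found with an overlap-aware search) make the site
  ambiguous and it is excluded.
* Among multiple matching chains of one structure the chain with the
  highest sequence coverage is used; among multiple structures the
  maximum rSASA is carried (this is what enables the
  alternate-structure rescue).
* Altloc conformers resolve to highest occupancy (ties alphabetical);
  the first MODEL of multi-model files is used; SEP/TPO/PTR map to
  their parent residues with a modified flag; a residue is observed if
  any of its atoms (in practice the Cα) is present.
* Zero eigenvalue tolerance: λ < 1e−8 × λ_max. The elastic energy at
  the input structure is exactly zero because reference distances are
  evaluated with the same floating-point expression as the energy.
* Histograms use 0.1-wide bins, half-open on the right with the last
  closed; %SASA values above 1 are clamped into the last bin for
  display only.

## Problem sizes

Unit tests run on 8–20-residue peptides and ~130-residue fixtures with
240-point sampling where only ordering matters, and 960–1920 points
where accuracy is asserted. The end-to-end cohort uses 56 proteins
(~125 residues each), and the dynamics fixtures evaluate the full
401-conformer ensembles; the acceptance script regenerates everything
from scratch in a few minutes on one CPU.

## Known limitations

* No side chains beyond Cβ in generated fixtures; real PDB inputs with
  full side chains are analysed at all-atom level, but their %SASA is
  normalised against reduced-atom reference tripeptides, which inflates
  ratios for large exposed side chains. For classification this is a
  systematic, threshold-calibratable effect; for absolute comparison
  with published per-protein values use the same normalisation
  throughout.
* mmCIF, crystallographic symmetry expansion and loop modelling of
  missing residues are out of scope; insertion codes are preserved but
  never used for arithmetic.
* The dynamics stage explores single modes at fixed amplitudes; mode
  combinations, anharmonicity and side-chain rearrangements are beyond
  the elastic-network approximation.
* Autophosphorylation (a kinase reaching its own buried site) cannot be
  inferred from structure alone; the pipeline accepts it only as an
  input annotation.
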