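# phosphoconform

Structural accessibility analysis of protein phosphorylation sites.

High-throughput mass-spectrometry phosphoproteomics reports tens of
thousands of phosphosites, but a kinase can only phosphorylate a residue
it can physically reach. `phosphoconform` asks, for each reported site
with a solved structure, whether the site lies in the **allowed region of
phosphoconformation** (solvent-accessible to a kinase) or the
**disallowed region** (buried), and whether an apparently buried site can
be rescued by a known conformational mechanism.

## The quantities at the core

For a phosphosite at sequence position *i*, the package analyses the
octapeptide *i−3 … i+4* (phosphoresidue at window position 4):

* **%SASA** of residue *r*: SASA(*r* in the structure) / SASA(*r* in an
  extended Gly-*r*-Gly tripeptide), computed by Shrake–Rupley sphere
  sampling (probe 1.4 Å, deterministic spiral lattice).
* **rSASA** of the site: the mean %SASA over the eight octapeptide
  residues. Sites with rSASA ≥ 0.2 are *allowed* (0.3 in the stringent
  variant); sites below are *disallowed*.
* **Rescue rules** for disallowed sites: recompute on the isolated
  monomer (interface burial); take the maximum over alternate deposited
  structures; accept a matching kinase consensus motif (S/T-P-X-K/R for
  CDKs); or sample conformers along the 20 lowest-frequency normal modes
  of a Cα elastic network model (E = ½k Σ (d_ij − d⁰_ij)², R_C = 10 Å;
  20 modes × 20 amplitudes + input = 401 conformers) and accept the site
  if any conformer exposes it above threshold.
* **Residue depth** (distance below the accessible surface) as an
  independent check, and **A_rel** = observed SASA / (4.44·M^0.77) as a
  whole-protein flexibility index.

Sites whose octapeptide cannot be evaluated are accounted for explicitly:
*disordered* (missing coordinates), *mutated* (exactly one
single-residue substitution restores the sequence match), *terminal*
(too close to a chain end), *low-coverage* (structure covers <70% of the
sequence).

A seeded synthetic-structure generator builds globules with buried
cores, homo-oligomers with interface-buried sites, rigid cages and
mobile flaps, and full cohorts with planted ground truth, so the whole
pipeline is testable without PDB or PhosphoSitePlus downloads.

## Worked example

```r
library(phosphoconform)

co  <- generate_cohort(cohort_spec(n_proteins = 8, seed = 7))
rep <- run_map(co$sites, co$structures)
dplyr::count(rep, status, label, rescue)
#> # A tibble: 5 × 4
#>   status     label      rescue              n
#>   <chr>      <chr>      <chr>           <int>
#> 1 disordered <NA>       <NA>                1
#> 2 matched    allowed    consensus_motif     1
#> 3 matched    allowed    interface           1
#> 4 matched    allowed    none                3
#> 5 matched    disallowed none                2
```

Three sites sit on exposed surface octapeptides (`allowed`, rSASA ≈
0.76–0.79), two are buried in globule cores (`disallowed`, rSASA <
0.001), one is buried at a homo-tetramer interface but reaches rSASA
0.57 on the isolated monomer (`rescue = interface`), one buried site
matches the CDK consensus (`rescue = consensus_motif`), and one falls in
a disordered segment (no coordinates for part of its octapeptide).

Conformational rescue runs separately, here on a rigid-cage negative
control and a mobile-flap fixture:

```r
dyn <- run_dynamics(rep_fixtures, structures_fixtures)
dyn[, c("accession", "rsasa", "max_conformer_rsasa", "label", "rescue")]
#>   accession    rsasa max_conformer_rsasa label      rescue
#> 1 CAGE      0.000377               0     disallowed none
#> 2 FLAP      0.171                  0.210 allowed    dynamics
```

All 401 conformers of the cage stay below 0.1, so the buried call
stands; a low-frequency mode of the flap swings its site above 0.2, so
the site is reclassified as allowed.

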