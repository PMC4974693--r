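---
title: "Comparing cocrystal ensembles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing cocrystal ensembles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalvar)
```

## The problem

A protein that binds many chemically different inhibitors — dipeptidyl
peptidase IV (DPP-4), the motivating system, is the canonical example —
accumulates large numbers of cocrystal structures. Comparing all of them at
once answers questions no single structure can: whether the backbone or
side chains move in response to the ligand, which residues are contacted by
most inhibitors, whether diverse ligands share geometric binding rules, and
which crystallographic waters are structural (hydrated) rather than
incidental. `xtalvar` implements that comparison end to end, together with
a synthetic-data generator whose ground truth lets every stage be verified
quantitatively.

## Units and selection rules

The unit of analysis is one protein molecule, its bound inhibitor, and the
water oxygens within 4 Å of the protein. A deposited entry may contain one,
two or four copies of the protein; each chain is screened independently:

- residues restricted to a configurable span (default 41–764, the 724
  ordered residues of mature DPP-4);
- fewer than `max_disordered` (default 6) span residues without any
  resolved heavy atom — partial side chains count as present, since
  "disordered" is read as missing coordinates, the standard interpretation;
- in inhibitor-bound mode, a hetero molecule with at least one heavy atom
  within 4 Å of the active-centre residue (default Ser630). Two qualifying
  hetero molecules are an error that must be resolved explicitly per entry,
  not silently tie-broken;
- hydrogens are dropped at parse time: all distances in this package are
  between heavy atoms. Alternate locations are resolved by keeping the
  highest-occupancy conformer (ties: lexicographically first altloc) — a
  deterministic rule chosen because depositions vary. Insertion codes are
  rejected outright; they do not occur for this protein and silently mixing
  author numbering schemes would corrupt residue correspondence, which is
  everywhere by author residue number.

## Superposition and RMSD

All pairwise fits minimize RMSD = sqrt(mean of squared pair distances) over
proper rigid motions, computed by the Kabsch algorithm: SVD of the
cross-covariance of the centred coordinate sets with a determinant
correction so a reflection can never be returned. The optimum of this
least-squares problem is unique for non-collinear point sets, so any
correct minimizer (e.g. the superposition tools of molecular-graphics
programs) gives the same answer; the test suite verifies agreement both
with an independent rotation-grid-plus-polish search and with
`bio3d::fit.xyz`. Collinear or too-small inputs are refused
("underdetermined superposition") rather than answered arbitrarily.

Pairs are matched on shared Cα atoms by residue number (the intersection —
residues missing from either unit are simply absent from that pair's fit).
`pair_combinations(n)` = n(n−1)/2 makes the bookkeeping explicit: 147 units
mean 10,731 fits.

## Variation between units

Two flavours of the same statistic, the mean over unit pairs of an atom's
post-superposition displacement:

- **Cα variation**: the pair is superposed on *all* shared Cα atoms (a
  global fit), then each residue's Cα displacement is recorded. This
  measures where the backbone genuinely differs between units; it is not
  invariant to internal deformation, which is the point.
- **Side-chain variation**: the pair is superposed on that one residue's
  N/Cα/C atoms (a local fit), so whole-molecule motion cancels and the
  statistic isolates side-chain reorientation. It is measured at the
  reporter atom furthest from the main chain (Arg Nη, Tyr Oη, Ser Oγ,
  Val Cγ, Asn Nδ, Glu Oε, His Nε, Phe Cζ, Trp Cη, ...). For symmetric
  reporter pairs (Arg NH1/NH2, Glu OE1/OE2, Val CG1/CG2) the two per-atom
  displacements are computed with fixed name correspondence and averaged —
  plain averaging, no symmetry-swap minimization, matching how such atoms
  are conventionally tallied; a swap-minimizing variant would only lower
  values for residues whose naming flips between deposits.

Pairs in which a residue (or its reporter) is unresolved are dropped from
that residue's denominator M. Residues present in fewer than two units have
undefined variation and are reported as missing. Per-amino-acid baselines
(e.g. "the average of the equivalent amino acids") are computed as
unweighted means over residues of the same type.

Under the generator's Gaussian displacement model these statistics have
closed forms that the tests exploit: the difference of two σ-noised copies
is Gaussian with per-coordinate variance 2σ², so the expected squared pair
RMSD is 6σ² and the expected displacement (a Maxwell mean) is 4σ/√π. The
acceptance suite verifies both to within 5 % at 10 units × 500 residues for
σ ∈ {0.1, 0.2, 0.5} Å, and recovers a planted graded mobility profile with
Spearman ρ > 0.9.

## Binding area and binding modes

A residue contacts an inhibitor when any heavy-atom pair is closer than
4 Å. Contact fractions are tallied over *distinct* inhibitors
(deduplicated by chemical-component identifier; an inhibitor present in
several copies counts once) with unit-level tallies always emitted
alongside, because both denominators are informative. Membership thresholds
are strict: core means fraction > 0.70, extended > 0.30, so the degenerate
setting high = low = 0 reduces to "any contact". Increasing the cutoff can
only grow fractions and memberships (a tested monotonicity invariant).

Binding-mode classification takes a `site_map` naming which residue numbers
play the Glu205/Glu206/Tyr662/Arg125/Asn710/Ser630 roles, so renumbered or
synthetic systems can be analysed:

- **Amine network**: one primary or secondary amine nitrogen of the ligand
  simultaneously < 4 Å from a Glu205 Oε, < 4 Å from a Glu206 Oε and < 5 Å
  from the Tyr662 Oη. Amine class is decided by valence alone — a ligand N
  with 1–2 heavy-atom neighbours within 1.8 Å bond distance — because no
  connectivity records are assumed. A nitrogen-free ligand trivially fails,
  matching the known single exception among DPP-4 inhibitors.
- **Polar anchor**: any ligand O, N or halogen < 4 Å from an Arg125 Nη atom
  or the Asn710 Nδ2/Oδ1 atom. Both amide atoms are accepted because the
  Nδ/Oδ assignment demonstrably swaps between deposits. Published
  descriptions of this mode oscillate between "and" and "and/or"; the
  package reports the OR flag plus separate per-partner flags, so either
  tally is recoverable.
- **Covalent Ser630**: Ser630 Oγ < 3 Å from a ligand carbon, the signature
  of nitrile warheads.

π–π stacking geometry (Tyr547, Phe357) is deliberately out of scope: the
literature's grouping of those rings is visual, with no numeric rule to
implement.

## Conserved waters

Water oxygens within 1 Å of one another after superposition are "the same"
water. That pairwise rule does not by itself define a multi-unit consensus,
so the package makes its choice explicit: all waters are mapped into a
reference unit's frame via the global Cα fits, then greedily clustered —
the point with most in-radius neighbours seeds a site, one water per unit
(the nearest) joins, the centroid is recomputed once and membership is
finalized within the radius, and the procedure repeats on the remaining
pool. The procedure is deterministic; ties break by lowest unit id, then
lowest atom serial. Units with no deposited waters are excluded from the
support denominator, and the default support threshold is expressed as a
fraction (61/143) so it scales to ensembles of any size. Site supports are
stable (±1) under a change of reference unit on synthetic data, and frame
invariance, radius monotonicity and one-member-per-unit are tested
invariants.

Annotation distinguishes hydrated from incidental water: proximity to the
binding area (< 4 Å, evaluated per member in that member's own unit — the
consensus-frame alternative is coarser and was not chosen), the number of
member units whose ligand comes within 5 Å, and B-factor comparisons of
each member against its own unit's water average and protein heavy-atom
average, the classical signature of structural water.

## Exposed surface area

Per-residue solvent-accessible surface area via Shrake–Rupley sampling on a
deterministic spherical Fibonacci lattice (default 960 points/atom, probe
1.4 Å, radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å), with waters and ligand
excluded before the calculation. The isolated-sphere and two-sphere cases
have closed forms that the tests check to 1 % and 2 %; a fully enclosed
atom scores exactly zero. Absolute values from other parameterizations
(e.g. analytic-surface web servers) will differ slightly; downstream use is
ordering residues by exposure, and the tests assert that the ranking is
stable under ±5 % perturbation of the radii table.

## The synthetic generator — what it does and does not emulate

`ensemble_spec()`/`generate_ensemble()` build an idealized α-helical
template (2.3 Å radius, 1.5 Å rise, 100°/residue) with N/Cα/C backbone and
side-chain reporter pseudo-atoms pointing radially outward. Six consecutive
mid-chain residues are assigned the binding-site roles and their functional
atoms converge on a pocket centre outside the helix barrel — a straight
helix would splay them apart, and the pocket construction is what lets the
planted ligand satisfy the amine-network distances (defaults 3.0/3.2/4.2 Å,
comfortably inside the 4/4/5 Å rules even under coordinate noise). Each
unit is the template plus per-residue isotropic Gaussian noise (the σ
profile), whole-residue deletions at the missing-residue rate, planted
waters (present in a configurable fraction of units, default 0.8, jitter
0.2 Å, B = 10 Å²) over uniform random waters (box = bounding box + 6 Å,
≥ 2.4 Å from any atom, B = 40 Å²; only those within 4 Å of the protein are
retained, mirroring the unit definition), all under a random rigid pose.
Protein B-factors are constant at 25 Å², between the two water classes.
One seeded RNG stream drives all draws in a fixed order (pose, protein
noise, missing residues, water presence and jitter, random waters), so
ensembles are reproducible bit for bit, and coordinates are rounded to the
PDB format's 3-decimal precision so the file round trip is exact. Units can
be written as legal PDB files to exercise the real I/O path.

What it does **not** emulate: real side-chain chemistry and rotamer
libraries, correlated (domain-level) motion, crystal-contact artefacts,
resolution-dependent water registration, or ligand diversity — every
synthetic unit carries the same inhibitor. Passing tests therefore
demonstrate that the statistics, thresholds and clustering behave correctly
on data with known structure; they do not certify agreement with any
particular experimental ensemble, which additionally depends on deposition
quality and chain-selection choices the generator does not model.

## Numerical choices and problem sizes

- Kabsch degeneracy guard: second singular value of either centred set
  below 1e-8 × scale → error instead of an arbitrary rotation.
- Binding-area thresholds are strict inequalities; distance rules are
  strict `<` at 4/5/3 Å exactly as stated above.
- Water clustering stores the assignment centroid, so the within-radius
  membership invariant holds exactly.
- Tests and the acceptance script run at deliberately modest scales chosen
  to make the statistical tolerances tight while keeping the suite fast:
  10 units × 500 residues for scale recovery (the across-residue mean has
  ≪ 1 % sampling error there, so the 5 % bands are meaningful), 20 seeds ×
  20 units × (5 planted + 50 random waters) for conserved-water recall, and
  4–10 units × 60–120 residues for end-to-end pipeline checks.

## Known limitations

- Residue correspondence is by author numbering only; no sequence alignment
  is attempted, so ensembles mixing numbering conventions must be
  renumbered upstream.
- No symmetry-mate expansion or biological-assembly reconstruction: a water
  or ligand contact donated by a crystallographic neighbour is invisible.
- Outlier-rejection ("fit-and-trim") superposition variants are not
  offered; all shared Cα atoms enter every fit, which can differ from
  graphics-program defaults that trim cycles.
- The SASA module is a sampling method with its own radii table; compare
  rankings, not absolute Å² values, against other tools.
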