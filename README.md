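# xtalvar

Ensemble comparison of protein–inhibitor cocrystal structures.

When one protein has been crystallized with dozens of different inhibitors —
the motivating case is dipeptidyl peptidase IV (DPP-4), a diabetes drug
target with well over a hundred deposited cocrystal copies — a systematic
comparison of all those copies answers two questions: does the protein
change its backbone or side chains depending on the bound ligand, and do
chemically diverse inhibitors obey common geometric binding rules? `xtalvar`
implements that comparison as a reusable, tested pipeline for structural
bioinformaticians:

- **Unit extraction** — one protein chain restricted to a residue span
  (DPP-4 convention: residues 41–764, i.e. 724 residues), its bound
  inhibitor (a heavy atom within 4 Å of the active-centre residue), and the
  water oxygens within 4 Å of the protein; chains with six or more
  disordered residues are rejected.
- **All-pairs superposition** — Kabsch (SVD) rigid-body fits on shared
  Cα atoms, minimizing

  RMSD = √( (1/N) Σᵢ χᵢ² )

  with χᵢ the distance of the i-th matched atom pair; `n` units give
  `n(n−1)/2` fits (147 units → 10,731).
- **Variation profiles** — per-residue mean post-superposition displacement
  over all unit pairs,

  Variationᵢ = (1/M) Σₖ δᵢₖ,

  in a Cα flavour (global fit) and a side-chain flavour (per-residue
  N/Cα/C local fit, measured at the reporter atom furthest from the main
  chain, e.g. Arg Nη, Tyr Oη, Ser Oγ; symmetric atom pairs averaged).
- **Binding area & binding modes** — contact-frequency definition of the
  inhibitor binding area (<4 Å, core >70 % / extended >30 % of distinct
  inhibitors), plus per-unit classification of the recurring modes: the
  amine network (one primary/secondary amine N simultaneously <4 Å to
  Glu205 Oε and Glu206 Oε and <5 Å to Tyr662 Oη), the Arg125/Asn710 polar
  anchor (<4 Å), and the covalent nitrile–Ser630 Oγ bond (<3 Å).
- **Conserved waters** — water oxygens within 1 Å after superposition are
  treated as the same structural water; greedy centroid clustering yields
  consensus sites with per-unit support, proximity flags and B-factor
  comparisons against each unit's water and protein averages (hydrated vs
  incidental crystal water).
- **Exposed surface area** — per-residue Shrake–Rupley solvent-accessible
  area (waters and ligand excluded), averaged over units.
- **Synthetic ensembles** — a generator that emulates the statistical
  structure of such data (per-residue Gaussian displacement, random rigid
  poses, planted ligand geometry, planted conserved waters over random
  clutter, missing residues) with full ground-truth bookkeeping, so every
  stage is testable without downloading structures.

## Worked example

```r
library(xtalvar)

e <- generate_ensemble(ensemble_spec(n_units = 5, n_residues = 120,
                                     sigma = 0.15, n_planted_sites = 4,
                                     n_random_waters = 40, seed = 20))
cfg <- run_config(e$units, span = e$units[[1]]$span,
                  active_site_residue = e$truth$site_map$ser630,
                  site_map = e$truth$site_map, sasa_points = 480)
rep <- run_pipeline(cfg)
print(rep)
#> <xtalvar_report> 5 units (0 rejected), 10 pairs
#>   mean/max C-alpha RMSD: 0.366 / 0.389 A
#>   mean C-alpha variation: 0.339 A
#>   binding area: 10 core / 10 extended residues
#>   amine network prevalence: 1
#>   conserved water sites (support >= 3): 4
```

The mean pairwise RMSD (0.366 Å) and mean Cα variation (0.339 Å) match the
closed forms for the generator's σ = 0.15 Å displacement field — σ√6 ≈
0.37 Å and 4σ/√π ≈ 0.34 Å — because superposition removes the random rigid
poses exactly. All five units carry the planted amine network (prevalence
1), the ten pocket residues contacted by the ligand form the binding area,
and the four planted water sites are recovered with full support and
flagged `low_b` (their B-factor of 10 Å² is below both the water and the
protein averages of their units):

```r
rep$waters$sites[, c("site_id", "support", "mean_b", "low_b")]
#>   site_id support mean_b low_b
#> 1      S1       5     10  TRUE
#> 2      S2       5     10  TRUE
#> 3      S3       4     10  TRUE
#> 4      S4       4     10  TRUE
```

With `out_dir` set, `run_pipeline()` also writes `rmsd_summary.tsv`,
`calpha_variation.tsv`, `sidechain_variation.tsv`, `area.tsv`, `modes.tsv`,
`waters.tsv`, `sasa.tsv` and a `report.json` with the headline aggregates
and every threshold echoed for provenance. Reruns on the same inputs are
byte-identical.

To analyse real deposits, point the pipeline at a directory of PDB files
(`run_config("path/to/pdbs", ...)`) or use the command-line wrapper:

```sh
Rscript inst/scripts/xtalvar.R run --pdb-dir pdbs/ --out-dir results/ \
    --span 41:764 --active-site 630 --max-disordered 6
```

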