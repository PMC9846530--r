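# nmrcsp

Chemical shift perturbation (CSP) analysis for protein backbone NMR, built
around solid-state NMR studies of the histone H3 core domain in condensed
nucleosome arrays. When the same protein is assigned under several
conditions — e.g. chromatin arrays differing only in linker DNA length —
the per-residue shift differences pinpoint where the local environment
changed. `nmrcsp` covers the complete desk side of such a study, for NMR
spectroscopists and structural biologists working from deposited shift
tables.

## What it computes

For each residue with amide ¹H, ¹⁵N and ¹³Cα shifts assigned in both
conditions, the combined chemical shift difference

&nbsp;&nbsp;&nbsp;&nbsp;Δδ = √( Δδ²(¹Hᴺ) + α·Δδ²(¹⁵N) + β·Δδ²(¹³Cα) )

with β = 0.3 and α = 0.14 (0.2 for glycine). Significance thresholds are
then derived from the data: the residues with Δδ below a 0.1 ppm trim
cutoff form a background subset, and thresholds sit at the subset mean
plus 2.5 and 5 subset SDs, classifying residues as `below`, `significant`
or `pronounced`.

Around that core:

* **I/O** — NMR-STAR v3 assigned-chemical-shift loops (BMRB dialect) and
  plain TSV, read and write; TALOS shift-input export; FASTA sequences;
  per-residue intensity TSVs.
* **Completeness** — non-proline assignment accounting over a residue
  range; relative peak-intensity profiles and their comparison.
* **Structure mapping** — per-residue Δδ or category codes written into a
  PDB file's B-factor column (only that field is touched; every other byte
  is preserved).
* **Synthetic data** — a seeded generator producing condition sets of
  shift tables (random-coil baselines, helix offsets, planted
  perturbations, Gaussian noise, undetectable segments) so the entire
  pipeline is testable without downloads.
* **Drivers** — `run_compare()` / `run_simulate()` write per-pair CSVs,
  summaries, manifests and B-factor maps; a thin CLI wrapper lives in
  `inst/cli/nmrcsp.R`.

## Worked example

Three synthetic linker-length conditions, then the 15 bp-like vs 60
bp-like comparison:

```r
library(nmrcsp)
tabs <- generate_condition_set(synthetic_spec(seed = 1))
prof <- pairwise_profile(tabs$linker15, tabs$linker60)
prof
#> <csp_profile> linker15 vs linker60
#>   85 residues, 83 with combined delta
#>   mean combined delta = 0.06 +/- 0.06 ppm (n = 83)

derive_thresholds(prof)
#> <threshold_result>
#>   pair: linker15 vs linker60
#>   trimmed subset (delta < 0.1 ppm): n = 70, mean = 0.0415, sd = 0.0215 ppm
#>   thresholds: 0.095, 0.149 ppm (k = 2.5, 5)
#>   classification: below 68, significant 5, pronounced 10, incomplete 2

assignment_stats(h3_sequence(), 44, 132, assigned_residues(tabs$linker60))
#> <assignment_stats> residues 44-132
#>   89 residues, 2 proline(s), 87 non-proline
#>   assigned: 83 out of 87 non-proline residues
#>   unassigned: 78, 79, 80, 81
```

Reading: 83 of the 87 non-proline core residues carry a combined Δδ; the
background (trimmed) mean is ~0.04 ppm so the significance levels land at
0.095 and 0.149 ppm, and the ten `pronounced` residues are the planted
DNA-interface perturbations of the short-linker condition. The two
`incomplete` records are the residues flanking a gap where one condition
lacks a nucleus. `plot(prof, thresholds = derive_thresholds(prof))` draws
the conventional per-residue bar chart.

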