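---
title: "Chemical shift perturbation analysis with nmrcsp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical shift perturbation analysis with nmrcsp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrcsp)
```

## The problem

Backbone chemical shifts are exquisitely sensitive reporters of local
protein conformation. When the same protein is assigned under two
experimental conditions — here, the structured core domain of histone H3 in
nucleosome arrays whose linker DNA length is varied — the per-residue shift
differences localize where the environment or conformation changed, without
requiring any new structure determination. `nmrcsp` implements the full
desk side of such a study: reading deposited shift tables, combining
per-nucleus differences into a single per-residue perturbation score,
deciding which residues are significantly perturbed, accounting for how
complete the assignment is, and projecting the result onto a crystal
structure for visualization.

## The combined shift difference

For each residue with amide ^1^H, ^15^N and ^13^Cα shifts assigned in both
conditions, the nucleus-wise differences are merged into one scalar by a
weighted Euclidean norm:

$$\Delta\delta = \sqrt{\Delta\delta_{H^N}^2 +
  \alpha\,\Delta\delta_N^2 + \beta\,\Delta\delta_{C\alpha}^2}$$

with $\beta = 0.3$ and $\alpha = 0.14$ for every residue type except
glycine, which uses $\alpha = 0.2$. The weights compress the wider ^15^N
and ^13^C dispersions onto the amide-proton ppm scale; glycine gets a
larger nitrogen weight because its ^15^N dispersion is narrower. All three
weights are user-configurable through `csp_weights()`, but only this
functional form is offered.

```{r}
combined_delta(0.05, 0.2, 0.1, "A")
combined_delta(0.05, 0.2, 0.1, "G")   # glycine branch
```

A residue only receives a combined value when all three nuclei are present
in both conditions (`complete = TRUE` in the profile). Partial records are
kept — their individual nucleus differences are still reported — but they
are excluded from every summary statistic. Prolines have no amide proton
and therefore never produce a combined value; they appear as gaps, exactly
as they do in amide-detected spectra. The difference is taken as
(first condition − second condition) per nucleus; the combined value is
invariant under swapping the two conditions.

## Significance thresholds

Rather than a fixed cutoff, significance levels are derived from the
profile itself. The residues whose combined difference falls below a trim
cutoff (default 0.1 ppm, strict `<`) form a background subset; thresholds
are placed at the subset mean plus 2.5 and 5 subset standard deviations.
Residues at or above the first threshold are `significant`, at or above the
second `pronounced`. This is a single-pass outlier heuristic, not a
hypothesis test: by construction roughly 1–2% of background residues will
exceed a mean + 2.5 SD level, so isolated single-residue flags deserve
skepticism while contiguous flagged stretches are the meaningful signal.

```{r}
derive_thresholds(c(0.02, 0.04, 0.06, 0.30))
```

Numerical conventions, chosen where the procedure leaves room and exposed
as arguments:

* **SD estimator** — sample SD (n − 1 denominator) throughout;
  `sd_type = "population"` switches to the n denominator.
* **Boundary rule** — thresholds are category *floors*: a residue exactly
  at a threshold takes the higher category. Documented because tie handling
  is otherwise ambiguous.
* **Trimming** — single pass at the fixed cutoff. An off-by-default
  `iterative = TRUE` variant re-trims against the current lower threshold
  until stable, which is more robust when moderate perturbations
  contaminate the sub-cutoff background.
* **Per-comparison subsets** — each condition pair gets its own trimmed
  subset. Pooling across comparisons can be done by concatenating the
  combined differences and passing the vector to `derive_thresholds()`.
* **Degenerate SD** — if every background value is identical the SD is 0,
  all thresholds collapse onto the mean, and everything at that value is
  classified by the floor rule (highest category). The subset must contain
  at least 3 values; otherwise an error advises a larger cutoff.

## Assignment completeness and intensity profiles

`assignment_stats()` counts non-proline residues in an inclusive residue
range and how many of them are assigned; "assigned" defaults to *has both
amide H and N shifts* (the fingerprint-spectrum definition,
`assigned_residues()`), switchable to requiring Cα as well. For the
135-residue histone H3 sequence shipped with the package, the core range
44–132 contains 87 non-proline residues (prolines 66 and 121 excluded):

```{r}
assignment_stats(h3_sequence(), 44, 132,
                 assigned = setdiff(44:132, c(66, 121, 78:81)))
```

`intensity_profile()` converts raw per-residue peak intensities to relative
ones. The normalization anchor is the dataset maximum (the strongest peak
becomes exactly 1); mean-anchoring is available via `anchor = "mean"`.
`compare_profiles()` reports RMSD and Pearson correlation over shared
residues (at least 3 required).

## Structure mapping

`write_bfactor_map()` writes per-residue values — combined differences or
category codes (`incomplete` 0, `below` 1, `significant` 2, `pronounced`
3) — into the B-factor column of a PDB file so any molecular viewer can
color by perturbation. Only the fixed-column temperature-factor field
(columns 61–66, two decimals) of ATOM/HETATM records on the selected chains
is rewritten; every other byte of the file is preserved. Values are
clipped to the representable −99.99…999.99 range with a warning. Both
histone H3 copies in an octamer receive the same per-residue values, since
the NMR data cannot distinguish them; insertion codes are not supported.

## The synthetic generator

Real deposited shift tables cannot be bundled or downloaded at test time,
so `synthetic_spec()` + `generate_condition_set()` produce condition sets
with the statistical structure the analysis assumes:

* **Baseline** — per residue type, an embedded random-coil shift table
  (values near the standard empirical tables); inside helical segments
  fixed secondary-shift offsets are added (Cα +2.8, CO +1.8, H^N −0.25,
  N −1.5, Cβ −0.5 ppm). Absolute baseline values are immaterial: every
  downstream statistic is a difference.
* **Observability** — residues outside the core range (default 44–132) and
  inside undetectable segments (defaults 35–43 and 78–81, emulating
  exchange-broadened stretches) are removed; prolines lack H/N.
* **Perturbations** — each condition plants per-nucleus offsets at
  designated sites. The default three-condition set uses a reference with
  no perturbation, a condition with moderate offsets (combined ≈ 0.16 ppm)
  at four sites, and one with stronger offsets (≈ 0.22 ppm) at ten
  DNA-interface residues, mimicking a short-linker condition.
* **Noise** — independent Gaussian noise per nucleus, defaults 0.01 ppm
  (^1^H) and 0.05 ppm (^15^N, ^13^C). Differencing two conditions then
  yields a background combined difference of ≈ 0.05 ppm on average, the
  right order for tightly packed solid-state samples. The defaults were
  fixed once from that consideration, not calibrated to reproduce any
  particular published average.
* **Seeding** — one master seed; each condition draws from a seed derived
  deterministically from it, so regenerating a single condition is stable
  and byte-identical across runs. The caller's RNG state is left
  untouched.

What the generator does *not* emulate: linewidths and line broadening,
peak overlap, referencing offsets between depositions, correlated
(segment-wise) perturbations, and assignment errors. Passing the recovery
tests therefore demonstrates that the statistics behave correctly under
the stated noise model, not that any particular biological conclusion
would be recovered from real spectra.

With the default noise and planted combined differences ≥ 0.15 ppm, the
full pipeline (generate → profile → thresholds → classify) attains
per-site sensitivity above 0.95 with a background false-positive rate
below 0.05 over hundreds of seeded replicates; the test suite checks this
at 200 replicates, a problem size chosen so the whole suite runs in well
under a minute.

## End-to-end runs

`run_compare()` drives the whole analysis over ≥ 2 conditions (tables or
NMR-STAR/TSV files): per-pair profile and classification CSVs, a summary
CSV with mean ± SD combined difference and mean ± SD |Δδ~Cα~| per pair,
and optional B-factor-mapped PDBs. All CSVs carry `#` provenance headers
with the package version and parameters, and re-runs are byte-identical.
`run_simulate()` writes a synthetic condition set plus a ground-truth
manifest of planted sites. A thin command-line wrapper over these two
functions ships in `inst/cli/nmrcsp.R`.

```{r}
tabs <- generate_condition_set(synthetic_spec(seed = 1))
out <- file.path(tempdir(), "csp-demo")
res <- run_compare(tabs, out)
res$summary[, c("pair", "n_complete", "mean_delta", "sd_delta")]
```

## Known limitations

* The NMR-STAR support is a minimal dialect: one assigned-chemical-shift
  loop, author numbering, no ambiguity codes or multi-list depositions.
* Thresholds inherit the weaknesses of any SD heuristic: they are not
  p-values, and with fewer than ~20 background residues the subset SD is
  itself noisy.
* Structure mapping is PDB fixed-column only (no mmCIF write) and matches
  residues purely by author number.
* The reported "±" spreads are descriptive SDs of per-residue values, not
  uncertainties of the means.
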