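# nbscreen

Analysis toolkit for nanobody (VHH) discovery campaigns, built around a
screen of alpaca-derived nanobodies against *Streptococcus pyogenes* Cas9.
It covers the full downstream analysis of such a campaign for bench
scientists triaging clones: the repertoire sequence census, relative
affinity measurement by ELISA, competition-based epitope binning,
single-molecule mass-photometry confirmation of simultaneous binding, and
a gel-based test that binders do not inhibit the enzyme.

## What it computes

**Repertoire census.** Clone nucleotide sequences are translated (reading
frame chosen automatically), deduplicated, and assigned a germline origin
by pairwise alignment against a user-supplied V/D/J reference (match 1 /
mismatch 0, affine gaps; identity = matches / alignment columns). Somatic
mutations are counted on the V alignment — nucleotide mismatches plus
indel columns — and amino-acid changes on the codon-aligned V translation.
FR1–FR4/CDR1–3 boundaries are transferred from fixed anchors on the
germline V (CDR3's end from the J's FR4 anchor). A lysine census
(inside vs outside CDR3) drives selection of clones that can be chemically
biotinylated with NHS esters without risking the antigen-binding loop.
Pairwise identity matrices and neighbor-joining cladograms summarize
library diversity.

**Dose–response.** Blank-subtracted absorbances are fit with the
four-parameter logistic

    A(x) = bottom + (top − bottom) / (1 + (EC50 / x)^h)

by deterministic least squares, yielding EC50s in nM.

**Epitope binning.** For a sandwich ELISA in which an unlabeled capture
clone immobilizes the antigen, the statistic for analyte *i* under capture
*c* is

    corrected AUC_i = AUC_i − AUC_c(self)
    percent binding_i = 100 · corrected AUC_i / max_j corrected AUC_j

with AUC the trapezoid area of blank-subtracted signal over
log10(concentration), clamped to [0, 100]. Percent binding below 25%
means the analyte was blocked (same epitope), above 60% it bound freely
(different epitope); the zone between is reported as indeterminate rather
than forced. Bins are connected components of the graph of same-epitope
calls; conflicts and transitivity-only pairs are flagged. The
normalization denominator is the within-experiment maximum by default, or
the tightest binder's direct-ELISA area via `reference_auc=`.

**Mass photometry.** A linear contrast-to-mass calibration, an EM-fitted
Gaussian mixture over landing-event masses (component count by BIC,
deterministic quantile initialization, 40 kDa noise floor), and a
combinatorial search for the nanobody subset whose summed mass explains
each peak, including a stepwise mass-shift report.

**Cleavage kinetics.** Gel band intensities become percent cleavage
(100·products/(uncut+products)), time courses aggregate replicate means
and SDs, and a treated-vs-control comparison calls a nanobody
non-inhibitory when trajectories stay within a configurable band (default
15 percentage points).

**Synthetic data.** Every input has a seeded generator with recorded
ground truth (`gen_repertoire`, `gen_dose_response`, `gen_competition`,
`gen_mp_events`, `gen_gel`), and `campaign_scenario()` bundles the
campaign's stated world: nine binders in three epitope bins, EC50s from
2 to 63.4 nM, the 160/180/190/209 kDa mass series, equal cleavage rates.

## Worked example

```r
library(nbscreen)

# the published qualitative competition outcomes, three captures x nine analytes
bins <- infer_bins(campaign_competition_calls())
print(bins)
#> bin1: D9, E6, F1, F8, G10, G7
#> bin2: C7, F9
#> bin3: C1
```

Three epitope bins: one clone (C1) in its own bin, a pair (F9, C7), and a
six-clone group. The same inference on simulated plates with measurement
noise recovers the planted map; self cells are 0 by construction, blocked
pairs sit far below 25% and free pairs far above 60%:

```r
sc <- campaign_scenario()
sim <- gen_competition(sc$epitope_map, sc$affinities, noise_sd = 0.02, seed = 42)
scores <- lapply(plates_to_experiments(sim$plates), score_competition)
binning_report(scores)$matrix[c("C1", "F9", "E6"), c("C1", "C7", "F9", "E6", "D9")]
#>     C1   C7   F9   E6    D9
#> C1   0 93.1 93.0 67.7 100.0
#> F9 100  1.1  0.0 62.2  89.3
#> E6 100 83.8 84.1  0.0   1.4

fit_4pl(dose_response_curve("C1", "Cas9", default_dose_grid(),
        fourpl(default_dose_grid(), 0, 1.8, 2, 1) + 0.05, blank = 0.05))
#> fourpl_fit: C1 vs Cas9  EC50 2 nM  hill 1.00  [0.000, 1.800]
```

## Analysis workflow

The `analysis/` directory holds the campaign's analyses as numbered
drivers over the package functions, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic inputs + ground truth
Rscript analysis/02_census.R          # census, gene usage, cladogram
Rscript analysis/03_dose_response.R   # 4PL fits, apo vs RNP, cross-reactivity
Rscript analysis/04_binning.R         # percent-binding matrix, bins
Rscript analysis/05_mass_photometry.R # mixture fits, complex assignment
Rscript analysis/06_cleavage.R        # time courses, inhibition verdicts
```

All sequence coordinates in outputs are 0-based half-open; every report
starts with a comment header recording the package version, seed and a
configuration hash.

## Acceptance script

`scripts/acceptance.R` regenerates the scenario's inputs from a seed and
re-runs every stage end to end — bin inference from the published
pattern, the selected-clone mutation census and its re-measurement on
synthetic sequences, the EC50 grid fits, noisy-plate bin recovery, the
stepwise mass series, and the cleavage verdicts — then writes its JSON
output:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
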