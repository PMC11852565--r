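---
title: "Methods: from nanobody repertoire to epitope bins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from nanobody repertoire to epitope bins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbscreen)
```

# Overview

`nbscreen` implements the downstream analysis of a nanobody discovery
campaign against SpCas9: a sequence census of the immunized-animal
library, relative affinity estimation by ELISA, epitope binning by
competition ELISA, mass-photometry confirmation that representatives of
each bin bind simultaneously, and a cleavage assay verdict that the
binders do not inhibit the enzyme. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions that were
genuinely open.

# Repertoire census

## Germline assignment

Each clone is aligned against every germline V gene
(`pairwiseAlignment`, global in the germline, local in the clone), with
match 1 / mismatch 0 and affine gap penalties (open 10, extend 1). The
scoring is deliberately plain: percent identity is defined as matches
over alignment columns, so the alignment that maximizes matches is also
the one the identity is measured on, and ties between germlines are
broken by gene name for reproducibility. The J segment is searched only
downstream of the V alignment, and the D segment only in the V–J
junction, with floors (>= 7 matched bases at >= 80% identity) below which
the D call is reported absent — mirroring how short, heavily mutated D
segments are routinely unidentifiable in real repertoires.

Two mutation counts are reported per clone, because they answer different
questions. `v_nt_mutations` counts nucleotide-level differences in the V
alignment (mismatches plus indel columns) — the mutational load of
affinity maturation. `aa_changes` counts residue differences in the
codon-aligned V translation — the protein-level consequence. Neither
bounds the other: two silent hits in one codon can produce a residue
change, and two hits in one codon can produce a single change, so the
package's generator records a position-wise translation comparison as the
ground truth rather than a per-mutation silent/non-silent tally.

## Region annotation

CDR/FR boundaries are transferred from fixed anchors on the winning
germline V translation (an IMGT-like fixed-anchor scheme: CDR1 at 25–33,
CDR2 at 50–58, CDR3 from 96 in the synthetic reference), with CDR3's end
taken from the winning J gene's FR4 anchor. Full numbering-scheme edge
cases (insertions inside CDRs) are out of scope; anchor transfer through
the alignment handles the substitution-dominated variation the campaign
actually shows. All coordinates are 0-based half-open, in memory and in
every output file.

## Lysine census and candidate selection

Chemical biotinylation with NHS esters targets lysines. A candidate is
kept when CDR3 carries at most `max_cdr3_lysines` (default 0) lysines and
the rest of the domain carries enough for efficient labeling. The
published selection rule is stated as "more than 3" lysines outside CDR3,
but the published selected set includes a clone with exactly 3 — the two
are inconsistent. The comparator is therefore exposed
(`selection_criteria(comparator = "at_least" | "strict_greater")`) with
`at_least` as the default, the behavior consistent with the published
table.

## Identity matrix and cladogram

Pairwise global alignments of the protein sequences give percent
identity; the cladogram is neighbor joining on 100 − identity. NJ can
emit tiny negative branch lengths on noisy matrices; these are clamped to
zero. On additive matrices NJ is exact, which the tests verify against a
four-leaf matrix built from known branch lengths.

# Dose–response

The four-parameter logistic `A(x) = bottom + (top − bottom)/(1 +
(EC50/x)^h)` is fit to blank-subtracted absorbances by least squares over
`(bottom, top, log10 EC50, log h)`, a parameterization that keeps EC50
and slope positive without constraints. Initialization is deterministic —
bottom and top from the data range, EC50 at the concentration nearest the
half-range crossing, h = 1 — followed by BFGS and a Nelder–Mead polish,
so fits are reproducible without a seed. Data whose signal span is below
`min_span` (default 0.05 absorbance, about twice a plate's blank noise)
are flagged `no_response` instead of fitted: a flat curve constrains no
parameter. Bottom/top are left unconstrained; the fit reports
`extrapolated` when EC50 falls outside [min dose/10, max dose·10].

Concentrations are stored in nM; mass/volume units are converted with a
per-clone molecular mass (default 14 kDa, a typical nanobody). The
default dose grid is the campaign's plate design: 12 three-fold dilutions
from 80 µg/mL.

The area under the curve is computed on the log10-dose axis. The dilution
series is geometric, so equal weight per dilution step — not per nM —
is the design-consistent choice; the published description does not state
the axis. Negative blank-subtracted values are clamped to zero before
integration because the AUC feeds a ratio statistic that must stay
non-negative; for fitting, negatives are kept (they are informative
noise). With replicates, the fit pools points and the AUC averages
per-replicate areas.

# Epitope binning

For capture clone *c*, every biotinylated analyte's AUC has the AUC of
*c*'s own biotinylated curve subtracted — the residual signal a fully
blocked analyte produces — and is then expressed as a percentage of the
largest corrected AUC. Percentages are clamped to [0, 100]: negative
corrected areas mean the analyte fell below even the self-blocked
baseline, which is noise, not information.

Two normalization denominators are provided. The default is the maximum
corrected AUC within the same capture experiment, which controls plate
effects. The alternative (`reference_auc=`) is the tightest binder's
direct-ELISA area, and it matters in one regime the tests exercise
exhaustively: if *every* analyte shares the capture's epitope, the
in-plate maximum is itself a blocked signal and normalizing to it
fabricates free binders, whereas the direct-ELISA reference keeps all
percentages low. The published description ("percentage of the tightest
binding biotinylated nanobody") does not disambiguate the scope; both
readings are available.

Classification uses two thresholds: same epitope at <= 25% binding,
different at > 60%. The zone between is reported as `indeterminate` and
deliberately contributes no edges — forcing mid-zone values into a bin
would fabricate certainty the data does not contain. Bins are the
connected components of the same-epitope graph, i.e. the transitive
closure of pairwise calls. Pairs called same in one experiment and
different in another stay connected but are flagged as conflicts;
intra-bin pairs never directly assayed are flagged
`inferred_by_transitivity`, since a campaign typically runs only a few
clones as capture.

# Mass photometry

Raw contrasts are converted to kDa by a least-squares line through
protein-standard points. Landing events below 40 kDa are discarded before
fitting: free nanobodies (12–14 kDa) sit below the instrument's detection
floor, and the sub-40 kDa region is dominated by noise.

Mass populations are fit as a univariate Gaussian mixture by EM with
deterministic quantile-spaced initialization, so no seed is needed. The
component count is chosen by BIC over k = 1..`max_k`, disqualifying
solutions with a component weight under 5% or a collapsed (sub-0.5 kDa
sd) component; a fixed `k` can be forced when the species count is known
from the experiment design. A hard resolution limit applies and is worth
stating plainly: two components separated by less than about one peak sd
(e.g. 10 kDa apart at sd 12) are not reliably resolvable from a single
pooled sample at any realistic event count — the likelihood surface is
nearly flat in the split. The stepwise experiment this package models
avoids the limit by design: each incubation state is acquired separately,
each acquisition carries one dominant complex peak, and the 10–20 kDa
per-addition shifts are read across acquisitions
(`stepwise_shifts`), not out of one overlapping mixture.

Peak composition is assigned by enumerating nanobody subsets and
minimizing |antigen + subset mass − peak|; the default tolerance of
±8 kDa sits below a single-nanobody step (10–20 kDa with tags), so
successive occupancy states cannot be merged. Near-equal nanobody masses
can make two subsets' expected masses almost tie; the assignment reports
the best-fitting subset and its residual rather than pretending the
identity of each bound clone is knowable from mass alone.

# Synthetic data and what a green test establishes

Every generator is seeded, reproducible, and returns its ground truth.
The defaults are the campaign's stated world: nine binders partitioned
{C1} / {F9, C7} / {E6, F1, F8, G10, G7, D9}; EC50s at the five published
values (2, 4.5, 6.6, 7.1, 9.1 nM) with the remaining four placed at
18.5/21/37/63.4 nM inside the published 18.5–63.4 nM range so the
described 2-fold (F8 vs E6) and ~3-fold (F1 vs G10) pairs hold; additive
absorbance noise sd 0.02 (a few percent of a ~1.8 top, typical for
endpoint A450 reads); competition blocking as a multiplicative residual
occupancy ε = 0.05 on blocked analytes; the 160/180/190/209 kDa mass
series at sd 12; first-order cleavage with equal rate 0.45/min across
conditions (the binders do not inhibit) sampled at 1, 5, 10, 60 min with
3 replicate lanes and 6% multiplicative intensity noise.

The repertoire generator is substitution-only by default, which keeps the
mutation-count oracle exact; indels are real but rarer, and counting them
(one mutation per affected alignment column) is tested through the
alignment path, not the generator. The competition model is an ε-scaled
occupancy, not a ternary-complex equilibrium: it exercises the statistic,
not plate chemistry. Consequently a green suite establishes that the
estimators recover known truth under the stated noise — it does not
certify performance on plate artifacts (edge effects, drift, hooks) that
the generators do not emulate.

# Numerical conventions

Percentages print at one decimal, rounded half away from zero, matching
the campaign's tables. Ties in germline assignment break by gene name;
bin labels order by size then first member. Degenerate inputs fail loudly
(`untranslatable`, `unassignable`, all-zero lanes) rather than silently:
a screening pipeline should never quietly drop a clone.

# Known limitations

- Germline assignment transfers fixed anchors; it is not a full
  numbering-scheme implementation and will mis-place boundaries for
  clones with large CDR insertions.
- The 4PL fit pools replicates rather than modeling plate random effects.
- Mixture fitting cannot resolve sub-sd mass splits from pooled data (see
  above); design experiments as stepwise acquisitions.
- The inhibition verdict is a bounded-difference test at the observed
  time points, not a rate-constant comparison; it answers the screening
  question ("does the binder visibly slow cleavage?") only.
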