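---
title: "Two-rule WDF gating for malignant-cell screening in body fluids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-rule WDF gating for malignant-cell screening in body fluids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xnbf)
```

## The screening problem

Cytological examination of body-fluid (BF) specimens — pleural effusions,
ascitic fluids, cerebrospinal fluid — is the reference method for detecting
malignant cells, but it is slow and runs in a separate pathology laboratory.
Automated hematology analyzers already measure BF samples on a fluorescence
flow channel (the WDF white-cell differential channel), producing four
signals per cell event:

* **forward scatter** (`fsc`) — cell volume,
* **side scatter** (`ssc`) — internal structure and granularity,
* **side fluorescence** (`sfl`) — nucleic-acid content after
  fluorochrome staining,
* **forward-scatter pulse width** (`fscw`) — the "time of flight" through
  the laser, elevated when doublets or cell clumps pass as one event.

Events whose fluorescence exceeds a cutoff are *high-fluorescence BF*
(HF-BF) cells: mesothelial cells, macrophages, and malignant cells. HF-BF
cells are excluded from the WBC count; the analyzer reports HF-BF# (cells
per µL), HF-BF% (per 100 WBCs, which can exceed 100), and TNC = WBC +
HF-BF#. Remaining WBC events split into PMN (neutrophils + eosinophils,
granular, high side scatter) and MN (lymphocytes + monocytes).

The HF-BF class alone is a poor malignancy marker because benign
macrophages and mesothelial cells dominate it in many effusions. The
algorithm implemented here screens the HF-BF events with two gates that
exploit what distinguishes malignant cells: they clump, they are large,
and they carry more DNA/RNA than normal leukocytes.

## The two-rule model

After normalizing each signal by its channel range (so all gating happens
in the unit hypercube):

* **Rule 1 (Area 1)** on the (`fscw`, `fsc`) plane gates events with pulse
  width and forward scatter above the WBC bulk — aggregated malignant
  clumps with a long time of flight.
* **Rule 2 (Area 2)** on the (`fsc`, `sfl`) plane gates events with
  fluorescence intermediate between WBCs and the typical HF-BF population
  and forward scatter lower than macrophages — isolated malignant cells.

Only HF-BF-labeled events can count toward either rule; an event may count
toward both. A rule is *positive* when its gated-event count reaches
`rule_min_events` **and** the implied concentration (events /
`volume_factor`) reaches `rule_min_conc`. The sample-level call is the OR
of the two rules.

## Parameters and defaults

The vendor's numeric cutoffs and channel scalings are proprietary and
unpublished; the source material defines the gates only pictorially. The
package therefore ships explicit, overridable conventions (normalized
units unless noted):

| parameter | default | meaning |
|---|---|---|
| `hfbf_sfl_cutoff` | 0.62 | WBC / HF-BF fluorescence cutoff (boundary is HF-BF) |
| `debris_fsc_floor` | 0.02 | events below are debris, never counted |
| `pmn_mn_boundary` | ssc ∈ [0.35, 1] × sfl ∈ [0, 0.62] | PMN region among WBC events |
| `area1` | fscw ∈ [0.45, 1] × fsc ∈ [0.35, 1] | Rule 1 clump gate |
| `area2` | fsc ∈ [0.15, 0.55] × sfl ∈ [0.45, 0.75] | Rule 2 isolated-cell gate |
| `rule_min_events` | 10 events | robustness to single-event noise |
| `rule_min_conc` | 10 cells/µL | concentration floor for positivity |
| `volume_factor` | 5 µL | analyzed volume (events → cells/µL) |

All boundaries are inclusive toward the HF-BF / malignant side: a
deterministic, screening-oriented tie rule. Percentages are reported half
away from zero to one decimal, matching how clinical tables print them.
When the WBC count is zero (a regime CSF samples approach) HF-BF% is a
flagged `NA`, never an error. Rule thresholds are conventions chosen to be
robust to single-event noise while remaining sensitive across the HF-BF#
range the packaged study table exhibits; they are not reconstructions of
instrument constants.

Gate membership uses the even-odd (crossing-number) rule with boundary
points counted inside. Gates are arbitrary simple polygons;
self-intersecting or zero-area polygons are rejected at construction.

## The synthetic-data generator

`draw_population()` models each cell population as a truncated correlated
4-variate Gaussian on the unit hypercube (rejection sampling, capped at
1000 rounds — specs are expected to keep ≥ 99.9% of mass inside, so
rejection is cheap). `apply_clumps()` turns `malignant_clump_seed` events
into clump events: a clump of *k* cells (default truncated geometric on
*k* ≥ 2, p = 0.45, capped at 8) multiplies the seed's signals by
`gain^(log2 k)` — i.e., each doubling of clump size applies the per-doubling
gain once (defaults: width ×1.6, forward scatter ×1.25, fluorescence ×1.3),
then clips to the channel range.

The canonical population parameters (`canonical_populations()`) and the
default gate geometry are one versioned convention that co-evolves: WBC
populations sit below the fluorescence cutoff, macrophages/mesothelial
cells are large and strongly fluorescent but outside both rule gates,
isolated malignant cells sit in the Area 2 band, and clump seeds reach
Area 1 once the width gain acts. `canonical_profile()` mixes these into
benign (no malignant fractions) and malignant (20% isolated + 10% clump
seeds) samples of 5000 events each at `volume_factor` 5 µL — event counts
and concentrations comparable to the mid-range of the packaged study table.

What the simulator does *not* emulate: real WDF correlation structure
(unpublished — correlations are user parameters, identity by default),
instrument noise floors, carryover, debris distributions, or the extreme
low-count CSF regime (a 2-cells/µL CSF sample gives too few events for any
event-cloud statistics). Passing recovery tests on synthetic cohorts
therefore demonstrates internal consistency of gating + simulation, not
clinical accuracy; the clinical performance claims rest entirely on the
packaged 92-sample study table.

## The packaged study table and evaluation layer

`load_study_table()` ships the 92-row clinical table (68 PE, 6 AF, 18 CSF;
27 samples cytology-positive at ≥ class IIIb on the Papanicolaou-style
ordinal scale `Negative < I < II < IIb < III < IIIb < IV < V`). Two
arithmetic invariants are enforced on every row at load time — total =
WBC + HF-BF#, and the printed HF-BF% equals the recomputed ratio at one
decimal — so the loader doubles as a transcription regression test.

`evaluate_method()` scores each screening method (the two-rule algorithm,
microscopic WBC differential, microscopic WBC count) against cytology:

```{r}
records <- load_study_table()
evaluate_all_methods(records)
```

`concordance_breakdown()` partitions the 27 cytology-positive samples by
their rule flags:

```{r}
concordance_breakdown(records)
```

Known discrepancies in the source material, preserved deliberately: the
results narrative says nine cytology-positive samples were missed by both
rules, but the table itself contains ten; the percentage printed for the
three Rule-2-only samples (7.40%) is not 3/27; an abstract rounds the
algorithm's specificity to 87.8% where the raw counts (57/65) give 87.7%.
The package always recomputes from the table. Similarly, the published
true-positive/false-negative group sizes for the mean ± SEM comparison
cannot be reconciled with the table under any single-sample exclusion, so
`group_summary()` takes an explicit `exclusions` argument (never applied
silently) and those published means are not used as checks; the group
summary is instead validated by its definitions (partition identity, SEM =
SD/√n, rank-sum equivalence).

### Rank-sum testing

`mann_whitney_u()` computes U from midranks. Exact mode enumerates all
`choose(n1+n2, n1)` group assignments and reports the two-sided tail of
|U − n1·n2/2|; the enumeration stays exact under ties (where the classical
exact distribution does not apply). Approx mode uses the normal
approximation with tie-corrected variance and a 0.5 continuity correction.
Auto mode (the default) picks exact when n1 + n2 ≤ 20 and no tied value
spans both groups. On the study table, the false negatives of the two-rule
algorithm carry significantly fewer HF-BF cells than the true positives —
the main driver of its missed detections.

## Numerical and design choices

* Normalization is linear (signal / channel range), not logarithmic:
  the gate geometry is defined on the linear normalized scale, and log
  display transforms are a plotting concern only.
* Rounding is half away from zero everywhere a percentage is reported,
  because that is how the clinical tables were printed (base R's
  round-half-to-even would disagree on exact .05 boundaries).
* `point_in_gate` ties: boundary inclusive; `classify_events` ties:
  fluorescence exactly at the cutoff is HF-BF; both documented above.
* Degenerate inputs: empty clouds classify to an empty label vector; a
  zero-WBC sample yields `NA` HF-BF%; diagnostic metrics with a zero
  denominator are `NA`-flagged, never errors, so toy inputs remain usable.
* Determinism: every simulator entry point takes a seed; cohort draws use
  child seeds derived from the master seed, so cohorts are reproducible
  bit-for-bit and per-sample draws are independent of list order effects.
* Problem sizes: validation cohorts use 50 samples × 5000 events and the
  membership property checks use 10⁵ random point/polygon pairs — large
  enough for stable binomial margins, small enough to run in seconds.

## Limitations

The gate coordinates are conventions, not recovered instrument constants;
on real FCS exports they must be re-calibrated (via `gating_config()` or a
JSON/YAML config) against the instrument's actual channel scaling. The FCS
reader covers plain list-mode files (versions 2.0–3.1, integer/float/double,
uniform bit width) and rejects anything fancier. The evaluation layer
reports point estimates only — no confidence intervals or ROC analysis —
mirroring the scope of the source study.
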