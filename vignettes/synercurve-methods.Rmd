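---
title: "Methods: AUSC-based synergy scoring and combination-unique DE sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AUSC-based synergy scoring and combination-unique DE sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synercurve)
```

## The scoring model and its assumptions

`synercurve` scores combination synergy for designs where a priming agent
(here an EZH2 inhibitor, given days before) modulates the dose–response of
a secondary agent (panobinostat, a pan-HDAC inhibitor) across a panel of
cell lines. The classical combination-index framework is unusable when many
lines have *no* single-agent response to the priming drug, so the score is
built entirely from the secondary drug's curves:

1. **Media normalization.** Every raw well signal is divided by the mean
   untreated (media-only) control signal of its cell line, per biological
   replicate; replicate-level normalized values are then averaged per dose
   and their SEM retained. Normalizing before averaging keeps the SEM on
   the scale of the reported survival fractions.
2. **Anchor normalization.** Each curve — secondary agent alone, and
   secondary agent after priming — is divided by its own zero-secondary-dose
   value. The anchored curve starts at exactly 1 and carries only *shape*
   information: whatever viability the priming drug removes on its own
   cancels exactly (a property the test suite checks to 1e-12 across
   priming-kill fractions 0–0.8).
3. **AUSC.** The area under each anchored curve is the composite trapezoid
   sum over adjacent dose points.
4. **Score.** `delta_ausc_rel = (AUSC_single − AUSC_combo) / AUSC_single`.

The score assumes (a) multiplicative, roughly symmetric-on-log-scale plate
noise, (b) a monotone dose layout (serial dilution), and (c) that the
zero-secondary-dose wells of the combination arm measure the priming
agent's standalone toxicity faithfully — anchoring amplifies noise in that
single point, which is why lines very sensitive to the priming agent alone
can show exaggerated or even negative scores.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `axis_mode` | `"log10_dose"` | — | serial dilutions are log-spaced, so the log axis weights each dilution step equally; `"index"` is available. For *uniform* dilution ratios the two differ by a constant factor that cancels in `delta_ausc_rel`. |
| `call_threshold` | 0.1 | relative AUSC decrease | reporting convenience only; no biological meaning is attached and it is printed alongside every summary. |
| `clip` | `FALSE` | — | anchored survival above 1 is retained by default because clipping biases the area downward; a clip option exists for exploratory plots. |
| `fdr_max` | 0.05 | — | strict comparison (`< 0.05`); the FDR column is taken as supplied by the upstream DE caller. |
| `fpkm_min` | 1 | FPKM | inclusive (`>= 1`), required of at least one of control/treated, so genes switching on or off are kept. |
| `fc_min` | 2 | linear fold change | `|FC| >= 2` is the standard threshold; 1.5 gives the lenient variant, and both are reported by `run_desets()`. Infinite fold changes (0 FPKM against a positive FPKM) always satisfy the criterion. |

### Numerical and tie-break choices

- The zero-dose point is excluded from log-axis integration (log10(0) is
  undefined); its information is already encoded by the anchoring. Whether
  one also includes it on a linear/index axis is a convention the data do
  not decide, so both axis modes are implemented and the mode is recorded
  in every score.
- The FDR threshold is strict and the FPKM floor inclusive, matching the
  conventional phrasing of the filters.
- A gene passing all thresholds with log2 FC exactly 0 has no direction and
  is excluded with a message (only possible at `fc_min = 1`).
- Duplicate gene identifiers in an input table keep the first occurrence,
  with a warning — deterministic and auditable.
- Cross-set overlaps are direction-agnostic by default (a gene counts as
  shared if present in both sets in either direction); a direction-aware
  mode is available in `overlap()` and `shared_count()` since published
  overlap counts rarely state which convention they use.
- Curves must share an identical dose grid before scoring; no interpolation
  is attempted.

## What the simulators emulate — and what they do not

`simulate_viability_panel()` draws well signals as
`baseline × (1 − pretreat_kill)[combo arm] × Hill(dose; EC50_eff) × exp(ε)`
with `ε ~ N(0, noise_sigma²)`. Synergy is planted as a *potency shift*
(EC50 divided by `potency_shift` in the combination arm of selected lines)
rather than an efficacy change, emulating the left-shift of the secondary
drug's curve that priming produces. Defaults describe the modelled assay:
near-complete kill (`emax = 0.95`), EC50 10 nM and Hill slope 1.5 for the
secondary agent on a two-fold dilution grid 0–80 nM, 5% multiplicative
noise, biological triplicates, priming kill 0.2 and a 4-fold potency shift.
Multiplicative lognormal noise reflects positive, scale-proportional
luminescence readouts.

`simulate_de_tables()` plants disjoint gene blocks — up/down for agent A
(3.5% each), a small agent-B block (0.5% each; the secondary agent alone
perturbs few genes at the doses modelled), a combination-unique block
(15%, split evenly up/down) — and retains 90% of each single agent's
effects in the combination table. These defaults make roughly two thirds of
the combination's filtered genes unique to the combination, the structure
the analysis is designed to detect. Observed log2 fold changes are
`true ± N(0, dispersion)` with `dispersion = 0.25` acting as the per-gene
standard error, so null genes have *exactly* uniform p-values and planted
genes (|log2FC| ≈ 2, i.e. 8 standard errors) are nearly always detected.
Baseline expression is lognormal with median 10 FPKM (`sdlog = 1.2`),
typical of expressed-gene FPKM distributions, so the FPKM ≥ 1 floor
genuinely bites on the low tail. FDR columns use Benjamini–Hochberg.

The simulators do **not** emulate: correlated noise between neighbouring
wells or edge effects; count-level RNA-seq noise (the negative-binomial
mean–variance relation, length biases, isoform switching) — p-values are
generated from a Gaussian test statistic, not from read counts; partial or
dose-dependent effect sizes; or any dependence between the two analysis
tracks. Passing tests therefore demonstrate that the *statistics and set
algebra* are implemented correctly and are well calibrated under the
assumed noise model, not that real plate or sequencing data satisfy that
model.

## Degenerate inputs

Curves need at least two points (two *nonzero*-dose points on the log
axis); anchoring requires a positive zero-dose survival; scoring requires a
positive single-agent AUSC; empty gene sets are valid everywhere
(`persistence_report()` returns `NA` for an empty earlier set rather than
erroring); a panel without combination arms yields an empty, well-formed
result.

## Problem sizes used by the test suite

The suite validates the trapezoid on 1000 random 4–12-point curves against
an independent implementation (1e-12), calibrates the null score on 200
simulated 4-line panels and the planted-synergy detection rate on 200
2-line panels, checks all Venn regions against brute-force enumeration on
500 random 3-set instances, and measures unique-gene recovery on 20
simulated 10 000-gene table trios. These sizes give stable Monte-Carlo
estimates while keeping the default test run short.

## Known limitations

- The score compares two curves on a shared dose grid; unequal grids are
  rejected rather than interpolated.
- `delta_ausc_rel` is unbounded below: a line whose anchored combination
  curve sits *above* the single-agent curve can score arbitrarily negative,
  and strong priming-agent toxicity inflates the variance of the anchor
  point.
- The published supplementary DE tables that accompany the motivating
  dataset are not shipped; the set-algebra pipeline is validated against
  simulated tables with known ground truth and brute-force recomputation
  instead.
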