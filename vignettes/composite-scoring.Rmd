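---
title: "Composite scoring and quality control for predicted protein-protein interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite scoring and quality control for predicted protein-protein interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiscorekit)
```

## The problem

All-against-all interaction screens with AlphaFold-Multimer-class
predictors produce, per candidate complex, five models each carrying
several confidence metrics: the interface-quality machine-learning
**pi-score** (roughly bounded in [−2.63, 2.63]), the predictor's own
**ipTM_pTM** combination in [0, 1], the contact-based **pDockQ** in
[0, 1], and a residue-pair **predicted aligned error** (PAE) matrix in
Ångström. None of these alone separates true from spurious interfaces
reliably: each has its own scale and its own gray zone, and candidates
near any single threshold get misclassified. `ppiscorekit` condenses them
into one interpretable number per candidate and automates the quality
control around the screen.

## The scoring model

For a hetero pair, scoring uses only the **best** of the five models,
ranked by ipTM (ties break to the lowest model index, so selection is
deterministic):

$$\mathrm{iQ} = \frac{\pi + 2.63}{5.26}\cdot 40 \;+\; \mathrm{ipTM\_pTM}\cdot 30 \;+\; \mathrm{pDockQ}\cdot 30$$

For a homo-oligomer of $n$ distinct chain-pair interfaces, each with its
own pi-score (pDockQ is not produced for these jobs):

$$\mathrm{hiQ} = \frac{\bar{\pi} + 2.63}{5.26}\cdot 60 \;+\; \mathrm{ipTM\_pTM}\cdot 40,
\qquad \bar{\pi} = \tfrac{1}{n}\sum_i \pi_i$$

The affine map $(\pi + 2.63)/5.26$ sends pi-score onto [0, 1], so both
composites live on a 0–100 scale and are strictly increasing in every
constituent. The weighting emphasizes pi-score, the constituent that most
directly measures interface quality.

Evaluated at the constituent scores' published individual thresholds
(pi-score 0.05, ipTM_pTM 0.5, pDockQ 0.5):

```{r anchors}
round(compute_iq_score(0.05, 0.5, 0.5), 2)
round(compute_hiq_score(0.05, 0.5), 2)
```

Both anchor values sit just above 50, which motivates the operational
rule: **retain when the composite strictly exceeds 50**. The anchors are
documentation of where the formula puts the constituent thresholds, not
the cutoff itself; the cutoff is a round 50 and is configurable.

### The PAE gate

Composites are only computed for models that pass a PAE gate: the
**minimum** PAE over all inter-chain residue pairs (both orientations of
the asymmetric matrix) must be at or below 10 Å. The choice of the
minimum as aggregate was a genuinely open design point — "inter-chain PAE
below a threshold" does not name a statistic. We gate on the minimum
because a single mutually-confident inter-chain region is what evidences
a physical interface; a median or mean would punish large proteins whose
interface is small relative to their bulk. Both alternatives remain
available (`pae_stat = "median"` / `"mean"`) for sensitivity analysis.
Gate failures keep all their constituent scores in the output table, with
a reason, so near-misses can be audited; they are never silently dropped.

### Numerical choices

* pi-scores outside [−2.63, 2.63] are **clamped** with a warning rather
  than rejected: the upstream score is unbounded in pathological cases,
  and the normalization implies the intended range. ipTM_pTM and pDockQ
  are bounded by construction upstream, so out-of-range values there are
  treated as errors, not noise.
* Retention uses strict `>`; a candidate exactly at the cutoff is
  rejected.
* Best-model ties on ipTM break to the lowest model index.
* Matrix coordinates are 0-based half-open internally; every user-facing
  table is 1-based with the structure file's author numbering.

## Quality control and planning

**Signal peptides.** Secreted proteins are modeled post-translocation:
an annotation table (id, cleavage position — the format a SignalP run
summarizes to) drives trimming, and every downstream stage consumes the
mature sequence. The package deliberately consumes the *table* rather
than invoking the predictor, which keeps it self-contained; organism
class only parameterizes the external call and is therefore ignored here.
Cleavage at or beyond the last residue is an error (an empty mature
sequence is never silently produced), and trimming is idempotent.

**MSA depth.** Alignment depth per query position is the number of rows
with a non-gap residue in that column; A3M lowercase insertion states do
not consume query columns. A protein is **shallow** when its *median*
depth falls below 100 rows — the median because ragged alignment ends
would dominate a mean; 100 rows is a common heuristic for adequate
co-evolutionary signal, and the threshold is exposed
(`depth_threshold`) because it is a heuristic. Shallow proteins are
listed in `shallow_MSA.txt` and their interactions annotated
`unreliable_msa` everywhere downstream — they are **not** excluded, since
exclusion would silently discard discoveries; the flag lets the reader
weigh the evidence.

**Memory-aware planning.** From $n$ mature sequences the planner emits
$\binom{n}{2}$ hetero jobs plus one homo-oligomer job per copy count in
$2..\texttt{max\_copies}$ (default 2: the screening phase asks whether a
protein self-associates at all; higher stoichiometries are a follow-up).
Complexes whose total residue count exceeds the accelerator's capacity go
to `OOM_int.txt` instead of being attempted. Capacity is a
piecewise-linear map through anchor points (8 GB → 1800 residues, 16 →
2700, 24 → 3600, 48 → 5500, 80 → 7200), clamped at the ends; the anchors
are environment-dependent and overridable — the mechanism, not the
constants, is the contract. Job-list lines use `A;B` / `id,count`; the
formatter is pluggable because downstream tools differ in dialect.

## Interface geometry and reporting

Distograms and contact tables are computed from the model structures:
the default representative atom is **Cβ (Cα for glycine) with an 8 Å
cutoff**, the standard contact-prediction convention; `min-heavy` mode
(minimum over heavy-atom pairs) lower-bounds both. Contacts list every
cross-chain pair under the cutoff, distance-ascending, chains in
lexicographic order. By default these are produced only for retained
candidates; `all_structures = TRUE` overrides.

The report bundle contains the score heatmap over all protein pairs
(diagonal: best hiQ; cells that were never scored or failed the gate are
NA, rendered blank — *absent is not zero*), the interaction network
(nodes: proteins with a retained interaction, plus homo-oligomer-only
proteins kept as isolated annotated nodes; edges weighted by iQ; shallow
proteins outlined distinctly), and a JSON run manifest with thresholds
and input checksums. Every figure has a TSV or GraphML sidecar; the
sidecar, not the figure, is the record. The network layout is seeded so
reruns are comparable, and all sidecars are byte-stable across reruns.

## What the toy-cohort generator emulates — and what it does not

`generate_cohort()` writes a complete input bundle: FASTA, signal-peptide
table, A3M alignments with a known gap pattern, two models per job with
score JSONs, PAE JSONs (both upstream JSON dialects, alternating) and
poly-alanine PDB structures whose Cβ atoms sit at designed distances. The
default design uses 7 proteins (10–13 residues mature, plus one
3595-residue protein to exercise memory exclusion), 6 scored hetero pairs
and 4 homo-dimers, with composites on both sides of 50, one PAE-gate
failure, one near-miss, and 4 intended retentions forming network
components of sizes 3, 2 and 1. Alignments are 120 rows (deep) or 5 rows
(shallow) with a 10% gap rate — sizes chosen so the full chain, including
the property suites, runs in seconds while still exercising every rule.

The generator's ground-truth manifest is computed by straight-line
arithmetic kept textually independent of the scoring and geometry
modules, so it can serve as an oracle; it also re-audits its own planted
geometry by brute-force rescan before writing, and refuses contradictory
designs. The toy data emulate formats and decision rules, **not**
biophysics: chains are ideal-geometry poly-alanine (only inter-residue
distances matter downstream), scores are planted rather than predicted,
and PAE matrices are block-structured. Green tests therefore demonstrate
that the bookkeeping, formulas, gates and reports are correct — they say
nothing about the predictive accuracy of the upstream models on real
proteins, which is the predictor's responsibility, not this package's.

## Limitations

* The package trusts its inputs: it never recomputes pi-score, pDockQ,
  ipTM or PAE from structures.
* The benchmark question — how the composite compares with its
  constituents in sensitivity/specificity on reference sets — requires
  external datasets and predictor runs and is out of scope; the property
  suites (monotonicity, range, gate/cutoff semantics) are the package's
  internal evidence.
* Homo-oligomer interface enumeration relies on the upstream score file
  providing one pi-score per distinct interface; interfaces are not
  re-derived from symmetry.
* Mutually exclusive interfaces on a shared partner are left to manual
  inspection of the distograms and contact tables.
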