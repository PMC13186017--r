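---
title: "Phosphosite co-regulation networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphosite co-regulation networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoscoreg)
```

## The problem

Large compendia of human phosphoproteomics experiments report, for thousands
of phosphosites, whether phosphorylation went up or down between an
experimental state and its control. Individual phosphosites on the same
kinase can decode different inputs and drive different outputs, so
protein-level summaries blur the signal. `phoscoreg` asks a site-resolved
question: across many independent comparisons, which phosphosites on *other*
proteins (PsOPs) consistently move with — or against — each major phosphosite
of a target protein?

The package operationalizes that question as a pipeline over a long-format
compendium in which one row is one phosphosite observation in one
comparison, identified by publication (PMID), dataset, and condition. The
condition — not the dataset — is the atomic comparison unit, because one
dataset can contain several distinct comparisons.

## Quality filtering and direction calling

Only Class I sites are analyzed: localization probability ≥ 0.75 and
ambiguity score (A-score) ≥ 13. Profiling sources frequently omit the
A-score, so a missing A-score passes the gate by default; `filter_config(strict_ascore = TRUE)`
rejects such rows instead. We use ≥ 13 (not > 13) as the A-score comparison;
both conventions circulate in curation practice and the flag makes the
stricter one available.

A differential observation is called:

* **Up** if fold change ≥ 1.3 and p < 0.05,
* **Down** if fold change ≤ 0.76 and p < 0.05,
* **Unchanged** otherwise (including significant fold changes inside the
  dead zone, and missing p-values).

Fold changes are linear ratios; log2-scale inputs are declared either
globally (`filter_config(log2_fc = TRUE)`) or per row (`log2_flag` column)
and exponentiated on read. When several peptides report the same site in the
same condition, any significant call dominates Unchanged, and an Up/Down
conflict yields **Ambiguous**, which is excluded from all event counting —
a deliberate refusal to guess when the underlying evidence disagrees.

## Co-occurrence and co-regulation statistics

For a pair of sites, only conditions where *both* carry an Up or Down call
contribute, giving four event counts: both up (`n_uu`), both down (`n_dd`),
and the two discordant combinations (`n_ud`, `n_du`). Two ratios summarize
them:

* positive co-regulation ratio = (n_uu + n_dd) / (n_ud + n_du),
* negative co-regulation ratio = its reciprocal,

with `Inf` when the denominator is empty and `NA` when no event exists. For
the within-protein co-occurrence heatmap we report a bounded concordance
score, (concordant − discordant) / total ∈ [−1, 1]. The field does not share
a single convention for what a co-occurrence heatmap cell encodes; we chose
this score for boundedness and sign interpretability, and always export the
raw counts beside it so any alternative statistic can be recomputed.

For target-site/PsOP pairs the same four counts, written `n_UmUo`, `n_UmDo`,
`n_DmUo`, `n_DmDo` (m = target site, o = PsOP), form a 2×2 contingency table
of target direction × PsOP direction. A pair is a **high-confidence**
co-regulation when all gates pass:

1. two-sided Fisher's exact test p < 0.05 (raw, not adjusted — an optional
   Benjamini–Hochberg flag exists for users who prefer FDR control);
2. sign-appropriate ratio ≥ 0.15;
3. concordant events strictly outnumber discordant ones (for a positive
   call; mirrored for negative);
4. events observed in ≥ 2 distinct conditions and ≥ 2 distinct publications.

The contingency-table construction and the two-sidedness are this package's
choices: the test itself carries no directional claim, and the sign comes
from count dominance. Gate 3 exists because a 0.15 ratio threshold is, taken
literally, permissive — it admits pairs with nearly seven-fold more
discordance than concordance — so dominance prevents a mostly-discordant
pair from ever being called positive. Pairs with an infinite ratio (zero
discordant events) pass gate 2: perfect concordance is the strongest
evidence, and gate 4 suppresses single-observation artifacts. Evidence
counts tally all informative events by default; a strict mode counts only
sign-supporting ones.

The exact test is computed by hypergeometric enumeration: all tables with
the observed margins whose point probability does not exceed the observed
table's (relative tolerance 1e-7, the standard guard against ties lost to
floating point) are summed. For example the table [[5,0],[0,5]] gives
p = 2/252 ≈ 0.0079 and [[3,0],[0,3]] gives p = 2/20 = 0.1 — six concordant
conditions split 3/3 are *not* enough for significance, which is why the
evidence gates alone do not drive calls.

## Role stratification and networks

High-confidence PsOPs are annotated against five flat-file resource kinds —
experimentally validated kinase–substrate edges, predicted kinase→site
edges, undirected protein–protein interactions, and kinase/phosphatase gene
lists — yielding the five functional classes: upstream kinase (of the
specific target site when the record names one), co-regulated kinase,
phosphatase, binary interactor, and downstream substrate. Resources are
consumed as versioned local snapshots, never live API queries, so a run is
reproducible; the same alias map normalizes symbols on both sides of every
match. A PsOP may hold several roles at once — kinases that also bind the
target are reported as both — and sharing across the three major sites is
partitioned into disjoint core / pairwise / site-exclusive tiers.

The assembled network has phosphosites as nodes and signed high-confidence
pairs as edges (FET p, ratio, and evidence counts as edge attributes; roles
aggregated per node). Every role-stratified view is a filter of this single
graph. Exports are GraphML, SIF (`coreg_pos` / `coreg_neg` relation tokens)
with sidecar attribute TSVs, and plain node/edge tables; outputs are sorted
and timestamp-free, so identical inputs give byte-identical files.

## The synthetic compendium generator

Real compendia cannot be redistributed, so the package ships a generator
that emulates their statistical structure with known ground truth. Defaults,
chosen once as a realistic mid-size benchmark:

| parameter | default | meaning |
|---|---|---|
| `n_studies` | 10 | studies, each with its own PMID |
| `conditions_per_study` | 4 | comparisons per study |
| `target_sites` | 3 | target phosphosites sharing one direction process |
| `n_pos_partners`, `n_neg_partners` | 20, 20 | planted partners |
| `n_background` | 40 | independent null PsOPs |
| `concordance` | 1.0 | probability a partner copies (or flips) the target |
| `detect_prob` | 0.9 | per-condition measurement probability |
| `p_target_informative` | 0.8 | probability the target is changed at all |
| `p_up` | 0.5 | Up probability given informative |
| `frac_low_quality` | 0.05 | rows drawn below the Class-I threshold |

One direction is drawn per condition and shared by all target sites,
mirroring the tightly coupled site axes seen in real kinases; planted
partners copy (positive) or mirror (negative) it with probability
`concordance`, and are Unchanged when the target is. Up fold changes are
log-uniform on [1.5, 4] and Down on [0.25, 0.67] — deliberately clear of the
1.3/0.76 call boundaries so planted intent is unambiguous (a
`boundary_stress` flag generates boundary-exact rows for testing the
thresholds themselves); significant p-values are uniform on (0, 0.01] and
unchanged ones on [0.2, 1]. Each study's own PMID makes the two-publication
gate genuinely binding: a single-study compendium can never produce a
high-confidence call.

What the generator does *not* emulate: correlated missingness, batch
effects beyond study structure, peptide-level quantification, multiply
phosphorylated peptides (assumed pre-resolved in curated input), or
isoform coordinate ambiguity. Passing recovery benchmarks therefore
demonstrates correctness of the statistical machinery under the stated
model, not robustness to every pathology of real compendia.

## Calibration and recovery benchmarks

Two standing checks use the generator:

* **Null calibration** — with no planted partners, background directions are
  independent of the target, so every (target site, PsOP) pair is null. The
  fraction passing the full gate, pooled over 17 generated compendia
  (2,040 pairs), stays below 0.05 plus three binomial standard errors;
  Fisher's exact test is conservative and the stacked gates push the
  realized rate to roughly 0.02–0.03.
* **Planted recovery** — at concordance 1.0 with the default design, recall
  and precision for both signs exceed 0.95. Because the three per-site tests
  of one null PsOP are almost perfectly dependent (all target sites share
  one direction process), false positives arrive in clusters and single-run
  precision is Poisson-noisy; the reported metrics are therefore
  micro-averaged over five independently seeded compendia, the standard
  stable estimator for small-count precision.

These problem sizes (a few thousand pairs, seconds of runtime) were chosen
to make the checks routine to run; scaling `n_studies` or `n_background` up
tightens the Monte-Carlo intervals without changing the logic.

## Numerical and interface choices

* Sentinels: undefined ratios are `NA`, empty-denominator ratios are `Inf`;
  an all-zero contingency table has no FET p (`NA`) and the pair is skipped.
* Tie-breaks: major-site selection ranks by combined profile + differential
  recurrence (configurable to differential-only) with ascending position as
  the deterministic tie-break.
* Degenerate inputs: empty files yield empty results with warnings; schema
  violations and unparseable numbers are errors naming the column and data
  row; a pipeline stage failure aborts naming the stage.
* All randomness flows from explicit seeds; the analysis path is seed-free.
* The command-line entry point (`inst/cli/phoscoreg`, subcommands `run-all`
  and `simulate`) is a thin wrapper; the exported functions are the primary
  interface, and the remaining pipeline stages are invoked through them.

## Limitations

Co-regulation is correlation across heterogeneous studies: it cannot by
itself establish direct kinase–substrate relationships, direction of
causality, or shared upstream drivers, and compendia skew toward
proliferative cancer models. The gates control false positives under
independence but cannot correct systematic biases in which conditions get
published. Site identity assumes canonical-sequence coordinates; isoform
positions must be mapped upstream.
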