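---
title: "Quantifying lysine acylation and drug attenuation with acylsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lysine acylation and drug attenuation with acylsite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lysine succinylation and malonylation are acyl modifications fed by the
central-metabolism intermediates succinyl-CoA and malonyl-CoA.  In label-free
shotgun proteomics they are detected as mass shifts of +100.016 Da (C4H4O3)
and +86.000 Da (C3H2O3) on lysine side chains of tryptic peptides.  `acylsite`
covers the downstream half of such an experiment: it starts from the
peptide-level quantitation table that identification/alignment software
exports (one row per peptide ion with per-sample normalized abundances) and
ends with differential modified peptides, protein-level direction summaries,
a graded classification of how far a drug co-treatment pulls perturbed sites
back toward control levels, and pathway over-representation.

The motivating experimental design is a cell-culture insult/rescue study:
two vehicle control groups (different solvents), an NMDA-receptor-antagonist
insult group (MK-801), and a co-treatment group in which an antipsychotic is
added on top of the insult.  Everything upstream of the exported table —
spectra, alignment, identification — is out of scope; the package consumes
the table and never re-scores identifications.

## Input conventions

A peptide table carries six metadata columns (`sequence`, `modifications`,
`charge`, `score`, `mass_error_ppm`, `accession`) followed by one abundance
column per sample.  Modifications are written `PTMName(K12)` and separated
by semicolons, a convention close to common vendor exports while remaining
unambiguous.  Missing abundance cells are zero-filled with a warning —
alignment software emits zeros for unmatched features — and a strict mode
rejects them instead.  Nothing is silently dropped: every row either parses
or is reported with its row index.

Protein sequences come from FASTA (UniProt `sp|ACC|NAME` headers yield
`ACC`), gene sets from GMT, and the sample-to-group mapping from a design
CSV whose optional `role` column declares which groups act as `vehicle1`,
`vehicle2`, `model`, and `treatment`.

## Filtering rules

Peptides are kept when `|mass_error_ppm| < 20` and the number of tryptic
missed cleavages is at most one.  The mass-error rule uses the absolute
value because exports sign their errors.  Missed cleavages are counted with
two conventions: an acyl-modified lysine blocks tryptic cleavage and is not
counted, and K/R followed by proline is not a cleavage site (the standard
tryptic exception, controllable by a flag since upstream tools differ).  The
C-terminal residue is never a missed cleavage.  `filter_peptides()` returns
both partitions so that kept plus rejected always reconstructs the input,
each rejection labeled `mass_error` or `missed_cleavages`.

## Quantitation

`normalize_total()` equalizes column sums to their grand mean; it exists for
raw or simulated tables and should be skipped for tables that the upstream
software already normalized (the simulator emits planted means directly, so
the bundled examples run with `normalize = FALSE`).  Protein-level relative
abundance uses Hi-N with N = 3: for each protein the three peptides with the
highest mean abundance across all samples are fixed once, and the protein's
value per sample is their mean in that sample.  Ranking across all samples —
rather than re-selecting per sample — keeps the peptide set constant so
ratios between samples stay comparable.  Ties are broken by identification
score, then sequence, then row order, making the result invariant to row
permutations.  Acyl-modified peptides are excluded from protein quantitation
by default because their intensity tracks site stoichiometry rather than
protein amount; a flag-free workaround is to pass `features = "all"`-style
subsets explicitly.  With N at least the number of peptides, Hi-N reduces
exactly to the plain mean — a limit the tests exercise.

## Differential analysis

Each acyl-modified peptide is tested across all design groups with a
classical one-way fixed-effects ANOVA; p-values come from the F distribution
with (k−1, n−k) degrees of freedom.  The test runs on `log2(abundance + 1)`
by default, the standard variance-stabilizing choice for label-free
intensities; a linear-scale option is retained.  Degenerate rows are
resolved explicitly: zero within-group variance gives p = 1 when the group
means agree and p = 0 (with a warning) when they do not, which makes the
zero-noise simulator limit exact.  Significance is `p <= 0.05` on the raw
p-value — mirroring the "ANOVA at 5%" reporting convention of this kind of
study — while BH q-values are reported alongside for readers who want
FDR-controlled lists.  Direction is the sign of the non-reference group
means' average minus the reference (vehicle) mean; proteins whose
significant sites disagree in direction are labeled `Both`.

## The attenuation classifier

The co-treatment question is: how far does the antipsychotic pull an
MK-801-perturbed site back toward control?  The procedure is deliberately
simple and threshold-based:

1. **Vehicle concordance.** Only features whose two vehicle means differ by
   at most 10% enter.  "Within 10% of each other" is read as the symmetric
   relative difference `|v1 − v2| / mean(v1, v2)`, which avoids depending on
   the order of the vehicles.
2. **Baseline.** The average of the two vehicle means.
3. **Severity.** The model group's signed fractional deviation from
   baseline, in either direction: none (≤10%), mild (10–25%], moderate
   (25–50%], severe (>50%).  Exact boundary values fall in the milder
   class ("dysregulated by 10%" is read as strictly exceeding).
4. **Attenuation.** A dysregulated site is attenuated when the co-treatment
   deviation returns back over the threshold its severity crossed
   (`|treated| < 0.10/0.25/0.50` for mild/moderate/severe) *and* moves
   toward control (`|treated| < |model|`).  Overshoot past control still
   counts if its magnitude lands within a band — the rule is
   direction-agnostic throughout.
5. **Residual band and asterisks.** Attenuated sites land in `lt10`,
   `10to25`, or `25to50` by `|treated|`, and earn one asterisk per
   additional threshold passed on the way back:
   `asterisks = severity index − residual index`.  `**` therefore marks
   exactly the severe (>±50%) disturbances that return to within ±10% of
   control.

The ANOVA filter is *not* applied before classification by default — the
procedure is purely rule-based — but `anova_filter = TRUE` composes the two.
Deviations are computed on linear-scale group means because the bands are
percent changes of quantitation scores, not log-fold changes.  Proteins
contributing more than one attenuated peptide are flagged
(`multi_peptide`), mirroring the footnote convention of reporting a gene
once with a marker.

The classifier is verified two independent ways: against a separately coded
scalar truth table on a dense grid of deviation pairs over [−1, 1]², and
via monotonicity/symmetry properties (sign-flip invariance; shrinking the
residual never removes attenuation or asterisks).

## Over-representation

`enrich()` computes the exact hypergeometric upper tail (via `phyper`,
cross-checked in the tests against exhaustive combinatorial enumeration for
every universe up to N = 12) and BH-adjusts across the tested sets.  A set
is reported when FDR ≤ 1%, p ≤ 0.01, and at least 5 gene names of the set
are found — the last rule is read as overlap `k < 5`, not set size, because
the reported dot sizes count gene names found.  The background defaults to
the proteins quantified in the experiment rather than the whole annotation:
the question is whether the dysregulated subset is unusual among what was
measured.  A GMT-universe background is available by passing it explicitly.
`dotplot_export()` collects per-comparison results into a long table and a
dot plot (size = overlap, color = FDR).

## The synthetic-data generator

Real inputs for this kind of study require commercial identification
software, so the package ships a generator that emulates the statistical
structure the analysis assumes, with known truth:

* **Design.** Always two vehicle groups plus model and treatment, 3
  replicates each by default.
* **Proteins and peptides.** 500 proteins of 4–10 tryptic peptides; peptide
  bodies avoid K/R/P so each peptide has exactly the missed-cleavage count
  the construction intends (zero), and modified peptides place one acyl
  mark on an internal lysine.
* **Intensities.** Baselines are log-uniform over four decades (typical LFQ
  dynamic range); observed abundances are planted means times
  `2^N(0, sigma)` with `sigma = 0.1` on the log2 scale, i.e. roughly 7%
  multiplicative noise per observation.
* **Planted effects.** 7% of peptides are modified (matching the mid-single
  digit percentages such experiments report); 10% of modified sites get a
  discordant vehicle pair (gap planted strictly above the 10% tolerance);
  of the concordant sites 30% are dysregulated, split evenly across the
  mild/moderate/severe bands with deviations drawn uniformly inside the
  band but at least 0.02 from each boundary, so recovery tests measure the
  rules rather than coin-flips at the thresholds; severe deviations extend
  to 100% (about the upper range of fold changes such data show).  Half of
  the dysregulated sites are attenuated, with residual bands drawn evenly
  among those feasible for the severity.  Non-dysregulated concordant
  sites have no planted effect, and concordant vehicle pairs are planted
  identical, so "planted differential" means exactly "some planted group
  difference exists".
* **Truth labels** equal the classifier applied to the noiseless planted
  means by construction, which the tests verify; at `sigma = 0` the whole
  pipeline reproduces them exactly.

What the generator does **not** model: retention-time alignment artifacts,
missing-not-at-random dropout, correlated peptide noise within a protein,
charge-state duplication, or interference between co-eluting features.
Passing recovery tests therefore demonstrates the correctness of the rules
and their noise robustness under idealized LFQ noise, not performance on
raw instrument output.

At the default conditions the severity-band accuracy is about 0.95 and the
precision of `**` calls is high but estimated from few sites — the planted
rates yield only a handful of severe-to-within-10% sites per run — so that
metric is intrinsically variable between seeds; the fixed-seed checks in the
test suite state the conditions they run under.

## Numerical and design choices

* Band boundaries: severity strictly exceeds its threshold; residual is
  strictly below.  Both routes of every boundary comparison are exercised
  in tests with bit-identical inputs to avoid floating-point ambiguity.
* The degenerate-variance ANOVA conventions (p ∈ {0, 1}) make zero-noise
  simulations exact instead of NaN.
* Problem sizes in tests and the acceptance script (500 proteins, 1000
  null features, 201×201 grids, universes to N = 12) were chosen so the
  whole suite runs in about a minute while keeping every estimate's
  sampling error well inside the asserted margins.
* The missed-cleavage KP exception defaults to on; upstream tools disagree
  on it, so it is a flag.
* Whether the original Hi-N implementations include modified peptides is
  not documented; excluding them is the defensible default for PTM work
  and the choice is localized in one place in the pipeline.

## Limitations

No stoichiometry (modified/unmodified occupancy) analysis, no site
localization scoring, no mixed models or batch correction, no raw-spectrum
handling.  The enrichment background cannot reproduce any specific web
service's internal universe; results are comparable within a run of this
package, not across tools.
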