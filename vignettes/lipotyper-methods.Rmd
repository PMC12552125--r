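---
title: "Methods: blank filtering, lipotype quantification and differential statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blank filtering, lipotype quantification and differential statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipotyper)
```

# Scope and model

`lipotyper` analyzes species-level concentration tables from quantitative
shotgun lipidomics platforms (Lipidyzer-style direct-infusion DMS panels
processed by the Shotgun Lipidomics Assistant). The input contract is a wide
matrix of non-negative concentrations — rows are lipid species in LipidMaps
shorthand, columns are biological, process-blank and QC samples — plus a
metadata sheet with one row per sample carrying a sample type and any number
of grouping variables. Everything downstream operates on this pair.

The pipeline has five analysis stages:

1. **Blank filtering.** A species must reach at least `blank_fold` (default
   2) times its blank background in at least `global_fraction` (default 80%)
   of all biological samples. The background is, per species, the mean over
   blank samples (a `max` option exists for stringency; missing blank values
   count as 0, so a species absent from the blanks is kept wherever it was
   measured). A species failing globally is *reintroduced* if it reaches the
   same intensity criterion in at least `group_fraction` (default 60%) of
   the samples of one experimental group, where groups are formed by
   concatenating all grouping variables (separator `|`, declared order).
   Both boundaries are closed ("at least"). Fractions are computed over
   biological samples only: blanks cannot contain species by definition and
   QCs are pooled material. Missing values are never imputed at any stage.
2. **Class quantification.** Species sum into the 16-class registry (CE,
   CER, DCER, HCER, LCER, DG, FFA, LPC, LPE, PC, PE, PG, PI, PS, SM, TG);
   missing values count as absent (0) in sums but stay missing for
   species-level statistics. Percent-of-total uses one shared denominator —
   the sum of all retained species in a sample — so class percents equal the
   sum of their member-species percents and compositions are invariant to
   per-sample global scaling (dilution, input amount).
3. **Saturation profiles.** Within the TG class, the CE class, or the pooled
   glycerophospholipids (PC, PE, PG, PI, PS, LPC, LPE), species
   concentrations are summed per number of double bonds in the sum
   composition, normalized over total lipid, and expressed as fold change
   over the mean of the control samples. Control-sample fold changes
   therefore average exactly 1 per bin, by construction.
4. **Differential statistics.** Class- and species-level tests are run on
   percent-of-total values (not fold changes), two-sided, with
   Benjamini–Hochberg correction applied separately within the class family
   and the species family of each comparison. A raw-concentration mode
   exists behind `scale_stats = "raw"`.
5. **Lipotype PCA.** Principal components of samples on species
   percent-of-total values; features with missing values are excluded rather
   than imputed, and component signs are fixed (largest-|loading| feature
   positive) for reproducibility.

# Nomenclature

Shorthand names are parsed as a class token plus `carbons:double_bonds`
chains joined by `_` (sn-position unknown) or `/` (known). Class tokens are
case-insensitive; the common dialect synonyms TAG, DAG, FA, HexCER, LacCER
and dhCER map onto the registry codes. The canonical form sorts chains
ascending by (carbons, double bonds), which makes canonical names safe join
keys: two files listing `TG 16:0_18:1_18:2` and `TG 18:2_16:0_18:1` collide
loudly instead of silently duplicating a species.

The registry is fixed at 16 classes. The panel's published figure set names
15 of them; PI — a standard class on this platform — completes the stated
16. Ether/oxygen-modified species (`O-`, `P-`) are rejected with a clear
error: the targeted panel does not report them, and passing them through
silently would corrupt sum-composition binning.

# Statistical choices

**Test selection.** The published analyses use "two-sided t-test or
Mann–Whitney U-test" (paired variants for within-experiment designs)
without stating a selection rule. The rule here is a Shapiro–Wilk normality
gate at α = 0.05 on each group (or on paired differences): any rejection —
or a degenerate constant group, where Shapiro–Wilk is undefined — selects
the rank test. A forced-test override (`test =` `"t"`, `"mwu"`,
`"paired-t"`, `"wilcoxon"`) exists for reproducing specific figures. The t
is Welch's (unpooled variance); the Mann–Whitney uses the exact null
distribution for groups of ≤ 8 without ties and the tie-corrected normal
approximation with continuity correction otherwise.

**Multiplicity.** BH is the hand-implemented step-up
q(i) = min over j ≥ i of p(j)·m/j, capped at 1. It is verified in the test
suite both against `stats::p.adjust` and against the brute-force reject-set
definition over all α — two independent routes.

**Experiment aggregation.** When wells nest within independent experiments
(`replicate_id`), `aggregate = "experiment"` averages wells per experiment
first and tests the per-experiment means, matching the figure-legend
convention of testing means per experiment; paired tests then pair
experiments across groups by `replicate_id`.

**Numerical notes.** Zeros in input tables are measured values (below
detection), not missing — the blank filter depends on this. Fold changes
use no pseudocount by default (`epsilon` is available); features whose
control mean is 0 are reported missing and flagged rather than fabricated.
Z-scores use the sample (n−1) standard deviation — appropriate for small
well counts — and constant features z-score to 0 with a flag. Conservation
identities (class sums vs species sums) hold to floating-point summation
order, i.e. relative 1e−12, not bitwise: summing per class and then across
classes associates additions differently than summing species in row order.

# The synthetic generator

Real cell-pellet lipidomes for this platform are not redistributable at
desk scale, so the package ships a generator whose outputs exercise every
pipeline path. **What it emulates:** cell-type lipotype structure (three
templates over the 16 classes whose orderings follow the published
qualitative profile of iPS cell-derived neurons, astrocytes and microglia —
e.g. PC/PE dominant everywhere, astrocyte-maximal CE and DG,
microglia-maximal SM/TG/FFA/PS, neuron-maximal CER/LPC/LPE), multiplicative
log-normal species noise (concentrations are positive and MS variability is
proportional; σ² = log(1 + cv²), default cv 0.2), per-sample and
per-experiment global scale factors (which cancel under percent-of-total,
as pipetting/input variation does), log-normal blank background at a set
fraction of typical signal (default 5%), ≥ 2 blanks and ≥ 1 QC per run,
experiment nesting via `replicate_id`, and injectable effects (per-class,
per-double-bond-window, or per-species multipliers applied to one group).

**What the absolute numbers are NOT:** the class fractions, species rosters
(~1,100 names over realistic fatty-acyl grids) and effect sizes are free
synthetic parameters, not measurements; every bundle manifest labels the
data as synthetic. A green simulation-based test establishes that the
*pipeline computes its quantities correctly under the stated noise model* —
it says nothing about instrument performance, isotope correction, batch
drift or real biological effect sizes, none of which are modeled.

Two generator features exist purely to exercise the blank filter:
`low_fraction` (default 5%) of species are drawn at blank level everywhere
(these get removed), and `groupwise_fraction` (default 2%) are at blank
level in all but the last group (these get reintroduced). The second is by
construction a real group difference, so null-calibration and
effect-recovery studies run with `groupwise_fraction = 0`.

**Effect defaults.** Multipliers are chosen to be detectable at n = 6 per
arm under the default noise: CE ×1.5 (all species), TG ×2.0 restricted to
saturated/monounsaturated (db ≤ 1) and highly polyunsaturated (db > 5)
species, SM ×0.7 for the ApoE4-like effect; CE ×0.4, TG ×0.5, saturated
phospholipids ×1.6, LacCER ×1.8, HexCER ×1.6 for the reactive-astrocyte
effect. The TG value is 2.0 rather than something milder because the effect
touches only ~17% of TG class weight: power analysis of the generator
showed a ×1.4 default gives a class-level log2FC of ~0.09 against a
seed-to-seed standard error of ~0.05 — not reliably detectable, violating
the stated detectability requirement.

Note one compositional subtlety the generator makes visible: injecting
×1.5 on all CE species yields a class-level percent-of-total log2FC
slightly *below* log2 1.5 ≈ 0.585 (typically ≈ 0.53 with the astrocyte
template), because raising CE also raises total lipid. This is a property
of compositional data, not an estimator bias, and the recovery tolerance
(±0.15) accommodates it.

`species_per_class` thins class rosters for Monte-Carlo runtime; thinning
is stratified over double-bond bins so the saturation tails (db ≤ 1, db >
5) survive — a top-weight-only rule would silently delete the very species
the effects target.

# Degenerate inputs and tie-breaks

- No blanks → validation warns, filtering errors (`no_blank_error`).
- No grouping variables → a single group `"all"`; the reintroduction rule
  then coincides with a 60% global rule.
- A species tied exactly at a fraction boundary (0.8, 0.6) passes.
- Features with < 3 usable values per group are skipped and reported, not
  tested.
- PCA excludes features with missing values; with `scale = TRUE`
  zero-variance features are dropped before scaling.
- Identical groups give p = 1 and log2FC = 0 (a zero-variance t would be
  NaN).

# Known limitations

- The parser covers the targeted DMS panel's dialect, not the full LIPID
  MAPS ontology (no ether/oxygen modifiers, hydroxylation, sn-stereo).
- The "phospholipid" saturation pool excludes SM by glycerophospholipid
  definition; `include_sm = TRUE` switches this, as the published pooling
  is not explicit on the point.
- Whether QC samples belong in the filter denominators is not documented
  for the original pipeline; biological-only is assumed and parameterized.
- The single published robust-regression outlier exclusion is out of scope;
  no outlier removal is performed.
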