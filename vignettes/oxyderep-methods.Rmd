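---
title: "Methods: accurate-mass dereplication and 16S mutation scanning under oxidative stress"
author: "oxyderep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accurate-mass dereplication and 16S mutation scanning under oxidative stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyderep)
```

## The experimental system

The package analyses data from a cultivation design in which actinobacterial
strains (high-GC producers such as *Streptomyces* and *Rhodococcus*) are grown
in liquid culture under three aeration regimes — natural aeration (`C`),
elevated dissolved oxygen (`O2`), and elevated oxygen plus daily ozonation
(`O3`) — and sampled weekly for up to twelve weeks. Each sampling yields two
extract fractions (`biomass` and `cultural_liquid`) which are profiled by
high-resolution LC-MS, screened for radical-scavenging (DPPH) and antibiotic
(disk diffusion) activity, and, in parallel, the strains' 16S rRNA gene is
re-sequenced weekly to look for oxidative-stress mutations. The package
implements the computational side of that workflow: identifying metabolites
by accurate mass, finding metabolites whose synthesis is condition-dependent,
encoding the bioassays, and calling and localizing 16S substitutions.

## Accurate-mass dereplication

Dereplication assigns known-compound identities to observed neutral
monoisotopic masses by matching against a natural-product library. A feature
with observed mass $m$ matches a library record with mass $\mu$ only when,
simultaneously,

$$|m - \mu| < 0.001\ \mathrm{Da}
  \quad\text{and}\quad
  \frac{|m - \mu|}{\mu} \times 10^6 < 10\ \mathrm{ppm},$$

and the record's biological source (producing genus, compared
case-insensitively) equals the queried strain's genus. Both bounds are
strict: boundary-equal differences are rejected, and the two tolerances are
a conjunction, not an either/or — at low masses the ppm bound is the binding
constraint, at high masses the Dalton bound is. The ppm denominator is the
*library* mass: the tolerance is a property of the library assignment, and at
these masses the difference against an observed-mass denominator is far below
rounding. Multiple passing records are all reported, ranked by absolute ppm
error; single-identity reporting corresponds to rank 1.

Monoisotopic masses are computed from Hill-notation formulas with a bundled
element table (C exactly 12, H 1.00782503207, N 14.0030740052,
O 15.9949146221, ...). Adduct m/z arithmetic uses electron-corrected shifts
(`[M+H]+` adds the proton mass 1.00727646688 Da, `[M+Na]+` adds Na minus an
electron, and so on): the sub-mDa electron term matters at a 0.001 Da
tolerance. The default positive-mode set is `[M+H]+`, `[M+Na]+`, `[M+NH4]+`,
`[M+K]+`, editable as a CSV resource. Matching operates on neutral
(deconvoluted) masses by default, since that is how high-resolution feature
tables report molecular mass; `mz_mode = TRUE` instead tries every adduct on
raw m/z values.

A note on residual errors: for the formula-assignable metabolites in the
bundled library, the computed monoisotopic masses sit within 1 ppm of the
observed masses they are matched to (e.g. desferrioxamine E, C27H48N6O9,
computed 600.348277 Da against an observed 600.3486 Da, +0.54 ppm). The
sub-0.001 ppm discrepancies between such residuals and those printed by
commercial dictionaries reflect the dictionaries' internal mass conventions,
which are not reproducible from public information; the bundled library
stores literature masses verbatim for records without a trustworthy formula
and computes masses from formulas otherwise.

The bundled reference library is an openly redistributable ~30-record
fixture (named actinobacterial products plus clearly labelled synthetic
decoys), not a replacement for a comprehensive commercial dictionary; on
real data the library CSV/JSON should point at whatever licensed resource is
available.

## Feature alignment and the presence matrix

Cross-sample comparison requires matching the "same" feature across runs.
`align_features()` uses greedy single-pass centroid clustering: features are
sorted by mass (then RT, then sample id, making the result independent of
input row order), and each feature joins the nearest existing cluster within
both tolerances that does not already contain a member from the same sample,
ties broken by smaller mass gap then smaller RT gap; consensus values are
member medians. Greedy clustering was chosen over density-based methods for
determinism and auditability: every assignment is explainable by two
distances. Defaults are 5 ppm and 0.2 min, appropriate for a
high-resolution Q-TOF over an 18-minute gradient; for synthetic data
generated with 2 ppm mass noise and 0.05 min RT jitter the tests use 10 ppm
and 0.5 min (roughly ten jitter SDs), which makes cluster splits — the one
failure mode that could corrupt downstream presence logic — statistically
negligible.

The presence matrix is boolean: a cluster is present in a designed sample
when a member feature from that sample exceeds the intensity floor. The
floor defaults to 0 (any detection counts) because the study design treats
detection, not abundance, as the signal; it is configurable for noisier
instruments. Designed samples without any data yield all-false columns plus
a warning rather than an error, so incomplete uploads fail loudly but not
fatally.

Two detectors operate on the matrix. `detect_only_experimental()` returns
clusters with zero control-column presence and at least one experimental
presence — the presence-level meaning of "synthesized only under
experimental conditions". `induced_in_window()` returns clusters whose
consensus RT lies in a window (the late-eluting 10.6–17 min region is where
induction concentrates in this system) and whose experimental presence count
strictly exceeds the control count. Induction is deliberately defined on
presence counts, not intensities: the upstream data model is qualitative,
and an intensity-based variant would require normalization machinery that is
out of scope.

## Bioassay encoding

The DPPH readout is colorimetric (pink-to-yellow at 517 nm). The package
encodes it quantitatively as the scavenging fraction
$1 - A_{\text{sample}}/A_{\text{control}}$ with a configurable positivity
threshold defaulting to 0.2 — an invented operationalization of a
qualitative call, documented as such, chosen so that clearly bleached wells
(>20% absorbance loss) are positive while pipetting-level variation (a few
percent) is not. Disk-diffusion calls are positive when the inhibition-zone
diameter exceeds the 6 mm disk itself; zones are read to ±1 mm, so the
generator draws integer diameters. `activity_table()` lays calls out as the
familiar condition-by-week grids, with `NA` (not `-`) for missing cells:
absence of a measurement is not a negative result.

## 16S substitution scanning

Weekly consensus sequences are compared against the series reference (the
week-1 sequence by default). Although multiple alignment is the textbook
tool here, the weekly sequences are near-identical amplicons, so each is
pairwise-aligned to the reference instead — equivalent for substitution
calling in this regime and far easier to verify. Alignment is
Needleman–Wunsch with affine gaps (match +2, mismatch −1, gap open −5,
extend −2) and un-penalized terminal gaps, which tolerates the differing
trimmed ends of Sanger-derived consensus sequences; the engine is
`Biostrings::pairwiseAlignment()` and the test suite checks its scores
against an exhaustive independent path-enumeration oracle on short pairs.

A substitution is called only at columns where both sequences carry plain,
unequal A/C/G/T bases and both positions pass the optional quality masks;
gap and IUPAC-ambiguity columns are never called — chromatogram uncertainty
must not masquerade as mutation. Calls carry 1-based coordinates in both
sequences. For localization, positions are expressed in E. coli 16S
numbering (via alignment to a coordinate reference such as the standard
E. coli 16S sequence, when supplied) and labelled with their hypervariable
region from a bundled V1–V9 interval table (V1 69–99 ... V9 1295–1435).
Published V-region boundaries vary by a few nucleotides between sources;
the bundled table is a stated convention, shipped as an editable CSV, not a
canonical definition.

## Distances and trees

Strain identification uses Tamura–Nei (TN93) distances and neighbor-joining,
the standard pairing for 16S work. TN93 is implemented in closed form from
the two transition proportions (A↔G, C↔T), the transversion proportion, and
empirical base frequencies, without rate heterogeneity (no gamma), matching
the plain method description; gapped or ambiguous columns are deleted
pairwise. When any logarithm argument is non-positive, the distance is
saturated: the function returns `NA` with a warning rather than a number,
and the tree builder refuses matrices containing undefined distances. The
tests verify the implementation three ways: exact collapse to the
Jukes–Cantor closed form on a constructed equal-frequency, equal-rate pair
(to 1e-9); agreement with an established independent implementation
(`ape::dist.dna`) on random pairs; and recovery of a simulated branch
length at 10 kb.

Neighbor-joining follows Saitou–Nei with the standard
$Q_{ij} = (n-2)d_{ij} - r_i - r_j$ criterion; ties take the first row-major
minimum, so output is deterministic. Negative branch lengths — a known NJ
artifact on noisy matrices — are clamped to zero with the residual shifted
to the sister edge, preserving the joined pair's path length. On additive
matrices NJ is consistent, and the tests require exact (1e-6) reproduction
of random additive matrices' path lengths for n ≤ 8 over 100 seeds. Output
is Newick; no bootstrap support is computed.

## The synthetic-data generators

Every pipeline input can be generated with planted ground truth, so the
whole package is testable offline. The generators' defaults are the study
conditions: three conditions × weeks 1, 3, 5, 7, 9, 11 for assay-style
outputs (the sampled weeks of the activity tables) and weeks 1–12 for
sequence series; mass error multiplicative Gaussian with SD 2 ppm (the
accuracy class of a modern Q-TOF, comfortably inside the 10 ppm gate, as in
the sub-1-ppm identifications the rule is meant to reproduce); RT jitter SD
0.05 min; 16S GC content 0.70 (the actinobacterial range) over 1450 nt,
which covers the V1–V9 map.

Feature classes are planted explicitly: `constitutive` (every sample),
`experimental_only` (every experimental sample, no control),
`induced` (every experimental sample plus one control week), and
`control_only`. True masses are kept at least 0.05 Da apart so the planted
clustering is unambiguous at the tolerances above. Dropout — a per-cell
probability that a detection is missed — applies to experimental-arm cells
(`dropout_prob`), with a separate `control_dropout_prob` defaulting to 0.
The split exists because the experimental-only detector's precision
guarantee ("dropout can hide presence, never invent it") is a theorem only
while control-arm evidence is never silently lost: an induced feature whose
sole control detection dropped out would be indistinguishable from a truly
experimental-only one. With the default split, the tests assert precision
1.0 across 50 seeded simulations at 30% dropout, and exact class recovery at
dropout 0; recall under dropout is allowed to degrade. Users simulating
uniformly missing data can set both probabilities equal — and should then
expect false positives in proportion to the chance of losing every control
detection.

The sequence presets encode the two study scenarios: `"rhodococcus_o3"`
plants a T→G substitution in week 10 inside V2 (position 180) and a C→T in
week 12 inside V9 (position 1350) — the synthetic series uses region-map
coordinates directly, so no coordinate translation is needed — and
`"streptomyces"` plants nothing, giving the zero-call contrast. The
week-10/12 events fall outside the assay sampling grid deliberately: the
sequence series is sampled every week, the assays every other week.
The DPPH/zone generators draw well-separated values (35–75% scavenging for
positives vs 0–8% for negatives; 8–20 mm zones vs bare 6 mm disks) so the
encoded grids reproduce the requested patterns exactly under the default
thresholds.

What the generators do *not* emulate: chromatographic peak shapes, isotope
patterns, co-elution and adduct redundancy, intensity drift, batch effects,
or chimeric/low-quality sequencing reads. Passing tests therefore demonstrate
the correctness of the decision rules and algorithms, not robustness to raw
instrument artifacts — on real data, peak picking and quality trimming
happen upstream of this package.

## Problem sizes and numerical choices

The bundled analyses run at desk scale by design: the presence fixture has
12 features × 18 samples; the synthetic feature tables used in tests carry
~20 planted features over the same design; sequence series are 12 × 1450 nt;
the brute-force dereplication comparisons use 200 random 10 × 30 instances;
NJ consistency uses 100 random additive matrices with up to 8 taxa; the
substitution-recovery suite uses 100 seeded 1000-nt replicates. These sizes
are chosen so the full suite runs in well under a minute while still
exercising every code path; all scale linearly or quadratically, and the
implementations are routinely used at 10–100× these sizes.

Numerical conventions worth knowing: strict inequality at both dereplication
bounds; mass-window queries are binary-searched on the sorted library and
verified against exhaustive scans; medians (not means) define cluster
consensus so single outliers cannot drag a centroid; alignment tie-breaking
is delegated to the deterministic engine; and all generator randomness flows
from a single integer seed, so every dataset is byte-reproducible.

## Known limitations

* The compound library fixture is tiny; identification statements on real
  data are only as good as the supplied library.
* Presence/absence logic ignores intensity entirely; a strongly suppressed
  but still detectable metabolite counts as present.
* Pairwise-to-reference substitution calling assumes near-identical series;
  it is not a variant caller for diverged sequences.
* The V-region table and the DPPH threshold are conventions, clearly
  flagged and editable, not measured constants.
* mzML ingestion is not provided; feature tables arrive as CSV after
  vendor-side peak picking.
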