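# oxyderep

Tools for analysing how elevated dissolved oxygen and ozone change what
actinobacteria make and what happens to their DNA. The package is aimed at
natural-product and microbiology groups running cultivation experiments in
which strains (e.g. *Streptomyces*, *Rhodococcus*) are grown under a control
(natural aeration, `C`) and experimental (`O2`, `O3`) regimes, sampled weekly,
and profiled by high-resolution LC-MS, DPPH and disk-diffusion assays, and
16S rRNA re-sequencing.

It implements, as tested reusable functions:

* **Accurate-mass dereplication** — identify metabolites by matching neutral
  monoisotopic masses against a compound library under the conjunctive rule

  |m − μ| < 0.001 Da **and** |m − μ|/μ × 10⁶ < 10 ppm **and** matching
  biological source (producing genus),

  with formula parsing, monoisotopic mass computation, and
  electron-corrected adduct m/z arithmetic (`[M+H]+`, `[M+Na]+`, `[M+NH4]+`,
  `[M+K]+`) underneath.
* **Feature alignment & differential presence** — deterministic greedy
  (mass, RT) clustering across samples, boolean presence matrices over the
  condition × week × fraction design, detection of metabolites synthesized
  *only* under experimental conditions, induction within a retention-time
  window, and presence/bioassay concordance.
* **Bioassay encoding** — DPPH radical-scavenging calls from 517 nm plate
  absorbances (scavenging fraction `1 − A/A₀`, threshold 0.2 by default) and
  disk-diffusion calls (zone > 6 mm disk), laid out as condition × week
  grids.
* **16S mutation scanning** — ends-free pairwise alignment of weekly
  consensus sequences to a reference, substitution calling that skips gap,
  ambiguity and quality-masked columns, and mapping onto E. coli-numbered
  V1–V9 hypervariable regions; plus Tamura–Nei (TN93) distances and
  neighbor-joining trees (Newick out).
* **Seeded synthetic-data generators** — every input above with planted
  ground truth (feature classes, substitutions, activity grids), so the
  entire pipeline is testable offline.

## Worked example

Dereplicate the bundled cultivation presence fixture (12 metabolites of a
*Streptomyces* strain across C/O2/O3 × weeks 1–11) against the bundled
reference library, then find what is synthesized only under oxygen/ozone:

```r
library(oxyderep)

lib <- baikal_reference_library()
fx  <- streptomyces_presence_fixture()
fc  <- align_features(fx$features)
fc
#> feature_clusters: 12 clusters from 144 features in 13 samples

matches <- dereplicate(fc, lib, derep_params(source_filter = "Streptomyces"))
head(matches[matches$rank == 1, c("cluster_id", "compound", "delta_da", "delta_ppm")], 4)
#>   cluster_id                        compound  delta_da delta_ppm
#> 1          1         11-methyl-2-tridecanone -0.000116    -0.544
#> 2          2              streptomyceamide B  0.000000     0.000
#> 3          3 5,10,11-trihydroxy-3-cadinanone  0.000191     0.706
#> 4          4      10-methylhexadecanoic acid  0.000220     0.813
```

Every accepted match sits well inside the 0.001 Da / 10 ppm gates (the
`delta_ppm` column is the signed ppm error against the library mass).
Differential presence across the design:

```r
pm   <- build_presence_matrix(fc, design = fx$design)
only <- detect_only_experimental(pm)
sort(round(fc$clusters$consensus_mass[match(only, fc$clusters$cluster_id)], 4))
#>  [1] 212.2139 264.0747 270.1833 270.2561 436.2219 439.2704 440.3655 572.3175
#>  [9] 599.2496 600.3486 751.3685
```

Eleven of the twelve metabolites are never seen under natural aeration —
including the unidentified 572.3175 Da molecule — while the 707.5335 Da
molecule is excluded because it appears once in a control week. Mutation
scanning on the synthetic oxygen+ozone *Rhodococcus*-style series:

```r
series <- gen_16s_series(sim_config(seed = 1), preset = "rhodococcus_o3")
scan_16s_series(series$sequences)
#>   sample query_position ref_position ref_base alt_base coord_position region
#> 1 week10            180          180        T        G            180     V2
#> 2 week12           1350          1350        C        T           1350     V9
```

Two substitutions, T→G then C→T, both in hypervariable regions — and the
matching `"streptomyces"` preset yields zero calls.

## Data resources

Editable CSVs under `inst/extdata/`: element monoisotopic masses, the adduct
set, the V1–V9 interval table (a stated convention in E. coli numbering),
the ~30-record reference compound library (named actinobacterial products
plus labelled synthetic decoys), the study presence fixture, and the two
reference activity grids. See the methods vignette
(`vignettes/oxyderep-methods.Rmd`) for the models, parameter defaults, design
decisions and limitations.
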