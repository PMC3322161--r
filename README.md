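# silicoplex

In-silico design and simulation of gel-based multiplex PCR
species-identification assays, modelled on the triplex/nonaplex ITS2 assays
used to distinguish the seven sharpnose (*Rhizoprionodon*) shark species in
fisheries and market surveys.

Shark fins and meat usually reach the market without the morphology needed
for species identification. The assay this package models solves that with a
single PCR: a universal primer pair anneals in the conserved 5.8S/28S rDNA
flanks and amplifies the whole ITS2 locus from any shark (the positive
control), while one species-specific primer (SSP) per target species —
anchored with its 3′ end on nucleotides unique to that species — extends to
the universal reverse primer and produces a diagnostic band of a
characteristic size. Lane readout: diagnostic + control band ⇒ identified;
control only ⇒ non-target; no bands ⇒ assay failure (never "species
absent").

`silicoplex` is for molecular ecologists and fisheries-forensics developers
who want to design such assays, or sanity-check existing primer sets,
entirely on the computer:

* **in-silico PCR** — binding-site search under an explicit annealing rule
  (≤ *k* mismatches and an exactly matched 3′ anchor), amplicon prediction
  and band-pattern simulation for arbitrary multiplexes;
* **species calling** — the total decision procedure over band patterns,
  with the positive-control guard against false negatives;
* **genetic distances** — Tamura–Nei (TN93) distances with all intermediate
  quantities (base frequencies, transition/transversion proportions),
  pairwise or as a matrix:

  d = −(2g<sub>A</sub>g<sub>G</sub>/g<sub>R</sub>) ln w₁ −
  (2g<sub>T</sub>g<sub>C</sub>/g<sub>Y</sub>) ln w₂ −
  2(g<sub>R</sub>g<sub>Y</sub> − g<sub>A</sub>g<sub>G</sub>g<sub>Y</sub>/g<sub>R</sub> −
  g<sub>T</sub>g<sub>C</sub>g<sub>R</sub>/g<sub>Y</sub>) ln w₃

  with w₁ = 1 − g<sub>R</sub>P₁/(2g<sub>A</sub>g<sub>G</sub>) − Q/(2g<sub>R</sub>),
  w₂ = 1 − g<sub>Y</sub>P₂/(2g<sub>T</sub>g<sub>C</sub>) − Q/(2g<sub>Y</sub>),
  w₃ = 1 − Q/(2g<sub>R</sub>g<sub>Y</sub>);
* **primer design** — diagnostic-site discovery in a target/non-target
  alignment, composition-filtered candidate enumeration (Tm, GC,
  self-complementarity), zero-binding specificity screening, and selection
  of one primer per species maximising the diagnostic size ladder;
* **synthetic panels** — seeded ITS2-like panels with controlled Tamura–Nei
  divergence (0.003–0.28), conserved universal-site flanks and deep decoy
  taxa, so everything above is testable offline.

The published nonaplex (seven SSPs, diagnostic sizes 230–1300 bp, control
window 860–1500 bp) ships as a built-in assay; its two universal primers are
placeholders with synthetic sequences (the real FISH5.8SF/FISH28SR sequences
are published elsewhere) and can be overridden everywhere.

## Worked example

```r
library(silicoplex)

panel  <- generate_panel(synthetic_panel_config(seed = 1))
design <- design_assay(panel$templates)
glance(design)
#> # A tibble: 1 × 4
#>   n_taxa min_pairwise_gap_bp control_min_bp control_max_bp
#>    <int>               <dbl>          <int>          <int>
#> 1      7                 166           1549           1549

bands <- simulate_assay(panel$templates, design$assay)
calls <- call_species(bands, design$assay)
dplyr::count(calls, outcome)
#> # A tibble: 2 × 2
#>   outcome        n
#>   <chr>      <int>
#> 1 identified     7
#> 2 non_target    10
```

Seven designed primers whose products are at least 166 bp apart on the gel;
all seven synthetic target species are identified and all ten decoy species
yield only the control band — the in-silico analogue of an assay with no
false positives and no false negatives. The packaged assay behaves the same
way on real template FASTA:

```r
assay <- load_packaged_assay("nonaplex")
min_pairwise_gap(assay$diagnostic_key$expected_bp)$min_gap_bp
#> [1] 130
```

A thin command-line wrapper (`exec/silicoplex`) exposes the same workflows
as `identify`, `simulate`, `design`, `distances` and `synth` subcommands.

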