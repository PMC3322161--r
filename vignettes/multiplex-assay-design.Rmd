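---
title: "Designing and simulating multiplex species-identification PCR assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and simulating multiplex species-identification PCR assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silicoplex)
```

## The assay model

Gel-based multiplex PCR species identification exploits a locus — here the
nuclear ribosomal ITS2, flanked by the conserved 5.8S and 28S genes — that is
nearly invariant within species but divergent between even closely related
congeners. Two kinds of primers are mixed in one tube:

* a **universal pair** annealing in the conserved flanks, which amplifies the
  whole locus from essentially any shark and serves as the **positive
  control**: its band proves the reaction worked, so that a blank lane is
  read as *assay failure*, never as "species absent";
* one **species-specific primer (SSP)** per target species, anchored on
  diagnostic nucleotide differences, which together with the universal
  reverse primer produces a **diagnostic amplicon** whose characteristic size
  identifies the species on an agarose gel.

A target-species lane therefore shows two bands (diagnostic + control); a
non-target lane shows the control band only; a blank lane is a failed
reaction. With seven SSPs plus the universal pair in one tube (a *nonaplex*),
any of the seven sharpnose (*Rhizoprionodon*) species is identified in a
single reaction; the packaged assay (`load_packaged_assay("nonaplex")`)
carries the published seven diagnostic sizes
{230, 420, 560, 720, 850, 1150, 1300} bp, whose minimum pairwise gap is
130 bp, and a 860–1500 bp control window. The two universal primers are
shipped as named placeholders with *synthetic* sequences — the real
FISH5.8SF/FISH28SR sequences are published elsewhere — and every function
accepts a user-supplied universal pair.

## Annealing as a testable rule

Wet-lab specificity ("failure of the SSP to anneal to non-target DNA") is
modelled by a `binding_policy()`: a primer binds a site when it has at most
`max_mismatches` mismatches overall (default 2) **and** its
`three_prime_anchor` terminal bases (default 3) match exactly — polymerase
extension requires a matched 3′ end, which is exactly why SSP design places
the diagnostic difference at the 3′ end. Both knobs are exposed on every
function and the CLI. IUPAC ambiguity codes in a primer match any consistent
base; an ambiguous template base only matches a literally identical primer
letter (conservative for diagnostics). No thermodynamic annealing, product
competition or polymerase kinetics is modelled: every eligible product is
reported, and the variably faint whole-locus control seen on real gels is
available only as a cosmetic `faint_control` tag.

Coordinates are 1-based and closed throughout, matching R's string and
ranges conventions.

## Tamura–Nei distances

Between-species divergence is quantified with the Tamura–Nei (TN93)
distance, which separates purine transitions, pyrimidine transitions and
transversions under unequal base frequencies; frequencies are estimated from
the pooled pair, and the gap policy defaults to pairwise deletion. Saturated
pairs return `d = Inf` with a flag rather than an error. When sequences are
not pre-aligned, pairs are globally aligned (Needleman–Wunsch, affine gaps,
match 1 / mismatch −1 / open 10 / extend 0.5 by default) via Biostrings.
Because the alignment parameters behind any published distance table are a
free choice of the original software, distance reproduction is always
checked with tolerances, never bit-exactly.

## The design pipeline

`design_assay()` reconstructs the SSP design workflow:

1. **Diagnostic sites** (`find_diagnostic_sites()`): every alignment column
   where the target differs from at least one non-target congener; *fully*
   diagnostic columns differ from all of them.
2. **Candidates** (`enumerate_candidates()`): windows of 18–25 nt whose 3′
   anchor covers a fully diagnostic site, filtered by composition — Tm
   55–70 °C (Wallace rule `2(A+T)+4(G+C)` below 14 nt, else
   `64.9 + 41(GC−16.4)/N`), GC 0.40–0.70, no self-complementary 3′
   tetramer. These bounds match the published sharpnose primers; the
   original tools' exact thresholds are not published, so the simplest
   widely used formulas are documented and configurable.
3. **Specificity screen** (`screen_specificity()`): a candidate survives
   only with *zero* binding sites on every other panel template (congeners
   and decoys) under the policy — the in-silico analogue of the wet-lab
   non-target panel.
4. **Ladder selection** (`select_ladder()`): one candidate per taxon
   maximising the minimum pairwise product-size gap (exhaustive over
   distinct sizes when the space is small, greedy-with-swap otherwise; ties
   broken by more non-target mismatches, then name), with diagnostic sizes
   required to clear the positive-control window by 50 bp.

Composition bounds are guidelines rather than physics: when a taxon's few
diagnostic sites offer no window inside the strict bounds (the closest
species pair may contribute only two or three sites, and those can fall in
composition-hostile neighbourhoods), `design_assay()` retries that taxon
under two progressively relaxed, documented tiers (16–28 nt / Tm 52–72 °C /
GC 0.35–0.75, then 15–32 nt / Tm 45–80 °C / GC 0.25–0.85 without the
self-dimer filter) and reports that it did so. The strict defaults are
unchanged for every taxon they satisfy.

`select_ladder()`'s own default spacing floor is 100 bp. `design_assay()`
instead uses the smallest spacing any credible gel read can support: the key
stays unambiguous as long as adjacent sizes differ by more than twice the
reading tolerance, the key tolerance is tightened automatically when the
achieved gap demands it (down to ±10 bp, i.e. a 21 bp floor), and the
ladder search *maximises* spacing anyway, so achieved gaps are typically
well above 100 bp. A flat 100 bp floor would spuriously reject panels whose
most closely related species pair happens to offer only a couple of
diagnostic positions that sit near each other. The ±25 bp default tolerance
reflects routine agarose size-reading precision and the fact that published
diagnostic sizes are round numbers; designs that had to tighten it report
so in the key.

## The synthetic panel

`generate_panel()` produces the study conditions every other module is
tested against, without any downloads: seven target taxa whose ITS2-like
cores (one length drawn from 1282–1365 bp per panel) diverge by controlled
Tamura–Nei distances, conserved 120 bp flanks carrying the universal primer
sites, and ten decoy taxa at ≥0.45 distance standing in for sharks of
other genera and orders (well above the ≥0.2 that already separates
non-congeners; at congener-level divergence the annealing policy would
occasionally and correctly flag candidate primers as cross-reactive,
which the deeply diverged wet-lab panel does not show). Divergence targets are path lengths on a fixed attachment tree
chosen to mimic the published distance structure — a 0.003 species pair, a
close cluster (≈0.01–0.02), one mid-range taxon (≈0.06) and two deep taxa
(≈0.21/0.22 from the cluster, 0.28 apart) — because an arbitrary dense
pairwise matrix is not additive and therefore not realisable by any
evolutionary process. Substitutions are applied one at a time at a 2:1
transition:transversion ratio, *measuring* the realized distance after each
and stopping at the nearest achievable value, so realized divergences track
targets within a few percent even when a branch is only two substitutions
long. The ancestral core is 58% GC (rDNA spacers are GC-rich), which also
puts 18–25-mers in the 55–70 °C Tm regime the composition filters expect.
Because the emulated reference panel demonstrably admits well-separated
fully specific primer sites for every species, the generator also
guarantees that analogue: if homoplasy, core-edge placement or clumping
leaves a taxon without at least two interior columns (≥100 bp apart) where
it differs from all other targets, that terminal branch is redrawn (its
divergences are unchanged) until they exist.

What the generator does *not* emulate: indel variation between species
(available via `indel_rate` for alignment stress-testing, off by default so
distances are well-defined without realignment), pseudogene/variant rDNA
copies behind faint off-target bands, intragenomic repeat heterogeneity,
and sequencing noise. Passing end-to-end tests on this panel therefore
demonstrates the *logic* of the assay — design, specificity, size ladder,
calling — not performance on real chromatograms.

## Calling decisions

`call_species()` is total: every band pattern maps to exactly one of
`identified`, `non_target`, `assay_failure`, `ambiguous`. The control band
is required by default even when a diagnostic band is present (the
false-negative guard); `waive_control = TRUE` mirrors practice on gels where
the control is variably faint. `ambiguous` (two key entries matched) has no
published precedent but makes the procedure exhaustive; it is an outcome,
not an error. Enlarging the tolerance can turn `identified` into
`ambiguous`, never into `non_target`.

## A worked run

```{r, eval = FALSE}
panel <- generate_panel(synthetic_panel_config(seed = 1))
design <- design_assay(panel$templates)
glance(design)
bands <- simulate_assay(panel$templates, design$assay)
call_species(bands, design$assay)
plot_gel(bands)
```

On the seed-1 panel this designs seven SSPs with a 166 bp minimum ladder
gap, identifies 7/7 targets, and calls all 10 decoys `non_target`.

## Numerical choices and limitations

* Problem sizes: tests and the acceptance script use one 17-template panel,
  1000 fuzzed scanner instances and a few hundred fuzzed band patterns —
  sizes at which every oracle can be brute-forced.
* The gel migration model places a ladder rung of size *s* at
  `log(max rung) − log(s)` relative units and interpolates piecewise-
  linearly in log-size (exactly the global log law inside the ladder span);
  out-of-span sizes are extrapolated and flagged. Two bands are deemed
  resolvable at a log-size separation ≥0.1 (≈10% size difference), typical
  for agarose in the 100–1500 bp range.
* Ladder-selection tie-breaks are deterministic (mismatch sum, then name),
  so designs are reproducible for a fixed panel.
* Saturated distances, empty candidate sets, missing taxa and infeasible
  ladders are reported as flags or typed errors naming the offender, never
  silent results.
* GenBank access is deliberately out of scope: accession-based workflows
  run through user-supplied FASTA.
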