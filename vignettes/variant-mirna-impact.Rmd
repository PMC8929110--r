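---
title: "Scoring 3'-UTR variants against tissue-specific miRNA target sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring 3'-UTR variants against tissue-specific miRNA target sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Substitutions and indels in a 3' untranslated region can create, destroy,
strengthen or weaken microRNA binding sites and thereby shift the
expression of the host gene. In a tissue where a gene is observed to be
downregulated — the motivating case is *DICER1* and *DROSHA* in
mesenchymal stromal cells (MSCs) during myelodysplastic syndrome — a
natural screen is: for every known 3'-UTR variant, compare the predicted
miRNA interactions of the reference and alternate alleles, count only
miRNAs actually expressed in the tissue, and prioritize variants that make
the transcript a *better* miRNA target.

`utrmirscan` implements that screen end to end. For each variant it
produces, per prediction route,

* **ΔN** — the change (ALT − REF) in the number of distinct interacting
  whitelisted miRNAs, and
* **ΔW** — the change in the summed hybridization free energies
  (kcal/mol; negative ΔW means stronger binding on the alternate allele,
  i.e. predicted downregulation),

then flags statistical outliers of the two per-route distributions and
reports candidate downregulating variants (ΔN ≥ 1, ΔW < 0, outlier in at
least one distribution).

## Allele windows

Interactions are predicted in short windows rather than against the whole
UTR: folding a multi-kilobase UTR lets distal self-structure shadow local
binding sites, and local windows keep REF/ALT comparisons symmetric. For a
variant at position $p$ the reference window covers
$[p - w/2,\; p + w/2 - 1]$ (default $w = 50$ nt), truncated at the UTR
ends. The alternate window is re-extracted with the same arithmetic from
the edited sequence, so an indel's window returns to nominal length
instead of inheriting the length change — otherwise ΔN/ΔW would be biased
by search-space size. Whether the original screen centered or anchored its
windows is not documented; centering maximizes symmetric context and is
this package's choice. Overlapping variants are evaluated independently,
one at a time (no haplotypes), matching per-variant reporting.

## Route 1: seed-anchored complementarity scan

The canonical determinant of miRNA targeting is contiguous pairing of the
miRNA 5' seed. `find_seed_matches()` reports, for every target offset and
each miRNA anchor position 1 or 2, the maximal uninterrupted antiparallel
complementary run beginning at that anchor, if it spans at least
`min_seed = 6` nucleotides. G-U wobbles count as matches by default
(`allow_wobble`). Both anchors are scanned because the seed is classically
nucleotides 2–8 while 5'-anchored tools start at position 1; each match
records which anchor applied. Runs longer than 8 keep their true length
(`full_len`) but are reported and classified by their first 8 pairs, the
top of the canonical taxonomy. A match whose target interval is strictly
contained in a same-anchor match is dropped; this containment rule is this
package's own deduplication choice.

Each hit is then re-scored in its *exact* hybrid configuration:
`rescore_seed_hit()` fixes the matched run as the seed helix, extends the
remaining miRNA 3' portion optimally against the target upstream of the
helix, and scores the assembled structure with the energy model below.
No energy gate is applied at this stage; weak sites are discarded by the
shared filter chain so both routes face identical gates.

## Route 2: minimum-free-energy hybrid

`duplex_mfe()` searches all co-linear (non-crossing) antiparallel hybrids
between window and miRNA by dynamic programming and returns the
minimum-free-energy structure, or nothing if the optimum is ≥ 0 kcal/mol
(only energetically favorable interactions are kept). By default the
optimum is constrained to contain an uninterrupted helix of ≥ 6 pairs
within miRNA positions 1–8 — the "energetically favorable seed
interaction" constraint of seed-aware RNA–RNA interaction tools.

The energy function is a reduced nearest-neighbor model at 37 °C
("reduced-nn-v1", embedded, versioned, never fetched):

* **Stacking.** The 6 × 6 table of pair-step free energies over
  {AU, UA, CG, GC, GU, UG}, transcribed once from the Turner 2004 RNA
  parameter set. All Watson-Crick steps are stabilizing; the two
  G·U-on-G·U steps (+1.3 and +0.3 kcal/mol) are mildly destabilizing and
  are retained as published rather than clamped negative.
* **Initiation.** A duplex initiation penalty of 4.09 kcal/mol.
* **Loops.** Affine penalties replace the full tabulated loop matrices:
  a bulge of $b$ nucleotides costs $3.2 + 0.35\,b$, an interior loop with
  $u$ unpaired nucleotides in total costs $1.3 + 0.35\,u$; no stacking is
  scored across a loop, and each loop side is bounded by
  `max_internal_unpaired = 15` nt (a common RNA–RNA interaction default).
* **Omitted.** Dangling ends, terminal mismatches and coaxial
  refinements; and — deliberately — any target-accessibility term.
  Accessibility requires a partition-function folding engine; this model
  scores the hybrid only. Consequently the ΔW magnitudes published for
  accessibility-aware tools are comparison benchmarks for this package,
  not values it is expected to reproduce numerically; the ranking signal
  is carried by the hybrid energy.

Ties in the DP are resolved by a fixed scan order with strict-improvement
updates (epsilon 1e-9), so identical inputs always yield identical
structures. `score_structure()` independently recomputes the energy of any
pairing string; the test suite asserts DP-energy/traceback agreement to
1e-6 kcal/mol on every emitted site, and agreement of the DP with
exhaustive enumeration of all co-linear pairings on fuzzed short
sequences.

## Site classification and filtering

Every site is assigned one class, first match in priority order:

| class | rule |
|---|---|
| `canonical_8/7/6` | an uninterrupted paired run covering ≥ k miRNA positions within 1–8 (wobbles count as pairs by default; `wobble_in_canonical = FALSE` splits runs at wobbles) |
| `centered` | ≥ 11 contiguous pairs whose miRNA interval starts at position 3–6 |
| `compensatory` | seed 2–8 paired except exactly one wobble or mismatch, plus ≥ 4 contiguous pairs within miRNA positions 13–17 |
| `none` | anything else (always filtered out) |

The published description of the non-canonical classes is prose; the
operational constants (11 pairs, start 3–6, 4 pairs at 13–17) follow the
literature definitions of centered and 3'-compensatory sites and live in
`filter_config()`, not in code.

`filter_sites()` retains sites with energy ≤ −8.5 kcal/mol (boundary
inclusive: exactly −8.5 is *sufficient*), miRNA name in the tissue
whitelist (exact mature-name match after trimming), and an allowed class.
The whitelist is a runtime input on purpose: the MSC screen used both a
26-miRNA abundant set and a 336-miRNA union, and either is expressible as
a file.

## Impact statistics

`summarize_allele()` counts distinct retained miRNAs and sums energies.
The default `sum_mode = "best"` sums the single best (lowest-energy) site
per miRNA, so one miRNA with many overlapping windows cannot dominate ΔW;
`"all"` sums every site. The original description says only "sum of
hybridization energies", so both modes are provided and the choice is
explicit configuration.

Outliers are defined by Tukey fences per route, never pooled across
routes: `outlier_w` ⇔ ΔW < Q1 − k·IQR and `outlier_n` ⇔ ΔN > Q3 + k·IQR,
with k = 1.5 and quartiles by the linear-interpolation convention
(R `quantile` type 7). The published screen never names its outlier rule,
so this is a documented calibration knob (`fence_k`), not a claim about
the original computation. With fewer than 8 variants in a route the fences
degenerate; the package then flags nonzero impacts and warns. Candidates
(ΔN ≥ 1, ΔW < 0, and at least one outlier flag) are sorted by ascending ΔW
within route.

## The synthetic generator

`simulate_dataset()` builds a block-structured UTR: each variant owns one
window-sized block. Create/destroy blocks carry a 12-pair Watson-Crick
helix complementary to miRNA positions 1–12; the site-making/-breaking SNP
toggles the target base pairing miRNA position 4 between the Watson-Crick
complement and a base that pairs neither canonically nor by wobble.
Neutral blocks contain no plant. The miRNA pool (default 21-nt, uniform
composition) is rejection-sampled for three deterministic properties: the
planted helix clears the energy cutoff with margin, the helix core has no
off-diagonal self-matches, and breaking position 4 removes every seed
match — excluding quasi-periodic miRNAs whose broken sites would still
match on shifted diagonals. Every block is then verified against the full
filter chain under both routes and re-rolled until its intended ΔN/ΔW
signature holds exactly.

Two consequences should be kept in mind when interpreting green tests.
First, planted-effect recovery demonstrates end-to-end *self-consistency*
of the pipeline (the generator uses the pipeline's own gates as ground
truth), not recall on real data. Second, the uniform background differs
from real 3'-UTRs, which are AU-rich; an AU-rich composition can be
supplied (`composition`), which raises chance seed-match rates and
re-roll counts. The generator does not emulate miRNA abundance, expression
dynamics, or population allele-frequency spectra.

The lower-level operations `generate_utr()` / `generate_variant_set()`
expose the same planting machinery for custom layouts (including
`canonical_7/6` and `centered` plants) with a truth table of planted
intervals and site-making variants.

## Validation scale and numerical choices

The shipped validation (test suite and `scripts/acceptance.R`) uses
problem sizes chosen to exercise the code thoroughly while staying
desk-sized: 1,000 fuzzed window/miRNA pairs per wobble setting for
seed-scan oracle equivalence; 500 fuzzed pairs with both sequences ≤ 8 nt
for duplex-DP equivalence against exhaustive enumeration (tolerance 1e-6
kcal/mol); 100 each of create/destroy/neutral planted variants under both
routes; 31 cutoff steps from −5 to −20 kcal/mol for filter monotonicity;
and 199 + 1 synthetic ΔW draws for outlier recovery. Energies are plain
doubles; all equality assertions use 1e-6 kcal/mol; all randomness flows
from explicit seeds.

## Known limitations

* Hybridization-only energies: no accessibility, so absolute ΔW values
  are not comparable to accessibility-aware tools, only rankings are.
* Single best site per (window, miRNA) in the energy route; suboptimal
  co-occurring sites within one window are not enumerated.
* Exact mature-name whitelist matching; isomiRs and arm-naming variants
  must be normalized upstream.
* Transcript-local coordinates only; genomic liftover and multi-isoform
  UTRs are out of scope.
* No p-values or multiple-testing control on ΔN/ΔW — the outlier fences
  are a prioritization heuristic, mirroring the screen this package
  reimplements.

## A minimal session

```{r}
library(utrmirscan)

sim <- simulate_dataset(n_create = 3, n_destroy = 3, n_neutral = 3,
                        rng_seed = 5, pool_size = 6)
res <- run_scan(sim$utr, sim$variants, sim$mirnas, sim$whitelist,
                verbose = TRUE)
res$impacts[, c("variant_id", "method", "delta_n", "delta_w")]
write_results(res$impacts, res$sites, "run/out")
```
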