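---
title: "Methods: models, rules and numerical choices in cblkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules and numerical choices in cblkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cblkit)
```

This vignette states exactly what each component of `cblkit` computes:
the structural model behind the EF-hand scanner, the rule sets for
lipidation and nomenclature, the statistical formulas, the design of the
synthetic-data generators, and the numerical conventions. It is the
reference for interpreting any result the package produces.

## The EF-hand model

An EF-hand is modelled as a fixed **36-residue window**: an entering
helix (window positions 1–12), a Ca²⁺-binding loop (positions 13–24) and
an exiting helix (positions 25–36). Within the loop, the six side chains
that coordinate Ca²⁺ sit at loop positions 1, 3, 5, 7, 9 and 12 — window
positions 13, 15, 17, 19, 21 and 24. All positions are 1-based; a window
starting at residue `start` covers `start .. start + 35`.

`scan_ef_hands()` applies a strict rule at every candidate offset:

1. **Acidic anchors**: D or E at window positions 14 and 22.
2. **Bidentate loop-12**: D or E at window position 24 (loop position
   12, the residue that chelates with both carboxylate oxygens).
3. **Oxygen-donor quorum**: at least `loop_min_donors` (default 3) of
   the six loop ligand positions hold an oxygen-bearing side chain
   (D, E, N, Q, S or T).

Each window also receives a **score**: the fraction of 8 elementary
checks satisfied (the two acidic anchors plus the six individual loop
donor positions). A window can pass the strict rule with score 6/8; a
fully canonical hand scores 1.0. With `strict = FALSE`, windows are
admitted by `score >= min_score` (default 0.5) instead.

Overlapping hits are resolved **greedily left to right**: accept the
leftmost passing window, then the next passing window starting at least
36 residues later, and so on. This matches how tandem EF-hands tile real
sequences and makes the output a deterministic function of the input.

`classify_cbl()` calls a record a CBL when the scanner finds **exactly
three** hands; four hands indicates a calmodulin-like protein and is not
a CBL. The scanner is validated in the test suite against an independent
brute-force oracle that re-implements the window rule position by
position with no shared code.

## The motif pattern language

`find_motifs()` and `parse_motif_pattern()` accept dash-separated
patterns in which each token is:

* a single residue letter (`D`),
* a set of alternatives separated by `/` (`D/E`),
* a wildcard `x`, or a run of wildcards `x4` / `x_4` (four arbitrary
  residues).

For example `E/D-D-P-E-x4-E-x6-E` denotes sixteen consecutive positions.
Matching is exact, case-insensitive on input, and returns all (possibly
overlapping) start positions. `nterminal_motif_check()` uses this
machinery for the two diagnostic N-terminal signatures: `D/E-x-E/D`
anchored at position 31 (group A) and `E-E/D-P` anchored at position 16
(group D).

## Lipidation rules

`predict_myristoylation()`: a glycine at position 2 (immediately after
the initiator Met) is the primary N-myristoylation call; failing that, a
glycine at position 7 is a secondary call; otherwise none.

`predict_palmitoylation()`: any cysteine within residues 1–25 is a
palmitoylation candidate; a cysteine at positions 3–6 is the
**canonical** S-acylation site. Sequences shorter than 25 residues are
flagged (`short_sequence`) and produce a warning rather than an error.

`lipidation_calls()` joins the two and derives two group diagnostics:
`group_b_like` (neither modification — the anchorless group) and
`palmitoylated_not_myristoylated`. `group_pattern_check()` aggregates
these per annotated group and flags violations of the expected pattern
(group B: canonical palmitoylation fraction 0; all other groups: above
0). Fractions are `NA` for empty groups.

## Nomenclature

`make_abbrevs()` builds species abbreviations deterministically: genus
initial + lowercase epithet first letter (e.g. *Oryza sativa* → `Os`).
Under the default `jump4` collision policy, species are processed in
alphabetical order; when a candidate collides with an already-assigned
abbreviation, the later species jumps to a 4-letter epithet prefix and
extends letter by letter until unique (*Capsella rubella* → `Cr`,
*Chlamydomonas reinhardtii* → `Crein`). The map is injective by
construction and identical across calls.

`assign_names()` numbers each query by its **best global alignment
score** against a reference panel: rice CBLs for monocots, *Arabidopsis*
CBLs otherwise (per a supplied lineage table). Alignments use
`Biostrings::pairwiseAlignment` with BLOSUM62, gap opening 10 and gap
extension 1, `type = "global"` (Needleman–Wunsch). Score ties are broken
by the lower reference CBL number, then lexicographic reference id. When
two or more members of one species map to the same reference number,
they become co-orthologous paralogs and receive suffixes `-1`, `-2`, …
in order of **descending alignment score**, ties broken by record id;
singletons carry no suffix (`OsCBL5`, but `OsCBL3-1`, `OsCBL3-2`,
`OsCBL3-3`). `parse_cbl_name()` inverts the scheme.

## Evolutionary statistics

All alignment statistics operate on gapped blocks built by
`protein_records(..., aligned = TRUE)` or `read_fasta(..., aligned =
TRUE)`.

**Site filtering.** `trio_counts()` applies *complete deletion*: any
column containing a gap in any of the three members is removed before
counting. `pairwise_diversity()` instead uses a coverage filter: columns
with at least `min_coverage` (default 95%) ungapped members are
retained, and the per-pair comparison skips residual gaps.

**Trio partition.** Retained columns are partitioned into five exclusive
classes: identical in all three; unique to A (B = C ≠ A); unique to B;
unique to C; divergent in all three. With three sequences these classes
are exhaustive.

**Relative rate test** (Tajima). With `u_A`, `u_B` the unique-difference
counts of the two test lineages relative to the outgroup,

$$\chi^2 = \frac{(u_A - u_B)^2}{u_A + u_B}, \qquad df = 1,$$

with the upper-tail p-value from `pchisq(..., lower.tail = FALSE)`. The
test is undefined when `u_A + u_B = 0`.

**Watterson's Θ and Tajima's D.** For `m` sequences, `n` sites, `S`
segregating sites and mean pairwise diversity per site `π`:

$$a_1 = \sum_{i=1}^{m-1} \tfrac1i,\quad
  a_2 = \sum_{i=1}^{m-1} \tfrac1{i^2},\quad
  \Theta_w = \frac{S/n}{a_1},$$

$$b_1 = \frac{m+1}{3(m-1)},\;
  b_2 = \frac{2(m^2+m+3)}{9m(m-1)},\;
  c_1 = b_1 - \frac1{a_1},\;
  c_2 = b_2 - \frac{m+2}{a_1 m} + \frac{a_2}{a_1^2},$$

$$e_1 = \frac{c_1}{a_1},\quad e_2 = \frac{c_2}{a_1^2 + a_2},\quad
  D = \frac{\pi n - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}}.$$

Harmonic sums are computed by direct summation (exact to double
precision over the relevant range of `m`; the suite checks up to
`m = 10^4`), not by asymptotic approximation. `tajima_test()` wires
`pairwise_diversity()` into `tajima_d()` for an alignment block.

## Composition, cost and protein properties

`aa_composition()` computes per-protein residue percentages and averages
them with **equal weight per protein** (not pooled residue counts), so
short and long members contribute equally. `cost_abundance_association()`
correlates mean abundance with a packaged per-residue biosynthetic
energy-cost table (`cbl_cost_table()`, in high-energy phosphate-bond
equivalents) using **Spearman's rank correlation**; ρ is `NA` if either
margin has zero variance. `molecular_weight()` sums average residue
masses plus one water (18.0153 Da) and reports kDa.
`isoelectric_point()` solves net charge = 0 by **bisection on pH in
[0, 14] to a tolerance of 1e-4**, using the EMBOSS pKa set (N-terminus
8.6, C-terminus 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5,
Y 10.1).

## Relative expression (2^−ΔΔCt)

`relative_expression()` implements the Livak method with these
conventions:

* ΔCt is formed **per replicate** (target Ct − reference Ct within the
  same well group), requiring a complete pairing on (condition,
  timepoint, replicate); incomplete pairings are an error, not a silent
  drop.
* ΔΔCt = mean ΔCt(sample) − mean ΔCt(calibrator); RQ = 2^−ΔΔCt. The
  calibrator is a condition (optionally a condition × timepoint cell);
  with a single-timepoint calibrator, every other cell is calibrated
  against it, otherwise calibration is within-timepoint.
* Significance is a **Welch two-sample t-test** on replicate ΔCt values
  against the calibrator's (`**` at p < 0.01, `*` at p < 0.05, `ns`
  otherwise; `NA` for the calibrator cell itself or when replicates are
  too few).
* The standard error is kept on the **cycle scale**; error bars are
  reported as `2^−(ΔΔCt ± SE)`, which is asymmetric on the fold-change
  scale by design.

`primer_efficiency_filter()` applies the usual inclusive 90–105%
amplification-efficiency acceptance window.

## Synthetic-data generators

All generators are **pure functions of (spec, seed)**: they save the
global `.Random.seed`, reseed, and restore it on exit, so calling them
never perturbs user RNG state and equal inputs give equal outputs.

`simulate_family()` draws background residues from a packaged
composition table (so synthetic sequences have realistic residue
frequencies), then plants:

* three canonical EF-hands at configurable starts (default 40, 120,
  200), with the acidic anchors, bidentate loop-12 and loop donors
  written explicitly;
* group-specific N-termini: Gly-2 plus a canonical Cys (groups A, C,
  D), the group-D `E-E/D-P` signature at 16, the group-A acidic pair at
  31/33, and for group B the removal of Gly-2/Gly-7 and of all Cys in
  1–25.

Random background can by chance create **spurious windows** that pass
the strict rule, or overlap a planted hand and shift the greedy
selection. The generator therefore rescans each sequence and repairs any
window whose acceptance would change the scanner output, by mutating one
rule-bearing position of the spurious window **to leucine** — a residue
that can satisfy none of the scanner's checks and none of the
lipidation or N-terminal motif rules, so a repair can never create a new
signal elsewhere. Positions belonging to planted hands or planted
N-terminal motifs are never touched. The planted truth (`$truth`:
groups, hand starts, lipidation positions) is therefore exact by
construction, and the test suite verifies exact recovery.

`simulate_alignment()` plants a chosen number of segregating columns
(default two states per column) and reports the ground-truth `S` and the
exhaustively computed pairwise `π`. `simulate_trio()` emits a 3-member
block realizing requested counts of identical, unique-to-each-member and
all-divergent columns in shuffled order. `simulate_ct_table()` plants
fold changes as −log2(fc) shifts on ΔCt with Gaussian noise (default SD
0.1 cycles) on the target-gene Ct values.

The generators are **validation instruments, not fitted models**: they emulate
the combinatorial structure the analyses consume (rule positions, site
classes, ΔCt shifts), not evolutionary processes. They do not model
indels within analysed windows, correlated substitutions, codon-level
evolution, amplification-efficiency deviations from 100%, or
between-gene noise heterogeneity. Conclusions about the *analyses* (their
correctness on known truth) transfer; conclusions about biology do not.

## Numerical conventions and problem sizes

* Chi-square and t-test p-values come from R's `pchisq`/`t.test`
  (Welch); no continuity corrections.
* Oracle-equality checks in the suite use a tolerance of 1e-12;
  published-value checks use the precision at which the values are
  reported (2 decimals for χ², 5 for p, 6 for Θ, ±0.001 for D).
* Default sizes (e.g. 36-residue windows, 95% column coverage, three
  qPCR replicates, 90–105% efficiency window) are package choices that
  mirror common practice in family surveys; all are arguments, not
  constants.

## Limitations

* The EF-hand rule is positional and ungapped; hands with loop
  insertions or non-canonical geometries are out of scope.
* Lipidation calls are sequence rules, not physics: no surrounding
  context scoring, no enzyme-specificity model.
* Nomenclature depends on the supplied reference panels; with distant or
  incomplete references, the best-score ortholog number is a label, not
  an evolutionary claim.
* Tajima's D is computed from summary statistics under the standard
  neutral-model variance; it is not accompanied by coalescent
  significance simulation.
* The pipeline (`run_pipeline()`) orchestrates desk-scale inputs; it
  performs no multiple-sequence alignment or tree inference itself, and
  expects aligned input where alignments are required.
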