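---
title: "Models and methods behind misilk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind misilk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misilk)
library(dplyr)
```

`misilk` analyses the architecture of minor ampullate spidroin (MiSp)
genes — motif grammar, spacers, tandem repeats, paralog divergence — and
relates it to the mechanics of the silk fibers the proteins form. This
vignette records the models, the tunable parameters and the reasoning
behind the genuinely open design choices, in the spirit of a methods
section. Every empirical number quoted here is computed by the package's
tests or by `scripts/acceptance.R`; nothing is asserted that the code does
not itself reproduce.

## Coordinates and containers

All sequence annotations use a single convention: 0-based, half-open
`[start, end)` intervals, stated once here and used everywhere (FASTA
round-trips, motif tables, BED-like exports). Sequence sets are tibbles
(`id`, `alphabet`, `residues`); trees are `ape::phylo` objects; every
user-facing function takes a data frame first and returns a tibble, so
analyses chain with the pipe. Alphabet inference is deliberately
conservative — only unambiguous A/C/G/T/U/N counts as nucleotide, because
most IUPAC nucleotide ambiguity codes (S, T, V, W, …) are also amino
acids; declare `alphabet = "protein"` for short Gly/Ala-only peptides.

## The motif grammar

Spidroin repetitive regions are dominated by four words: `GGX` (any third
residue), `POLY_A` = A\_n with n ≥ 4, `GA_RUN` = (GA)\_n with n ≥ 2
(starting on G, a trailing lone G excluded), and `GPG`. `scan_motifs()`
performs, per class, a greedy left-to-right scan with maximal extension:
`AAAAA` is one poly-A of length 5, `GAGAGA` one (GA)-run of length 6.
Two open choices are resolved as follows and exposed in the interface:

- **Overlap within a class.** `GPGPG` counts one GPG, not two: greedy
  non-overlapping matching makes coverage a well-defined residue fraction.
  Different classes are scanned independently and may overlap.
- **Coverage denominator.** `motif_coverage()` uses the whole described
  sequence by default, terminal domains included, because the published
  per-species GPG percentages are proportions *of the protein*; a region
  argument restricts the denominator (e.g. to the repetitive region) when
  the alternative reading is wanted.

Percent rendering follows the convention of printed tables: round half
away from zero to two decimals (`format_percent()`).

Hydropathy profiles are centred Kyte–Doolittle window means with the
classic window of 7; positions whose window would run off an end are
omitted rather than padded, so a profile of length n has n − 6 points.

## Spacers and tandem repeats

**Spacers** are Ser/Thr/Val-rich, Gly/Ala-poor interruptions of the
repetitive region, originally assigned by eye in the literature; there is
no canonical boundary rule, so the detector is parametric and its defaults
are documented rather than claimed canonical. A window of 25 aa slides
over the non-terminal span (margins 150 aa N-terminal, 100 aa C-terminal —
typical spidroin terminal-domain lengths, configurable because real
termini are assigned by homology); windows with Gly+Ala fraction ≤ 0.25
are flagged, flagged starts within 5 positions merge, edges are trimmed by
a centred-window refinement, and boundaries then snap to the contiguous
non-Gly/Ala run (spacer flanks are Gly/Ala-rich, so this sharpens the
boundary to residue precision on clean flanks). Regions shorter than 15 aa
are dropped. `spacer_homogeneity()` reports mean pairwise
global-alignment identity — near-perfect values are the within-protein
homogenization signature expected under intragenic concerted evolution —
and returns `NA` for a single spacer, which has no pairs.

**Tandem repeats** use a bespoke seed-and-extend consensus detector.
Candidate periods are the spacings between consecutive occurrences of
recurring 4-mers (one attempt per period/phase pair); a candidate is
extended copy-by-copy in both directions while each new period-length
window matches the running per-column majority consensus at identity
≥ 0.70; a trailing partial copy counts fractionally; per-copy identity is
computed against the final consensus, not the first copy. Two numerical
safeguards matter:

- **Period-multiple degeneracy.** A 28-aa array also "explains" itself at
  period 56 with slightly smoothed consensus identity. A block whose
  consensus is itself periodic at a divisor — at least as strongly as the
  copies match the consensus — is re-extended at that divisor. The
  threshold ("at least as strongly") deliberately does *not* collapse
  genuine higher-order units: a 150-aa ensemble unit containing four 30-aa
  motif units plus one spacer folds onto 30 aa at only ~0.77 identity and
  is kept at 150.
- **Phase arbitrariness.** Seeds land anywhere inside a copy, so the
  reported interval may be rotated by part of one period relative to the
  planted truth; period and copy number are exact, intervals agree within
  one period, and the first copy may straddle a terminal boundary
  (identity then dips by up to ~2 residues/period). Tests assert the
  invariant actually promised, not byte-identical coordinates.

Overlapping blocks are resolved by the `copies × period × identity`
score. Defaults (period 5–600, copies ≥ 2, identity ≥ 0.70) are chosen so
the repeat ranges reported for real MiSp (periods ~7–569 aa, 2–28 copies,
identities 0.81–0.97) are representable. `classify_modularity()` encodes
the two organisational modes seen in MiSp — a higher-order unit
(period > 160 aa, strictly, repeated at least once more) versus arrays of
short units only (period ≤ 30 aa repeated > 10×).

## Alignment, distances, trees

Pairwise global alignment uses match +1 / mismatch −1, gap open −5 and
gap extend −1, where the *first* gap residue costs the opening penalty
(the optimisation is delegated to `Biostrings::pairwiseAlignment()` with
parameters remapped to that convention; a brute-force dynamic-programming
oracle validates scores in the tests). Printed divergence percentages of
real sequence pairs are alignment-parameter sensitive, so checks against
them carry a ±1 percentage-point band rather than exact equality.
`p_distance()` uses pairwise deletion (gap-containing columns excluded);
`alignment_identity()` counts gap columns against identity.

Neighbor joining is `ape::nj()` behind `neighbor_joining()` (input
validation, optional midpoint rooting for display) — on additive matrices
it recovers topology and branch lengths exactly, which the tests assert.
Reconciliation is implemented here: each gene node maps to the species-tree
LCA of its descendants' species; a node mapping to the same species node
as one of its children is a duplication; losses are counted along the
induced embedding (each gene edge contributes the species-path depth
difference minus one, plus one at duplication nodes). The loss count is
the standard embedding-based count, documented because published analyses
often report losses only qualitatively. A brute-force minimum over all
valid reconciliation maps (≤ 8 leaves) is the test oracle.

Independent contrasts follow Felsenstein's pruning exactly: contrast
(x₁ − x₂)/√(v₁+v₂), ancestral value the variance-weighted mean, parent
branch lengthened by v₁v₂/(v₁+v₂). Contrast regressions are always
through the origin. Adjusted R² is 1 − (1 − R²)(n − 1)/(n − 2) with an
intercept and 1 − (1 − R²)·n/(n − 1) through the origin.

**The five-species regression.** The compiled species table
(`minor_silk_species()`) contains every published row, including species
with multiple sources and illegible or missing cells as `NA`.
`species_regression_data()` selects one row per species with both a GPG
percentage and an extensibility value, taking the first-listed source
where several exist — the selection is a function argument, not a
hard-coded constant, because the choice among multiple published rows for
*N. clavipes* (and the partially legible *A. diadematus* row) is a
documented analysis decision. With the default selection the raw fit
gives adjusted R² = 0.526, p = 0.102 at n = 5. The corresponding
contrasts fit in the literature (adjusted R² = 0.92) used branch lengths
from three divergence-time studies that are not published as numbers; it
is therefore treated as a sensitivity-band quantity, exercised by
`pic_regress()` on user-supplied trees and by slope-recovery simulations,
not asserted as an exact target.

## Expression ratios

`assign_reads()` implements the contract of a best-single-hit aligner
without the aligner: every forward-orientation ungapped placement of a
read against every reference is considered (via escalating exact/mismatch
matching), the placement with fewest mismatches wins, ties go to the
first-listed reference and then the leftmost position — deterministic by
construction, since the true aligner's tie-breaking is undocumented.
Reverse-complement search sits behind a flag because the library protocol
is unknown. The 3′-window count includes reads overlapping the 3′-most
500 coding bases by at least half the read length (the published analyses
state no overlap rule; half-read overlap is symmetric and insensitive to
the read-length/window ratio). A zero denominator yields an undefined
ratio (`NA`), not an error, because empty libraries are data, not bugs.
At a simulated depth of 2 × 10⁴ reads with strong 3′ bias and a true 4:1
mixture, both whole-gene and window ratios land within binomial bounds of
4 (acceptance script: 4.14 and 4.10 at seed 1).

## Tensile mechanics

True strain is ε = ln(L/L₀), true stress σ = F·L/(A₀·L₀) under the
constant-volume assumption, with A₀ = π(d/2)². In the units used
throughout (µN, mm, µm) stress comes out directly in MPa, and ∫σ dε in
MJ/m³ — numerically equal to J/cm³, the unit silk toughness tables print.
Two quantities the source methods leave unstated are defaulted and
configurable:

- **Breakage rule**: the last sample before stress drops by more than 50%
  from its running maximum (the final sample if no such drop), with dips
  ignored while the running maximum is below 10% of the peak — otherwise
  instrument noise during load-up can mimic failure. Strength is read at
  that breakage sample (not the running maximum).
- **Modulus window**: least-squares slope of σ on ε for ε ≤ 0.02, inside
  the initial linear regime of silk.

Toughness uses the trapezoid rule to breakage; it converges to the
analytic integral (ratio within 10⁻³ at 10⁴ samples) and is exact for the
simulator's piecewise-linear curves because the strain grid includes the
yield point. The ANOVA is the one-way decomposition computed from sums of
squares (three groups of fifty fibers give the familiar df = (2, 147));
the full multivariate MANOVA statistic is out of scope since per-property
univariate F values are what fiber comparisons report. Tukey HSD uses the
studentized range with the harmonic mean of group sizes and a compact
letter display built from maximal cliques of the not-significantly-
different graph.

## What the simulators emulate — and what they do not

The generators define the study conditions for every validation:

- `generate_spidroin()` builds N-terminus (150 aa), a repeat array
  (default: 12 copies of a 30-aa unit drawn from a motif mix of
  (GA)\_n 0.45, GGX 0.35, A\_n 0.15, GPG 0.05 — the composition mode of
  theridiid MiSp, making Gly/Ala/Ser the top residues), spacers of 30 aa
  planted after copies 4 and 8, and a C-terminus (100 aa). Class draws
  are weighted by mix weight over mean instance length so a class's
  *residue share* tracks its weight. Substitution rates default to 0.05
  per site for repeat copies and 0.005 for spacers — spacers more
  homogeneous than repeats, the empirical signature. Back-translation
  biases third codon positions toward A/T with probability 0.7,
  mirroring observed spidroin codon bias.
- `evolve_family()` evolves the coding sequence down a species tree
  (per-site substitution 0.02 per unit branch length by default), with
  duplication at nominated nodes, Poisson-distributed gene conversion
  copying tracts between paralogs (terminal-encoding regions only when
  `terminal_only = TRUE`), and slipped-strand mispairing expanding or
  contracting the repeat region in 6-nt units. Every event is logged, so
  inference is always scored against construction, never against other
  pipeline output.
- `generate_reads()` draws start positions with weight exp(−decay · f),
  f the fractional distance from the 3′-most start; decay 10 puts > 90%
  of reads in the last quarter (the exponential CDF fixes that choice).
- `simulate_tensile()` inverts a bilinear true-stress curve (initial
  slope = modulus up to a 0.02 yield strain, then linear to the breakage
  point) back to force–extension, adds Gaussian force noise, and appends
  a post-break collapse; with zero noise the property derivation recovers
  all four parameters exactly.
- `simulate_bm_traits()` is plain Brownian motion, optionally generating
  a response trait y = βx + BM noise for slope-recovery experiments.

What passing these tests does *not* show about real data: the mutation
model is uniform substitution (no rate heterogeneity, no indels outside
slippage, no selection), terminal domains are random rather than
homologous, conversion tracts have fixed length, reads carry i.i.d.
errors without quality structure, and fibers are noiseless bilinear
idealisations. The validations therefore certify the *inference
machinery* — planted structure is recovered under the stated noise — not
the realism of any particular biological parameter value.

## Validation problem sizes

The shipped checks use: 1,000 random 200-mers for motif-scanner
equivalence with exhaustive enumeration; 100 seeded arrays (28 aa × 12
copies, ~10% per-copy substitution) for repeat recovery and 100 generated
spidroins for spacer recovery; 500 Brownian replicates on a 16-tip tree
for contrast-slope recovery; 2 × 10⁴ reads for ratio recovery; and 50
simulated families (25 with terminal-only conversion at rate 8 per unit
branch length, 25 without) for the concerted-evolution signature — sizes
at which each statistical bound is already tight while the whole suite
runs comfortably on a laptop.

## Known limitations

GenBank-dependent checks (published GPG percentages, ORF and divergence
anchors of specific accessions) require the user to supply the accession
FASTA files; the package deliberately ships no third-party sequence data,
so those tests report a missing-fixture failure until the files are
provided under `inst/extdata/genbank/`. The ORF scanner searches the
forward strand by default (deposited coding sequences are in coding
orientation; a flag enables the reverse complement) with a 300-nt minimum
to skip spurious short frames. The reconciliation does not implement
rearrangement-based or edge-weight-thresholded variants, and tree
*inference* beyond neighbor joining (parsimony, likelihood, Bayesian) is
intentionally out of scope — trees come in as data.
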