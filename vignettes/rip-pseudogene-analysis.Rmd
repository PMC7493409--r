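---
title: "Detecting RIP-mutated ITS pseudogenes: models, parameters and design choices"
author: "ripITS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RIP-mutated ITS pseudogenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripITS)
```

## The biological model

Repeat-induced point mutation (RIP) is a premeiotic genome-defence
process of filamentous ascomycetes. It recognizes duplicated DNA and
converts G:C pairs to A:T pairs — C→T on one strand, which reads G→A on
the other — at up to roughly 30% of the G:C pairs in a single passage
through the sexual cycle, with a strong preference for cytosines followed
by adenine (the CpA↔TpA context; TpG↔TpA is the same preference seen from
the opposite strand). When RIP catches part of the ribosomal DNA repeat
array, the result is an AT-biased, GC-depressed **ITS pseudogene** that
escapes the homogenizing force of concerted evolution and persists in the
genome alongside the functional copies.

`ripITS` implements the resulting analysis problem end to end: given
functional ITS sequences and candidate paralog amplicons from the same
individuals, decide which candidates are RIP pseudogenes, characterize
their mutation spectra and dinucleotide context preference, and describe
the population structure (haplotypes, composition, divergence, tree
behaviour) of functional versus pseudogene copies.

## Detection procedure and its assumptions

For each candidate the reference is the functional copy **from the same
individual** (when several functional clones exist, the one with the
highest GC content, consistent with the RIPCAL convention of treating the
most GC-rich sequence as the unmutated model). A reference policy flag
controls what happens for candidates whose individual has no functional
record: `"auto"` (default) falls back to the globally highest-GC
functional sequence, `"same-individual"` refuses, `"consensus"` always
uses the global consensus.

Query and reference are aligned globally (match +1, mismatch −1, gap
opening 5, gap extension 2 — Biostrings conventions, deterministic
traceback). Every mismatch column with unambiguous bases in both rows
becomes one mutation event; gap columns and ambiguity codes are excluded
from both the event list and the comparable-site denominator (pairwise
deletion throughout the package). Event types are `C->T`, `G->A` and
`other`; context classes are read from the *ungapped reference* strand —
the 3′ neighbour for C→T, the 5′ neighbour for G→A (its antisense face) —
so a neighbouring alignment gap cannot distort the context, and edge
positions with no neighbour are classed `nonRIP`.

A candidate is called a pseudogene when

* `n_CtoT + n_GtoA ≥ min_transitions` (default **3**), and
* `n_CtoT + n_GtoA ≥ dominance_ratio × n_other` (default **2**).

The absolute threshold guards against isolated sequencing or PCR errors;
the dominance ratio ensures the signal is specifically a transition
excess rather than general divergence. RIP-scale pseudogenes carry
dozens of transitions per 417-nt amplicon, so the defaults sit far below
the signal and far above the noise; both are exposed in every interface.
Two frequency denominators are reported because the field is ambiguous on
this point: per comparable site (`f_CtoT`) and per comparable reference C
or G site (`f_CtoT_perC`, `f_GtoA_perG`).

## Coordinates, regions and scope

All user-facing coordinates are 1-based inclusive on the ungapped
sequence. The `RegionMap` (ITS1, 5.8S, ITS2, plus the "amplified"
sub-interval covered by the pseudogene-specific internal primer pair) is
user-supplied; the documented default follows the 562-nt functional
reference layout used throughout the package — ITS1 1–218, 5.8S 219–376,
ITS2 377–562, amplified 96–512 (417 nt, missing 95 bp of ITS1 and 50 bp
of ITS2). Pseudogene amplicons lack the primer-external regions, so group
statistics and haplotype collapsing for pseudogenes are computed on the
amplified interval (the default `scope = "amplified"`); functional-copy
statistics use the full ITS. Both scopes are computable and labelled.

Haplotypes are classes of identical sequences. The default normalization
is case-insensitive, ignores alignment columns gapped in *all* members,
and compares ambiguity codes literally (`N` ≠ `A`) — the strict reading
of "identical sequences"; both switches are exposed because the
conventional tools do not specify this. Haplotype ids are assigned in
first-occurrence order, which makes outputs deterministic while the
partition itself is order-invariant.

## The population simulator

The generator produces the data structure the analysis assumes, with
ground truth, and its defaults are the study conditions the package
emulates:

| parameter | default | meaning / rationale |
|---|---|---|
| `nIndividuals` | 147 | five-province survey layout (88/23/18/14/4) |
| occurrence | 43 carriers, 0 in Yunnan | deterministic largest-remainder allocation; overall 29.25% |
| `nFunctionalHaplotypes` | 17 | functional radiation size |
| `functionalDivergence` | 0.006 | expected pairwise *p*-distance between haplotypes |
| `dominantShare` | 0.62 | frequency of the dominant haplotype; the rest equifrequent, so a 147-individual sample realizes ~17 distinct haplotypes |
| `severity` | 0.20 | fraction of G:C pairs mutated per RIP event; reproduces the observed GC depression (63% → ~51%) and a ~11–13% transition frequency, below the ~0.3 single-pass ceiling |
| `contextWeights` | 0.55/0.20/0.15/0.10 | CpA↔TpA-dominant preference |
| copies per carrier | truncated geometric, p = 0.35, on 1..8 | mean ~2.9 copies; the 1–8 range is the empirically observed support |
| `sharedOrigin` | `TRUE` | one ancestral RIP product propagated population-wide |
| `pseudoDivergence` | 0.022 | per-lineage neutral substitution rate among shared-origin copies; pairwise pseudogene *p*-distance ≈ 0.044 |

Mechanics worth knowing:

* **Site mutation probability.** Each C (and each G, the antisense C)
  mutates independently with probability `severity × w(class)`, where the
  four class weights are rescaled to **mean 1**. With uniform weights
  every eligible site therefore mutates with probability exactly
  `severity` — so `severity = 1` saturates every G:C pair, and realized
  counts are exactly Binomial(#GC sites, severity), which is what the
  binomial-oracle tests assert. Probabilities are capped at 1; edge sites
  without a neighbour take the unscaled severity and are recorded as
  `nonRIP`. Contexts are evaluated on the pre-mutation sequence
  (single-pass RIP), so the result is independent of mutation order; an
  explicit `multiPass` flag re-evaluates contexts between passes in
  position order.
* **Ancestor.** Drawn with an exact base composition at the target GC
  fraction (0.6313) rather than i.i.d., so the realized composition does
  not wander with the seed; the GC-rich 8-mer `CGCCCCGG` is planted at
  ITS1 positions 60–67 — outside the amplified window, so its deletion
  (the 554-nt length variant) never introduces indels into pseudogene
  comparisons.
* **Functional radiation.** Independent per-lineage substitutions at rate
  `divergence/2`, uniform over sites and target bases; no indels by
  default. The deletion variant is planted explicitly where needed.
* **Carriers.** `"deterministic"` mode fixes exact per-locality carrier
  counts by largest-remainder apportionment (so study-scale tallies like
  43/147 = 29.25% are reproduced exactly); `"bernoulli"` mode samples
  them.
* **Determinism.** The configuration seed drives everything; identical
  config gives byte-identical FASTA/TSV output, which the pipeline
  verifies by manifest checksums.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis relies on: a tight
functional radiation with a dominant haplotype, GC-depressed
context-biased pseudogene paralogs, variable copy number per carrier,
per-region presence/absence, and a shared or independent mutational
origin. It does **not** model coalescent demography, recombination,
selection, PCR/cloning artefacts, chimeras, or DNA methylation. Two
consequences deserve emphasis:

* Under shared origin the spec-level idealization of "neutral divergence
  among copies" spreads ~2% random substitutions per copy to reach the
  observed pseudogene divergence (~0.044). Real pseudogene divergence is
  itself RIP-dominated, so the simulated `f_other` (~2%) is higher than
  real surveys report (<1%); passing tests therefore validate the
  counting machinery, not the real-world ratio of transition to
  non-transition divergence.
* Under shared origin *all* copies inherit one ancestral event draw, so
  "which context class dominates" is a single-draw statistic with high
  variance. The context preference of the process is only identifiable
  from independent draws, which is why the acceptance script measures the
  RIPCAL ranking on an independent-origin simulation.

## Trees

Neighbor joining is implemented from the standard Saitou–Nei
formulation: join the pair minimizing
$Q(i,j) = (n-2)\,d(i,j) - R(i) - R(j)$, two-point branch lengths, final
three-point resolution. Ties in Q are broken toward the smallest (i, j)
index pair in the current node order, making topologies deterministic
even on degenerate (all-equal) matrices. Negative branch-length estimates
are clamped to zero and counted in the `clampedBranches` attribute.
Undefined distances (pairs with no comparable sites) are an error that
names the offending pairs. On additive matrices the implementation
reproduces the generating tree's path lengths to 1e-9, and it is
cross-checked against an independent NJ implementation in the test suite.

Monophyly is defined by explicit outgroup rooting (no midpoint rooting):
a tip set is monophyletic iff some edge of the unrooted tree bipartitions
it exactly against everything else. Bootstrap support resamples alignment
columns, rebuilds the *p*-distance matrix and NJ tree per replicate, and
reports the monophyly fraction; an alignment with no variable comparable
column yields `NA` (flagged) rather than a fabricated support.

A tree-level behaviour worth recording: with the default CpA-skewed
weights, *independently* RIP-ed copies still tend to cluster together
under NJ, because high-weight contexts mutate in most copies
(convergent homoplasy shortens pseudogene–pseudogene distances). Breaking
pseudogene monophyly requires flattening the context preference; the
regression fixtures pin one such scenario (uniform weights, severity
0.25, functional divergence equal to the outgroup distance) alongside a
shared-origin scenario at the same severity that stays monophyletic.

## Numerical choices and degenerate inputs

* Gap/ambiguity exclusion applies to GC content, *p*-distance and
  mutation frequencies alike; a sequence (or pair) with no usable site is
  flagged `NA`, never silently zero.
* Group GC content is the unweighted mean of per-sequence GC fractions
  (not pooled base counts); group divergence is the unweighted mean over
  all pairs — both switchable by computing on your own subsets.
* The alignment scoring (+1/−1, gap open 5, extend 2) is fixed and
  documented; gap placement follows the deterministic traceback, so a
  planted indel is localized to within its repeat-equivalence window
  (the length-variant report is validated by reconstructing the query
  from the reported edits).
* RIPCAL consensus ties (equal GC) resolve to the lexicographically
  smallest id. Dominant-class ties are reported as `"mixed"`, absence of
  RIP-type events as `"none"`.
* Percentages in reports carry the raw fraction alongside two-decimal
  rounding; rounding is presentation-only.

## Problem sizes

The shipped test-suite exercises the oracles at deliberately modest
sizes: haplotype equivalence against the quadratic identity oracle at
n = 200; binomial calibration of the mutation engine over 1000 seeded
replicates at 200 G:C sites; exact additive-matrix recovery for 3–8
taxa; detection recall/false-positive runs with 50–150 simulated
pseudogenes; and study-scale (147-individual) populations for the
occurrence arithmetic and the acceptance script. These sizes keep the
whole suite under a minute of compute per file while leaving every
statistical check well-powered.

## Known limitations

* Pseudogene detection requires a functional counterpart (or an explicit
  consensus policy); it cannot classify a lone divergent sequence.
* The caller is tuned for RIP-scale signals; weak, partial RIP (a few
  transitions in half a molecule) sits near the thresholds by design and
  should be reviewed via the per-region spectrum rather than the binary
  call.
* NJ is provided to study distance-based tree behaviour, not as a
  substitute for likelihood or Bayesian phylogenetics; no substitution
  model corrections are applied to the distances (*p*-distances only).
* The simulator's neutral-divergence idealization among shared-origin
  copies inflates non-transition divergence relative to real RIP
  pseudogene families (see above).
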