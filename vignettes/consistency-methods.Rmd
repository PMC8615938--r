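---
title: "Measuring secondary-structure consistency between homologs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring secondary-structure consistency between homologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssecons)
```

## What the package computes

Secondary structure prediction (SSP) is bounded above by how much the
secondary structures of homologous proteins actually agree, and bounded
below by the agreement of randomly paired, unrelated proteins. `ssecons`
measures both sides. The unit of computation is a pair of proteins with a
*residue correspondence* — a monotone pairing of positions from a sequence
alignment or an external (typically structural) alignment. The pair's
8-state DSSP strings are projected onto the corresponding residues and
compared at the residue level (Q3/Q8) and segment level (SOV3/SOV8,
v'99). Per-pair scores are aggregated by identity bins, families, folds
and random fold subsets.

Key assumption: the correspondence defines the residue support of every
measure. Both Q and SOV are computed over the same `n_e` equivalent
residues; unaligned residues contribute nothing to either numerator or
normalizer. This keeps the two measures comparable and makes the analysis
identical whether the correspondence came from the built-in aligner or an
external structural alignment.

## The Q measure

Q = 100 · n_c / n_e, where n_c counts corresponding positions with equal
codes after optional 8→3 reduction (H,G,I → H; E,B → E; S,T,C → C). A pair
with n_e = 0 has no defined score: it is flagged unscorable and *excluded*
from aggregation with a logged count, never scored 0 — a zero would be a
statement about the proteins, not about the missing alignment.

## SOV v'99: numerical choices

For each state, every overlapping observed/predicted segment pair
contributes len(s1) · (minov + δ)/maxov to the total, and len(s1) to the
normalizer N once per overlapping pair; observed segments with no
same-state overlap add len(s1) to N only. The allowance is

δ = min(maxov − minov, minov, ⌊len(s1)/2⌋, ⌊len(s2)/2⌋).

Choices that matter:

- **Integer floor in δ.** The half-segment caps use `⌊·⌋`. On the worked
  pair `HHHCHHHCHHHC` vs `HHHHHHHCHHHC` this yields 70.2; real-valued
  halves would yield 73.8. The floor variant is the v'99 definition and
  the one the package locks in (it is asserted exactly in the tests).
- **Orientation.** SOV is asymmetric: one string plays "observed" and
  normalizes the score. When scoring a prediction the observed string is
  the reference (`first_as_observed`). Homolog pairs have no natural
  roles, so pair scoring defaults to `symmetric_mean`, the mean of both
  role assignments, which restores invariance under swapping the pair.
- **Continuity breaks.** Segments are computed on the projected strings
  with a break wherever either side skips residues or crosses a chain
  break, so segments are never merged across unaligned stretches. Breaks
  split runs; two same-state segments can therefore be adjacent, and each
  is treated as its own segment by the overlap sums.

The implementation (vectorized over segment pairs) is cross-checked in the
test suite against an independent term-by-term evaluator on a thousand
random pairs per run.

## The aligners

Global and local affine-gap alignment are implemented as full dynamic
programming (a Gotoh three-matrix kernel in C++), with no heuristic
seeding — the limit that word-based search heuristics approximate as the
word size shrinks. Defaults: BLOSUM62, gap opening 11, extension 2.

- **Gap-cost convention.** A gap of length L costs open + ext·L by default
  (the BLAST reporting convention; a single-residue gap costs 13), with
  open + ext·(L−1) selectable (`gap_convention = "emboss"`). The 11/2
  penalties are conventional for protein search engines; the convention
  flag exists because published penalty pairs are ambiguous between the
  two readings.
- **Identity denominator.** Percent identity divides by all alignment
  columns including gap columns (BLAST convention); dividing by n_e is
  selectable. Identity definitions are rarely stated in benchmark work,
  so both are exposed and the default is recorded in run manifests.
- **Determinism and symmetry.** The DP optimizes lexicographically:
  score, then number of identical residue columns, then fewest columns,
  with residual ties broken by move precedence diagonal > gap-in-B >
  gap-in-A. The secondary objectives are not cosmetic: with a score-only
  tie-break, two optimal alignments with different identity can exist and
  the reported identity would depend on input order. The lexicographic
  optimum is a property of the alignment *set*, which is mirror-symmetric
  under swapping inputs, so score and identity are both symmetric — a
  property the test suite checks. The exhaustive-enumeration oracle in the
  tests confirms score optimality over every length combination up to 6.
- **Degenerate inputs.** Empty sequences and residues absent from the
  matrix are rejected; a local alignment with no positive-scoring pair is
  the empty alignment with score 0.

## Aggregation

Pairs are averaged with each pair's n_e as weight — the arithmetic mean
would let many small proteins swamp few large ones. Identity binning comes
in three kinds: half-open levels [e, e′) with a singleton bin at exactly
100 and an explicit underflow bin below the lowest edge; cumulative
thresholds (≥ e); and cumulative cutoffs (< e), the convention of
nonredundant dataset construction. Default level edges are 5-wide from 10
to 60 and 10-wide from 60 to 100. Pairs below the lowest edge stay visible
in the underflow bin rather than being silently pooled.

Fold values collapse a fold's pairs by the n_e-weighted mean. Reading
"protein size" weighting as the pair's aligned-residue count keeps the
fold collapse consistent with the pair-level weighting equations, which
define their weight explicitly as n_e; a mean-chain-length weight is
available as an alternative (`fold_weight = "mean_length"`). Repeat
statistics partition folds into k = 10 near-equal random subsets (seeded
shuffle), average each subset unweighted, and report mean and sample
standard deviation (k − 1 denominator) across subsets.

## The random-pairing lower bound

`random_pair_null()` samples distinct record pairs uniformly (with
replacement over pairs) and scores them after a projection. Unrelated
proteins have no meaningful alignment, so the default projection is prefix
truncation — position k against position k up to the shorter length —
which measures pure composition agreement; a global-alignment projection
is available and the mode is recorded in the output. For i.i.d. state
sequences the expected Q is 100 · Σ p², which the tests verify against
simulation (12.5% for uniform 8-state codes). SOV uses the symmetric mean.
Histograms are emitted at 1-percent resolution.

## The synthetic benchmark

The generator emulates what the analysis needs from curated structural
family data: groups of global homologs spanning a wide identity range
whose SSE divergence grows as identity falls, with exact ground-truth
correspondences.

- **Grammar.** Proteins are built from SSE segments; segment states are
  drawn with probability ∝ frequency / mean length so residue-level
  marginals match the configured frequencies (defaults approximate
  globular composition: H 0.30, G 0.04, I 0.01, E 0.21, B 0.01, S 0.08,
  T 0.11, C 0.24), lengths are truncated-geometric with per-state means
  (H 10, E 5, C 5, shorter for bends/turns/bridges), amino acids follow
  state-conditioned propensities, and per-residue RSA and normalized
  B-factor annotations are drawn state-dependently.
- **Divergence.** Sequence divergence (substitution probability
  1 − identity/100, with replacements drawn from the same state's
  propensities and never equal to the original; geometric indels) is
  parameterized independently of SSE divergence (segment boundary shifts
  and whole-segment state flips), so tests can isolate alignment error
  from genuine structural difference. Measured identity on the true
  correspondence is unbiased for the target by construction.
- **Schedule.** The default spans six levels, 95% down to 25% identity,
  with boundary-shift probability rising 0.02 → 0.40 and flip probability
  0 → 0.14 — chosen once as a plausible emulation of the empirical
  identity–consistency relationship, and deliberately not calibrated to
  any published curve. Three families per level, four members each
  (member 1 is the parent; other pairs' true correspondences are composed
  through shared parent positions), each family its own fold.

What passing tests on this benchmark do *not* show: real families are not
star-shaped around a parent, real SSE divergence is not independent of
sequence divergence, segment lengths are not geometric, and real
correspondence error is structural-alignment error, not composition
noise. The benchmark validates the machinery and its invariants, not the
numerical value of any real-data limit.

## Problem sizes

The shipped analysis and test runs use desk-scale sizes chosen to exercise
every code path: the default benchmark is 72 records / 108 pairs; the
alignment oracle covers every length pair up to 6×6 over a 4-letter
alphabet; the SOV oracle runs on 1000 random pairs up to length 40; the
analytic null uses 10,000 pairs over 250 records per state model (20,000
pairs in the analysis script); identity recovery uses 50 replicates of a
300-residue parent at four target identities.

## Known limitations

- DSSP parsing supports the classic fixed-column layout only; records
  reflect the file as given (no re-assignment of π-helices across DSSP
  versions, whose effect on consistency statistics is negligible at this
  scale).
- Homolog-pair discovery (database search, E-value filtering) is out of
  scope: pair eligibility is an input concern, via family labels or
  explicit pair lists.
- Per-state conservation conditions on the observed string's state only;
  conditioning on both sides' states would be a confusion-matrix analysis
  the package intentionally leaves out.
- The aligners are quadratic full-matrix DP — correct and deterministic,
  not engineered for proteome-scale all-vs-all runs.
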