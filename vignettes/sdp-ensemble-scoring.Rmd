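---
title: "Group-specific SDP scoring over sub-sampled alignment ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-specific SDP scoring over sub-sampled alignment ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpensemble)
library(dplyr)
```

## The problem

In a protein family whose members have diverged in function — different
ligands, different DNA operators, different allosteric logic — specificity
is encoded by a modest number of *specificity determining positions* (SDPs):
alignment columns conserved *within* each specificity group (an ortholog
set, all orthologs of one family member) but to *different* residues
*between* groups. Classical SDP methods assign one score per column,
implicitly assuming every group uses the position. In diverse families that
assumption fails: positions acquire and lose specificity roles along
different lineages, so many positions are conserved in some ortholog sets
and drifting neutrally in others ("partial SDPs"). A single column-wide
score both misses these positions (false negatives, when degenerate groups
dilute the signal) and over-calls them for groups in which the position is
degenerate (false positives).

A second, independent problem is alignment uncertainty. With pools of a
thousand or more homologs, any single multiple sequence alignment (MSA) is
both slow to build and error-prone, and per-column statistics inherit those
errors silently. `sdpensemble` addresses both problems together:

1. **Sub-sampled alignment ensembles.** Instead of one comprehensive MSA,
   the pool is repeatedly sub-sampled (200 sequences per draw, allocated
   across ortholog sets proportionally to set size, clamped to 8–13 per
   set), each sub-sample is aligned together with a fixed reference
   sequence (201 rows per alignment), and all column statistics are
   aggregated by reference position across the ensemble (5000 replicates in
   the default protocol). The spread of a statistic across replicates
   measures its sensitivity to alignment variation.
2. **Group-specific, noise-filtered scores.** Every column receives one
   score *per group*, built from a support-filtered conservation contrast
   (below), so a position can be an SDP for some family members and not for
   others.

## Column statistics

All statistics build on the identity-matrix comparison
`comp(a, b) = 1` iff `a` and `b` are the same canonical amino acid.
Gaps and ambiguity codes (X, B, Z, U, O) compare 0 to everything,
*including themselves*: a gap carries no evidence of identity, which also
makes heavily gapped groups degenerate — consistent with the method's
intent. For a column with groups \(g_1, \dots, g_k\):

- **Group conservation** \(c_g\): the mean of `comp` over all unordered
  pairs of distinct sequences in \(g\) (for a group of \(n\) sequences,
  \(\binom{n}{2}\) pairs).
- **Group-wise conservation**: the unweighted mean \(\bar c = \frac1k \sum_g c_g\).
- **Between-group agreement** \(\bar a\): for each unordered pair of
  groups, the mean of `comp` over all cross pairs; then the unweighted
  mean over group pairs. Unweighted means are used throughout so that
  groups of unequal sampled size contribute equally.
- **SDP signal** (GroupSim-style): \(\bar c - \bar a\). It is maximal (1)
  when every group is fixed to its own distinct residue, and 0 both for a
  globally conserved column (\(\bar c = \bar a = 1\)) and a fully
  degenerate one (\(\bar c = \bar a = 0\)).

The **support set** \(S\) of a column is the set of groups with
\(c_g \ge 0.6\) (inclusive), decided *per alignment column of each
replicate*. With \(|S| \ge 2\), the noise-filtered contrast is

\[ C = \bar c_S - \bar a_S , \]

the group-wise conservation and between-group agreement restricted to
support groups, and the **group-specific score** of group \(g\) is

\[ \mathrm{score}(g) = W_g \, C, \qquad
   W_g = \begin{cases} 1 & g \in S \\ c_g & \text{otherwise.} \end{cases} \]

Restricting the contrast to \(S\) removes the noise contributed by
degenerate groups (which otherwise drag \(\bar c\) down and hide signal);
the weight then re-introduces each group's own evidence, so degenerate
groups get proportionally small scores rather than inheriting the support
groups' signal. When fewer than two groups are in support, the
between-group agreement over \(S\) is undefined (it needs a pair of
groups), so every score is 0 and the record is flagged
(`support_defined = FALSE`).

Because the mean of the values \(\ge 0.6\) can never be smaller than the
mean over all groups, \(\bar c_S \ge \bar c\) in every single replicate —
the rightward shift of positions in conservation–agreement space that
motivates the filter. `project_positions()` exposes both projections.

## Ensemble aggregation

Scores are averaged (unweighted arithmetic mean) over replicates per
(reference position, group). Averaging over the ensemble accounts for
heterogeneity in a group's conservation: a group conserved at a position in
every replicate scores higher than one conserved in only a fraction of
replicates — the closed form for a group in support in a fraction \(f\) of
replicates with constant contrast \(C\) and off-support weight \(w\) is
\(C(f + (1-f)w)\), which the tests verify against direct simulation.
Distribution summaries (median, quartiles, middle-95% band) use linear
interpolation between order statistics (`quantile` type 7) so they are
bit-reproducible.

A position is called **heterogeneously conserved** when at least 6 groups
have ensemble-mean conservation strictly greater than 0.6 and at least 6
others strictly less than 0.5. Note the deliberate asymmetry: support
membership is *inclusive* at 0.6, the heterogeneity call *strict* above
0.6. The two rules are stated that way in their respective definitions and
are kept distinct here rather than unified.

SDP calls are percentile-based: `rank_top(scores, f)` returns the
`floor(f * N)` highest-scoring keys (ties broken by position, then group,
for determinism), with `f` = 0.075, 0.05 and 0.01 surfaced as flags by the
pipeline. On 360 per-position scores, `f = 0.075` selects exactly 27.

## Sampling protocol and reproducibility

`allocate()` apportions the 200-sequence sub-sample across ortholog sets
proportionally to set size with clamping at 8 (to avoid small-number
effects in \(c_g\)) and 13 (to stop large sets from dominating). The exact
integer apportionment is not fully determined by those constraints, so the
package fixes it: clamped largest-remainder, implemented as a greedy that
minimizes \(\sum_i |n_i - \text{ideal}_i|\) subject to the bounds (the
per-set objective is convex, so unit-step greedy is optimal), with
deterministic tie-breaks (most-below-ideal, then larger set, then set
name). Properties guaranteed and tested: counts sum to the total, bounds
hold, permuting set order changes nothing, and a strictly larger set never
receives fewer draws. Allocation is computed once per pool; only the
within-set draws are random.

Replicate \(i\) (1-based) draws with seed `base_seed + i - 1`, so any
replicate can be replayed in isolation, and reruns with the same
configuration are byte-identical. The reference sequence is appended last
to every sub-sample (201 rows), is never drawn from the sets, and is
withheld from all column statistics; it serves only to map alignment
columns to reference positions (the k-th non-gap reference character is
position k, 1-based). Columns where the reference holds a gap cannot be
keyed to a position and are dropped from aggregation; their per-replicate
counts are kept in the `dropped_columns` attribute for diagnostics.

Alignment is delegated to an external aligner through a command template
(default: MAFFT L-INS-i); any tool that reads FASTA and writes aligned
FASTA can be substituted, and `score_ensemble()` accepts pre-aligned
replicates so scoring never requires an aligner.

## Pool curation

`curate_pool()` implements the supplementation rule used to extend ortholog
sets from external sequence collections: a candidate joins set \(S\) iff its
identity to *every* member of \(S\) is at least 0.35 (inclusive) and its
*minimum* identity within \(S\) strictly exceeds its identity to every pool
sequence outside \(S\); sets with fewer than 20 members are then dropped.
Both rules are evaluated against the pre-supplementation pool, which makes
the result independent of candidate order (tested). Pairwise identity is
not fully specified by the rule itself, so the package fixes a convention:
global alignment (BLOSUM62, gap opening 10 / extension 0.5), identity =
identical pairs divided by the full alignment length *including* gap
columns — the most conservative and symmetric of the common denominators.

## The synthetic-data generator

`generate_pool()` builds pools with planted column archetypes and known
ground truth, so every pipeline stage is testable without downloads or an
aligner:

- `GLOBAL_CONSERVED` — one residue everywhere (signal 0);
- `IDEAL_SDP` — one distinct residue per group (signal 1 for every group);
- `NEUTRAL` — independent uniform residues (degenerate);
- `PARTIAL_SDP` — distinct residues for a chosen support subset, uniform
  drift for the rest (support groups score \(C\), the rest \(c_g C\));
- `SHARED_SDP` — one residue shared by a subset of groups, distinct
  residues for the rest (all groups conserved, agreement elevated; with 4
  of 6 groups sharing, every group scores exactly \(1 - 6/15\)).

Substitution noise replaces a planted residue with a uniform draw from the
other 19 canonical residues, independently per sequence and position — the
simplest model with the needed statistical structure (purifying selection
vs. drift). Fixture sequences are equal-length and gap-free, so the true
alignment is the identity and the exact archetype scores can be computed by
hand. Alignment uncertainty is emulated by *column jitter*: with a given
probability per (replicate, sequence), one residue is misplaced — its
column gapped for that row and the residue moved to an overflow column
appended to the alignment (a reference-gap column, hence dropped from
aggregation). This perturbs the content of exactly one mapped column per
affected row while preserving row content as a multiset.

What the generator does *not* emulate: phylogenetic correlation between
sequences (no trees, no rate matrices), indel processes, compositional
bias, or realistic aligner error (jitter is local and independent).
Passing recovery tests on these fixtures therefore demonstrates the
correctness and robustness of the *scoring and aggregation machinery*, not
performance on real families, where group definitions, alignment quality
and conservation heterogeneity are all harsher.

## Numerical and design choices

- **Pairwise conservation convention.** The strict-pair form of group
  conservation (\(\binom{n}{2}\) distinct pairs) is the default. Under it,
  six identical residues of eight give \(15/28 \approx 0.536\), just below
  the 0.6 support threshold; under the self-inclusive convention
  (\(\binom{n+1}{2}\) pairs) the same pattern gives \(23/36 \approx
  0.639\), just above. Both conventions circulate in the field's
  informal descriptions; the package implements the strict-pair form and
  exposes `conservation = "self-inclusive"` as a switch rather than
  guessing intent.
- **Degenerate columns** (all gaps, single support group, empty support)
  are scored, flagged, and retained — output tables always have one row per
  position (support-only projections emit an `NA` sentinel with
  `n_defined = 0` instead of dropping the position).
- **Problem sizes.** The test suite and the acceptance script run the full
  protocol constants (200/201/8/13) on a synthetic 20-set, 1814-sequence
  pool shape for the allocation checks, and scale the stochastic recovery
  study to 20 groups x 30 sequences, 100 positions, 50 jittered replicates
  — sizes chosen so the planted structure is comfortably detectable while
  a full run stays in the seconds-to-minutes range on one CPU. The planted
  recovery fixture plants exactly 100 (position, group) pairs — ten partial
  SDPs with support sizes 6–10 plus one ideal SDP — matching the top-5%
  slot count of a 100 x 20 score table, so recovery is checked as an exact
  set identity: all planted pairs in the top 5%, no planted-degenerate
  group among them.

## Known limitations

- Group definitions are taken as given; the package neither infers ortholog
  sets nor optimizes groupings for SDP signal.
- Only the identity matrix is supported for `comp`; similarity-weighted
  comparisons (e.g. BLOSUM-weighted) are out of scope.
- Positions whose SDP-like pattern includes high between-group agreement
  (many groups conserved to the *same* residue) receive low scores by
  construction — the contrast penalizes agreement — and are better examined
  through the `SHARED_SDP` composition tables than through the ranking.
- The ensemble treats replicates as exchangeable; there is no modeling of
  systematic aligner bias shared by all replicates.

## A worked example

```{r example, eval = FALSE}
library(sdpensemble)
library(dplyr)

groups <- sprintf("G%02d", 1:6)
ap <- archetype_plan(30)
ap$kind[10] <- "IDEAL_SDP"
ap$kind[20] <- "PARTIAL_SDP"; ap$support[[20]] <- groups[1:3]
ap$noise <- 0.05
sim <- generate_pool(setNames(rep(25L, 6), groups), ap, seed = 7)

plan <- allocate(pool_set_sizes(sim$pool), total = 60, min_per_set = 8, max_per_set = 13)
msas <- generate_prealigned_ensemble(sim$pool, n_replicates = 25,
                                     column_jitter = 0.1, base_seed = 7, plan = plan)
ens <- msas |> score_ensemble() |> aggregate_ensemble()

glance(ens)
tidy(ens) |> arrange(desc(mean_score)) |> head(10)
rank_top(ens$scores, 0.05)
autoplot(ens)
```
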