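---
title: "Methods: de novo family discovery and lipase screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo family discovery and lipase screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipofam)
```

## The problem

Most protein sequences in metagenomic datasets cannot be assigned a
function by homology, and purely homology-based screens discard exactly
the families that are most likely to contain novel biocatalysts. `lipofam`
implements a discovery strategy that works from the opposite direction: it
*removes* everything that known domain profiles can explain, organizes the
unexplained remainder into protein families de novo, and then screens one
representative per family for the sequence architecture of a target enzyme
class — here, lipolytic enzymes (esterases and lipases), whose active site
is a Ser–Asp/Glu–His catalytic triad with the nucleophilic serine on a
conserved "catalytic elbow" (a G-x-S-x-G-type motif, first glycine
substitutable by alanine) and one of three oxyanion-hole variants (GX,
GGGX, Y). The package also implements the kinetic calculations used to
characterize an enzyme once found: Michaelis–Menten constants via the
double-reciprocal (Lineweaver–Burk) fit, specificity constants, relative
chain-length activity, Gaussian interpolation of temperature/osmolarity
optima, and enantiomeric-ratio calculations for kinetic resolutions.

## Pipeline stages and their parameters

`run_discovery()` executes the stages in a fixed order; each is exported
on its own so the funnel can be inspected stage by stage.

1. **Subtraction** (`filter_annotated()`): a sequence with a domain hit at
   E-value ≤ `annotation_evalue_max` (default `1e-5`) is "annotated" and
   removed. Domain hits come from a HMMER3 `--tblout` file via
   `parse_tblout()`, which keeps the lowest-E hit per (sequence, model)
   pair. The `1e-5` default is the reporting threshold of the original
   screen; hits up to the `1e-3` inclusion threshold merely pass through
   the adapter without triggering subtraction.
2. **Redundancy reduction** (`hierarchical_reduce()`): greedy incremental
   identity clustering at 90%, then 75%, then 60%. Identity is the CD-HIT
   convention: optimal global alignment (match +1, mismatch 0, linear gap
   −0.5 per gap column), identical aligned columns divided by the shorter
   length. Records are processed longest first, ties by id, so every
   cluster representative is its longest member and the pass is
   deterministic. A first-level representative that is a singleton at
   *every* level never co-clustered with anything and is discarded; this
   is the more permissive of the two readings of the discard rule, chosen
   because discarding at the 90% level alone would remove nearly every
   moderately diverged sequence.
3. **Similarity graph** (`all_vs_all_scores()`): Smith–Waterman local
   scores (BLOSUM62, gap open 11 / extend 1, via Biostrings) converted to
   bits with fixed gapped Karlin–Altschul constants (λ = 0.267,
   K = 0.041). How the original BLAST-derived "similarity distances" were
   weighted is not specified anywhere we could follow, so bit-score
   weighting is this package's documented choice. Edges below
   `weight_floor_bits = 25` are dropped; empirically, unrelated random
   sequences of length 80–200 score 14–25 bits, so the floor sits just
   above the random background.
4. **Markov clustering** (`mcl()`): from-scratch dense-matrix MCL.
   Self-loops get the maximum incident edge weight (1 for isolated nodes),
   columns are normalized, and the process alternates expansion (matrix
   square) with inflation (entrywise power `1.4`, renormalize), pruning
   entries `< 1e-5`, until the maximum column change is below `1e-8` or
   200 iterations. Attractors (positive diagonal) and their support define
   clusters; nodes claimed by several attractor systems go to the one with
   the largest mass on them, ties to the smallest family id. Inflation
   `1.4` is the study condition; self-loop and pruning choices follow the
   canonical MCL recommendations.
5. **Size filter** (`filter_families()`): families with fewer than
   `min_family_size = 11` members ("more than 10 sequences") are removed
   and survivors renumbered by decreasing size, ties by smallest member
   id.
6. **Representatives** (`select_representative()`): within each family,
   pairwise distances are one minus the shared-6-mer fraction (distinct
   6-mers in common over the smaller distinct-6-mer count, the k-tuple
   statistic guide trees are built from; members shorter than 6 residues
   fall back to alignment identity). The representative minimizes the row
   sum of that matrix, ties to the smallest id. Whether "total distance"
   should be measured on the raw k-tuple matrix or along the UPGMA guide
   tree is ambiguous in the source narrative; both are implemented
   (`mode = "matrix"` is the default, `mode = "tree"` uses cophenetic
   path distances) and they agree in rank for clique-like families.
   `upgma()` exposes the guide tree itself (via `stats::hclust`
   average linkage and `ape` for Newick output).
7. **Motif screen** (`screen_representatives()`): the three superfamily
   regular expressions, embedded verbatim apart from stripping a
   typesetting space inside two alternations (a literal space can never
   occur in a protein sequence, so keeping it would make those branches
   dead). Gap quantifiers are matched lazily and the leftmost match is
   reported; existence of a match — the screening criterion — is
   unaffected by greediness. Matches are reported with 1-based inclusive
   coordinates (the R/Bioconductor convention) together with the absolute
   positions of the catalytic nucleophile, the acidic residue, and the
   histidine.
8. **Confirmation gate** (`confirm_candidates()`): a motif hit is
   confirmed when its best profile E-value is ≤ `confirm_evalue_max`
   (default `1e-5`). External HMMER tblout results take precedence when
   supplied. The built-in scorer is an ungapped position-specific scoring
   model (`build_pssm()`: per-column counts plus `pseudocount ×
   background`, log-odds against the background; columns more than 50%
   gapped are dropped) scored by the best gapless segment
   (`score_sequence()`), with E-values calibrated empirically
   (`calibrate_evalue()`): `n_shuffles ≥ 100` random sequences at the
   median target length are scored, a Gumbel distribution is fitted by
   maximum likelihood, and `E(s) = db_size · exp(−λ(s − μ))`. This is
   deliberately *not* a plan7 profile HMM — no insert/delete states — and
   it makes no attempt to reproduce HMMER E-values numerically; it is a
   self-contained gate with the same contract, and the tblout adapter
   covers real HMMER use. Null sequences are drawn from the scored
   database's background composition rather than a uniform one, because
   compositional bias otherwise inflates false positives. When no profile
   source is supplied, `run_discovery()` skips the gate and carries all
   motif-hit representatives forward as candidates.

One threshold note: the source material states the annotation cutoff
inconsistently in different places (both "below 10^-5" and "above
10^-5" phrasings occur). The package resolves this as: annotated (and
confirmed) means best E ≤ 1e-5, which matches the direction in which
E-values measure significance.

## The synthetic metagenome generator

`generate_metagenome()` builds desk-scale datasets with known composition:
a set of planted families, each grown from a random ancestor (average
amino-acid background composition) as a star topology —
`generate_family()` mutates the ancestor at `round((1 − within_identity) ×
length)` positions per member, with substitutions drawn from a
BLOSUM62-biased distribution — plus background singleton decoys, shuffled
together with a covering truth table. Optionally a superfamily active-site
block is written into the ancestor; its pattern-constrained positions are
protected from mutation, so planted positives are guaranteed positives.
`evaluate_recovery()` scores a recovered partition against truth with the
adjusted Rand index (background decoys count as singleton classes;
computed over the ids present in the partition, via `mclust`), per-family
best-match precision/recall, and the fraction of representatives carrying
their family's majority truth label.

What the generator emulates: mutually divergent families with tunable
internal divergence, background decoys with realistic residue composition,
and motif-bearing candidates. What it does not emulate: sequencing error,
ORF fragmentation and partial proteins, length variation within a family,
phylogenetic (tree-like) within-family structure, and compositional bias
of real ocean metagenomes. Passing tests therefore demonstrate the
pipeline's internal correctness and its behaviour under controlled
divergence, not performance on real survey data.

**A consequence of the star parameterization worth knowing about.**
`within_identity` fixes each member's identity *to the ancestor*. Two
members mutated independently at a fraction `1 − w` of their positions
share, in expectation, only about `2w − 1` of their positions (plus a few
percent of coincidental matches). The redundancy-reduction ladder retains
a sequence only if it co-clusters with another at 60% identity or better,
so planted families with `within_identity` below roughly 0.75–0.78 have
member-to-member identities under the 60% floor and are discarded
wholesale before clustering ever sees them. This is faithful behaviour of
the reduction rule, not a defect of the clustering: the end-to-end test
over families spanning within-identity 0.65–0.90 documents it — families
above the threshold are recovered cleanly (partition agreement with truth
ARI > 0.95, no two planted families merged, representatives carrying the
right labels; a lone background decoy can occasionally attach to a family
through a chance alignment just above the edge floor), families below it
vanish at the reduction stage. Real
surveys are affected analogously: a protein family whose members have
diverged below the 60% pairwise floor will not survive a
redundancy-reduction ladder that discards sequences unmatched at all
levels.

## Numerical choices and degenerate inputs

- `X` residues are accepted on input but never count as identical in
  alignments, match only `.` in the regular expressions, and score the
  background-expected column value in the PSSM.
- Ties are broken by lexicographically smallest id everywhere a choice is
  otherwise arbitrary (cluster joining order, representative selection,
  attractor assignment), so results are reproducible across runs and
  platforms.
- Empty survivor sets are not errors: a screen legitimately returns zero
  candidates, and `write_tables()` then emits header-only artifacts.
- Nonlinear fits (`fit_mm_nonlinear()`, `gaussian_optimum()`) use
  `stats::nls` with a convergence scale offset so that exact
  (zero-residual) data converges; the Michaelis–Menten fit is initialized
  from the Lineweaver–Burk estimates and falls back to them (flagged)
  if the optimizer fails.
- Units are fixed once: concentrations in µM, rates in µM/min, `kcat` in
  s⁻¹ (`kcat = Vmax / (60 · [E])`), specificity `kcat/Km` in M⁻¹s⁻¹.
  Significant-figure rounding is applied only at reporting time.
  Published turnover numbers are used as given when reproducing
  specificity constants; they are not recomputed from `Vmax/[E]`, which
  would not reproduce them.
- All randomness (synthetic data, null calibration) flows from explicit
  integer seeds; calibration and generation are bit-reproducible given
  the seed.

## Problem sizes used by the test suite

The test suite exercises the full pipeline on a metagenome of 20 planted
families (15–40 members each, within-identity spanning 0.65–0.90, lengths
80–200) plus 400 background decoys — roughly a thousand sequences, which
the pipeline processes in a few minutes on one core. Motif screening is
validated on 36 planted carriers and 1,000 background sequences; oracle
equivalence for MCL runs on 50 random graphs of up to 8 nodes; kinetic
fits are validated on the published substrate grid (5–333 µM, seven
concentrations) and by Monte-Carlo noise studies with 100–200 replicates.
These sizes were chosen as the smallest at which every contract is
meaningfully exercised.

## Known limitations

- The greedy reduction is quadratic in the number of sequences; the
  package targets desk-scale datasets (thousands of sequences), not
  full-survey scale (millions). No distributed or out-of-core mode is
  provided.
- The MCL implementation is dense; graphs are expected to fit in memory.
- CD-HIT's accelerated heuristics (short-word filters, banded alignment)
  are intentionally not reproduced; identity here is exact global
  alignment, which CD-HIT only approximates.
- The confirmation gate is model-agnostic: no lipase profile library is
  bundled, and users supply either their own alignments (for
  `build_pssm()`) or HMMER results.
- The enantiomeric-ratio equations assume an irreversible, uninhibited
  kinetic resolution; outside that regime (e.g. product inhibition) the
  reported E is only apparent.
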