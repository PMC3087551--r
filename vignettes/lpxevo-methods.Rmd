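---
title: "Models and methods behind lpxevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lpxevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lpxevo` reconstructs the evolution of the nine-enzyme Kdo2-lipid A
biosynthesis pathway from annotated proteomes: detect the Lpx/Waa
families, separate paralogous subfamilies, build trees, and place gains,
losses, duplications, clusters and fusions. This vignette explains the
models the package implements, the tunable parameters and their
defaults, what the synthetic generator does and does not emulate, and
the numerical choices a maintainer would want to know about.

## Detection statistics

**Pairwise stage.** Candidate family members are found by exact
affine-gap Smith-Waterman (BLOSUM62, gap open 11, extend 1 by default; a
length-k gap costs `open + k·ext`). Significance follows Karlin-Altschul
statistics, `E = K · m · n_eff · exp(-λS)`, with one deliberate
convention: `n_eff` is held constant at the average query length (320
aa) times a constant genome size (20,000 genes), i.e. 6,400,000, so
E-values are comparable across genomes of different sizes. λ and K are
estimated by a maximum-likelihood Gumbel fit to gapped scores of 2,000
random-pair alignments of length 320 (for gapped alignment these
parameters have no closed form; the Gumbel location/scale map to K and λ
through `μ = ln(K m n)/λ`, `β = 1/λ`). The cutoff is E ≤ 0.01; an empty
hit list is the "no hit" state. Orthology is by reciprocal best hits
from a reference genome, with a retention rule for paralogs: every hit
at E ≤ 0.01 whose own top hit back in the reference genome is a member
of the family is kept. That rule is what lets duplicated copies (the
LpxL types, LpxM) survive the reciprocity filter.

**Profile stage.** Each family found by the pairwise stage seeds a
profile HMM: alignment columns with residue occupancy ≥ 0.5 become match
states; emissions and transitions take fixed-weight background
pseudocounts (`(count + w·bg)/(n + w)`, w = 1); the topology is local,
with uniform entry `B→M_k = 1/m` and exit `M_k→E = 1/(m-k+1)` so every
outgoing distribution sums to one. Scores are forward log-odds in bits
against a free-flanking background model, so the reported score sums
over all alignments (Viterbi, the single best path, is also available
and is never larger).

E-values for forward scores again use a constant trial count, 20,000
candidate sequences per genome-equivalent: `E(S) = 20000 · P(score ≥ S)`.
The survival law is a Gumbel whose **scale is fixed at 1/ln 2** and only
the location is fitted, anchored so the fitted tail matches the
empirical 95th percentile of ≥ 500 calibration scores on random
sequences. The scale is not a free parameter for a principled reason: a
forward score is log2 of a sum of likelihood ratios whose expectation
under the background is finite, so the null tail decays at most like
`2^-score`. A free two-parameter fit estimates the much steeper slope of
the score bulk and then wildly under-covers the deep tail where the 0.01
cutoff lives; the fixed-slope anchored fit is mildly conservative there
instead (measured: zero false detections in 50 × 20,000 null searches
where an accurate calibration would allow ~0.5). Conservative E-values
cost a few bits of sensitivity at the margin and guarantee the
false-positive budget.

Detection evidence is pooled: a family is present in a genome if either
stage reports it; cells supported only by the profile stage keep an
"HMM" provenance flag but count as present.

## Phylogenetics

Multiple alignments are progressive: a guide tree from fractional shared
3-mer counts (average-linkage clustering), then profile-profile
alignment up the tree under the same substitution matrix and affine gap
costs (two sequences therefore reproduce the global Needleman-Wunsch
optimum exactly). Distances are p-distances over mutually ungapped
columns, optionally Poisson-corrected (`-ln(1-p)`); saturated pairs
(p ≥ 1) are flagged rather than clamped. Trees come from neighbor
joining with two deterministic rules: Q-criterion ties break on the
lexicographically smallest label pair, and a negative branch-length
estimate is clamped to zero with the deficit moved to its sibling so
path lengths are preserved. Bootstrap supports resample columns with
replacement (default 1,000 replicates) and report, per internal
bipartition of the point tree, the percentage of replicate trees
containing it.

Likelihood is used for scoring, never for topology search: Felsenstein
pruning under a reversible model (equal-rates or WAG) with
discrete-Gamma rate heterogeneity (k = 4 equal-probability categories,
category means; k is a convention, not estimated). The pruning value is
invariant under re-rooting, which the tests exploit. Topology search by
maximum likelihood is deliberately out of scope: in this pipeline the
tree is a scaffold for event inference, and NJ plus likelihood scoring
keeps every downstream contract testable at desk scale.

For the genome phylogeny six families are concatenated (LpxA, LpxC,
LpxD, LpxB, WaaA, LpxL), one row per genome; a missing gene contributes
a gap block, and where a genome carries several copies one is kept — by
default the copy with the highest family-profile forward score.

## Subfamily classification

The metallophosphoesterase signature is scanned as an ordered five-block
pattern `D - GD - GN[HR](E/D) - H - GHXH` with variable spacers, bounds
1–300 per spacer (the biological pattern is unbounded; the cap keeps
scanning linear in practice and is config-exposed). Matching is
leftmost-first with shortest spacers, identical to a lazy
bounded-repetition regular expression with global non-overlapping
matching — the tests enforce that equivalence against a regex oracle.
The third block carries the diagnostic: arginine at its key position
calls LpxH, histidine calls LpxH2, anything else is indeterminate.
Block conservation is reported as a table, never used as a hard filter.

Clade assignment labels an unknown gene by the smallest
sufficiently-supported clade (default min support 70%) that contains it
together with references of exactly one family; a clade whose references
conflict leaves the gene unassigned, because every larger clade inherits
the conflict. Unlabeled internal nodes count as fully supported — a
missing support value cannot reject a clade.

## Event inference

Dollo parsimony formalizes the single-gain reasoning: the gain sits on
the branch above the MRCA of the present genomes, and the losses are the
maximal all-absent subtrees below it. This placement is provably the
loss-minimizing single-gain reconstruction, and the tests verify it
against brute-force enumeration over all gain placements on trees up to
16 leaves. Horizontal transfer is not modeled. Duplications come from
standard LCA reconciliation of a rooted gene tree with the species tree
(a gene-tree node mapping to the same species node as one of its
children is a duplication, charged to that species branch); implied
losses use the usual depth formula. Gene trees are rooted by an
outgroup member when one is configured, otherwise by midpoint. On
estimated (NJ) gene trees reconciliation over-counts duplications when
the topology errs; the recovery guarantees are therefore stated for true
gene trees, which the generator can emit directly from its event log
(`history_gene_tree()`).

## Genome context

A cluster is a maximal same-contig run of pathway genes with at most
`max_gap` intervening non-pathway genes (default 3 — the literature has
no operational definition, so the threshold is exposed and reported with
results). Strand is ignored by default with a same-strand option, and
composition is reported both as the ordered signature and
order-insensitively. A fusion is a gene matching two distinct families
on intervals that each reach 50 residues and overlap by at most 20% of
the shorter; calls are symmetric in the two families, and both families
count as present with fusion provenance.

## The synthetic generator

The generator emulates the study conditions so every stage can be scored
against known truth:

- **Species tree**: pure-birth (Yule) topology — the simplest rooted
  binary generator, shape-agnostic for the algorithms under test —
  rescaled to root-to-tip depth 0.75 expected substitutions/site, a
  deep-bacterial regime where the most distant family members retain
  roughly 20–30% identity.
- **Histories**: per-branch events; an entering copy is lost with
  probability `1-exp(-loss_rate)`, then each survivor duplicates with
  probability `1-exp(-dup_rate)`; copies born on a branch evolve that
  branch independently and experience no further same-branch events.
  Defaults 0.05/branch for both rates.
- **Sequences**: site-independent evolution under a single
  exchangeability matrix, WAG by default with equal rates as an option.
  The default matters: under uniform exchangeabilities a homolog at the
  tree's deepest pairwise distance scores near-randomly under BLOSUM62,
  which would contradict the regime being emulated (the pairwise stage
  finds most members; the profile stage adds a remainder). Real enzymes
  substitute conservatively, and WAG reproduces that. Motif columns are
  flagged invariant and never substituted. Root sequences are 300 aa
  drawn from the model's equilibrium frequencies.
- **Genomes**: one contig per genome, 0-based half-open nucleotide
  coordinates, random intergenic spacing and strand; the
  lpxD-lpxC-fabZ-lpxA-lpxB cluster planted with up to one intervening
  decoy, waaA-lpxK contiguous; 15 random decoy genes per genome;
  lpxC+fabZ fused (zero-length linker) with probability 0.2 per genome,
  matching a minority-of-lineages pattern.

What the generator does **not** emulate: insertions and deletions (so
alignment columns are unambiguous and aligner stress is limited to
substitution noise), among-site rate variation, compositional bias,
horizontal transfer, multi-contig assemblies, and annotation error.
Passing recovery tests therefore demonstrates correctness of the
inference machinery under a clean model of the intended setting, not
robustness to real-data artifacts.

## Problem sizes and determinism

The study-scale configuration is 20 genomes, the 9 pathway families plus
fabZ, rates 0.05, all stages at their paper-convention settings;
bootstrap replicates default to 1,000, and the test suite and acceptance
script run their end-to-end passes with 200 replicates (supports only
annotate trees; no reported quantity depends on them). The calibration
audit uses 200 searches × 20,000 null sequences with a compact profile
(the E-value law is calibrated per model, so the property does not
depend on model size). Every random step draws from an explicit seed
through a private RNG scope, and a full run writes a manifest with
settings, seeds and artifact checksums; identical configs reproduce
byte-identical artifacts, which the golden-file tests pin.

## Known limitations

Smith-Waterman here is exact DP, strictly stronger than heuristic seeded
search but quadratic — fine at desk scale, not for metagenomes. The
profile HMM omits Dirichlet-mixture priors and multi-domain parsing, so
very remote homology relies on seed-alignment breadth (the pipeline's
remedy, as in the original procedure, is enriching the seed with
additional family members). The HMM E-values are deliberately
conservative in the deep tail. Dollo cannot see a loss erased by a
subsequent regain, and reconciliation on estimated gene trees inflates
duplication counts with topology error. Six-frame DNA search is not
implemented; inputs are annotated proteomes.
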