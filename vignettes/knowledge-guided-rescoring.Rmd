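---
title: "Knowledge-guided rescoring of docking poses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-guided rescoring of docking poses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poseguide)
```

## The problem

Docking engines are good at generating a pool of plausible placements
("poses") for a flexible ligand in a protein binding site, and much worse
at ranking them: the scoring function frequently prefers a wrong binding
mode by a fraction of a pKd unit. When earlier crystal structures of the
same target exist, their bound ligands carry exactly the information a
scoring function lacks — where, in the shared site frame, real ligands
put their atoms. `poseguide` implements the machinery for exploiting
that prior knowledge independently of any particular docking engine:

1. **substructure hints** — positioned fragments shared between the new
   ligand and previously bound ligands, usable as alignment seeds;
2. **probabilistic rescoring** — a per-pose score bonus derived from the
   pose's 3D similarity to the known bound ligands;
3. **pose families** — RMSD clusters of poses ranked by Boltzmann-derived
   probabilities, so a prediction is a binding *mode* with a confidence,
   not a single conformer;
4. **ensemble selection** — a principled choice of K representative
   protein structures from a binding-pocket similarity matrix;
5. **evaluation** — symmetry-corrected RMSD, success-at-top-k, cumulative
   histograms, novelty fractions, and the usual distribution tests.

## The probabilistic rescoring model

Let the docking run produce $n$ candidate poses $L_1,\dots,L_n$ of
ligand $L$, each with a docking score in pKd units (higher = better),
and let $K_1,\dots,K_m$ be the known bound ligand poses in the same
site frame. With a bounded, normalized 3D similarity $S$ the model
computes

$$s_i = \frac{1}{m}\sum_{j=1}^m S(L_i, K_j),$$

the mean similarity of pose $i$ to the knowns. Over the whole pool the
$n \times m$ similarity table has mean $\mu$ and standard deviation
$\sigma$; under the null hypothesis that pose $i$ is an unremarkable
member of the pool, its mean of $m$ similarities has spread
$\sigma' = \sigma/\sqrt{m}$. The upper-tail probability

$$p_i = 1 - \tfrac12\left(1 + \mathrm{erf}\!\left(\frac{s_i - \mu}
{\sigma'\sqrt2}\right)\right)$$

is small exactly when pose $i$ looks much more native-like than the
pool at large. The natural probability-to-energy relationship turns it
into a score bonus; on the pKd scale, with $RT\ln 10$ identified with
one pKd unit, the bonus is

$$w_i = \log_{10}(1/p_i) \ge 0,$$

added to the docking score. Probabilities are floored at $10^{-6}$, so
the bonus is capped at 6 pKd — a deliberate guard against a single
similarity computation dominating the ranking. An unremarkable pose
($p_i \approx 1$) receives essentially no correction.

Two degenerate regimes are handled explicitly: with fewer than two
candidate poses $\sigma$ is undefined and the correction is skipped
($w_i = 0$); with $\sigma = 0$ the tail collapses to a step (0.5 at the
mean, floor above, 1 below). Note that $\sigma' = \sigma/\sqrt m$ is
applied literally even when the $m$ knowns are highly redundant; that
is statistically optimistic (the $m$ similarities are then correlated),
and users with near-duplicate knowns should deduplicate them first.

```{r rescore-example}
fx <- guided_fixture(fixture_spec(seed = 7))
rs <- rescore(fx$poses, fx$knowns)
glance(rs)
```

## Pose families

Poses are grouped by greedy leader clustering in order of decreasing
adjusted score: a pose joins the first family whose *representative*
(leader) is within `rmsd_threshold` (default 2.0 Å, symmetry-corrected),
else it founds a new family. Leader linkage was chosen over average or
complete linkage because it is deterministic, order-stable under the
score sort, and never needs the full pairwise RMSD matrix. A family's
weight is $10^{(\text{representative score} - \text{best score})}$ —
the Boltzmann weight on the pKd scale — and probabilities are the
normalized weights. Weighting by the representative rather than the
member sum avoids rewarding regions of pose space merely because the
engine sampled them densely; `weight = "sum"` is available for
sensitivity analysis.

```{r families-example}
fam <- build_pose_families(fx$poses, rs$adjusted_score)
head(fam[, c("family", "representative", "rep_score", "n_members",
             "probability")])
sum(fam$probability)
```

## The 3D similarity

The published work used a proprietary surface-shape/electrostatics
similarity for $S$; its functional form is not public. `poseguide`
therefore ships an openly documented similarity with the same contract:
symmetric, bounded in $[0,1]$, self-similarity exactly 1, computed
where the poses sit (never realigned), and vanishing as poses separate.
Heavy atoms contribute Gaussian shape densities whose decay is set so
two identical atoms at twice the van der Waals radius overlap at 1% of
the coincident-pair overlap; donors, acceptors, and charged centers
contribute 1.0 Å Gaussians matched only within type; shape and polar
terms combine 2:1 (configurable) and the total overlap is normalized as
$O(a,b)/\sqrt{O(a,a)\,O(b,b)}$, which guarantees the identities above
by Cauchy–Schwarz. The rescoring mathematics depends only on this
contract, not on any particular similarity — `rescore()` accepts any
similarity-matrix function via its `sim` argument.

## Substructure hints

`extract_hints()` mines connected common subgraphs (at least 4 heavy
atoms) between the ligand to be docked and each known bound ligand,
copies the matched fragment's coordinates verbatim from the known pose,
ranks fragments by 2D similarity to the whole ligand, and keeps at most
50. The search is depth-first with a budget: it stops either by
exhaustion or once 10,000 recursion entries have elapsed since the last
discovery of a larger match. "Recurrence initiation" is counted at
every entry into the extend step — the most literal reading of the
budget rule. The enumeration visits each connected ligand atom subset
exactly once (exclusive-neighborhood extension), branching over
consistent images in the known molecule, so an unlimited budget
provably reaches the maximum common connected subgraph.

Matching rules the search needs but that are not dictated by the
method's description are conservative and configurable: atoms match on
element plus aromatic flag; bonds must agree on aromaticity, and on
order when not aromatic; two mapped ligand atoms are bonded iff their
images are. Matches with identical ligand atom sets on one known are
redundant and removed; subset matches are additionally pruned when a
superset exists. Hints are emitted as data (SDF/MOL2 fragments);
injecting them into a docking engine's search is deliberately out of
scope.

## 2D similarity (rooted subgraph keys)

The 2D similarity enumerates, for every heavy atom, the neighborhood
ball of radius 0–3 bonds and encodes it canonically; the tally of one
molecule's keys found in the other, computed bidirectionally and
normalized, gives a score in $[0,1]$. Keys rooted at heteroatoms count
double by default (`hetero_weight = 2`) — the weighting direction is
fixed by the method, the factor is not, so it is exposed. "Subgraph" is
interpreted as the induced neighborhood ball rather than all rooted
paths; this keeps enumeration linear in atoms and matches the
"depth up to 3 at each heavy atom" description. Per root, balls that
stop growing are deduplicated — once the depth-$d$ ball equals the
depth-$(d\!-\!1)$ ball, deeper keys add nothing. Applied consistently,
this rule also deduplicates an interior atom whose radius-1 ball
already covers a small molecule (ethanol's middle carbon contributes
keys at depths 0 and 1 only, giving 8 keys in total for ethanol, not
3 atoms × 4 depths).

## Ensemble selection

Given a symmetric binding-pocket similarity matrix (produced by an
external pocket-comparison tool and consumed here as TSV/CSV), the
representative-selection problem only has pairwise similarities to work
with, and the chosen representatives must be actual structures. The
partitioning is therefore K-medoids (PAM-style swap refinement with 100
seeded random restarts) on distance $1 - \text{similarity}$, with each
cluster's exemplar the member whose mean similarity to co-members is
maximal — "closest to all cluster members". On matrices of up to 8
structures the multi-restart solution is verified against the
exhaustive optimum in the test suite. Two comparison strategies mirror
the published analysis: `choose_diverse()` (greedy max–min distance,
seeded at the pocket most dissimilar from all others — which by
construction chases outliers, explaining why maximal diversity
underperforms) and `choose_random()`. Ties are always broken by
identifier sort order; every stochastic step is seeded.
`single_linkage_tree()` provides the agglomerative similarity tree
(Newick export) used to visualize variant redundancy.

## Evaluation

`symmetry_rmsd()` computes heavy-atom RMSD minimized over all graph
automorphisms of the ligand (enumerated by color-refinement plus
backtracking, capped at 10,000 with a warning) and over optional rigid
site-symmetry operations such as a C2 axis; poses are compared in the
shared site frame with no superposition. Hydrogens are excluded —
crystallographic references rarely place them reliably. When a
structure reports alternate reference poses, the deviation is the
minimum over alternates. Success at rank $k$ and threshold $t$ is the
fraction of ligands whose best family-minimum RMSD within the top $k$
families is at most $t$; cumulative histograms integrate the standard
histogram into a proportion curve.

Curation of benchmark complexes applies four independent rules:
element whitelist (H, C, N, O, S, P, F, Cl, Br, I), molecular weight
below 1000 Da, at least 3 ligand heavy atoms with van der Waals
surface-to-surface distance under 1.0 Å to the protein, and a
buriedness ratio (protein atoms within a 4.0 Å shell per ligand heavy
atom) of at least 0.3. The buriedness threshold and shell are this
package's defaults — the published pipeline references an external
definition without printing values — and both are arguments. The
temporal split sorts by deposition date (ties by identifier) and takes
the earliest `ceiling(0.25 N)` complexes as the knowledge set; ceiling
was chosen so the early set is never empty-leaning at small N, and the
choice is documented rather than implied. Novelty fractions count test
items whose maximal similarity to the knowns falls strictly below a
threshold; because the published global threshold is not reproducible
here, the threshold is an explicit argument (a pooled 10th percentile
is a reasonable default choice). Distribution comparisons use the
two-sample Kolmogorov–Smirnov test (asymptotic p) and exact two-sided
binomial tests via the standard R implementations.

## What the synthetic fixtures emulate

All tests and the acceptance script run on synthetic data built by
`fixture_spec()` / `guided_fixture()`. The generator reproduces the
*statistical situation* that motivates knowledge guidance: a shared
scaffold of ≥ 6 heavy atoms across a ligand series (so every pair has a
≥ 4-atom positioned common substructure), a candidate pool of 100 poses
per ligand of which 10% are near-native (within 1 Å of the reference)
and the rest are flipped, translated decoys (≥ 4 Å), with decoy scores
out-ranking native scores by 0.5 pKd. Geometry uses idealized bond
lengths (1.5 Å) with clash-avoiding placement, not a force field; no
minimization is emulated, and `randomize_torsions()` removes
conformational memory exactly (bond lengths preserved to machine
precision). Every fixture is a pure function of its spec and seed.

```{r experiment, eval = FALSE}
# the end-to-end experiment (about 4 minutes for 100 ligands)
ex <- guided_experiment(100, fixture_spec(seed = 1))
glance(ex)
```

What passing on these fixtures shows: the pipeline recovers a planted
native binding mode from an adversarial score ordering whenever the
similarity signal is present, with exactly normalized family
probabilities. What it does not show: performance on real docking
pools, where decoys can be partially native-like, similarity
distributions are not bimodal, and protein flexibility blurs the site
frame. Quantities tied to the proprietary engine, the pocket-similarity
implementation, and corpus-scale benchmark tables are out of reach at
desk scale and are not claimed.

## Numerical choices

* Problem sizes: the shipped experiments use 100 ligands × 100 poses ×
  5 knowns and selection matrices up to 15 structures — sizes chosen so
  the whole suite runs in minutes on one core while keeping every
  statistical property testable.
* Probability floor $10^{-6}$, bonus cap 6 pKd; population (not sample)
  estimator for $\sigma$ over the full $n \times m$ table.
* Family threshold 2.0 Å, leader linkage, representative weighting —
  all arguments.
* K-medoids: 100 restarts, swap until local optimum, objective = mean
  distance to the assigned medoid; improvement margin $10^{-15}$ to
  keep tie-breaking deterministic.
* Centroid filter boundary is closed (exactly at the threshold is
  retained) with a $10^{-9}$ Å guard against floating-point noise.
* SDF dialect is V2000 with aromatic bonds as type 4 and formal charges
  via `M  CHG`; MOL2 is SYBYL with `.ar` types; docking scores travel
  in a `SCORE_PKD` data field (SDF) or `# SCORE_PKD` comment (MOL2).

## Known limitations

The 3D similarity is a documented surrogate, not a reimplementation of
the published one; absolute similarity values are not comparable across
implementations, only the rescoring behavior built on them. The 2D key
canonicalization relies on iterated color refinement, which cannot
distinguish certain regular graphs that chemistry rarely produces. The
automorphism cap and the substructure budget make worst-case highly
symmetric inputs tractable at the cost of completeness, and both
truncations are flagged, never silent.
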