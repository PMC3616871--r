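---
title: "Phylome-based phylogenomics: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylome-based phylogenomics: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomer)
```

This vignette documents the models behind each stage of the package, the
conventions and tunable parameters, and the design decisions taken where
the methodology left genuine freedom. It is the companion to the test
suite: every empirical claim below is one the tests or the acceptance
script actually compute.

## The phylome data model

A phylome is a named list of rooted gene trees, one per seed gene, whose
leaf labels encode both a sequence id and a species code. The default
naming convention is `SEQID_SPECIES` with the species code after the last
underscore; an explicit two-column mapping overrides it
(`leaf_species()`, `read_species_map()`). Each tree carries at most one
seed leaf (attribute `seed_leaf`). Species sets are represented internally
as integer bitmasks over a fixed taxon ordering, which caps the species
count at 30 — far above the tens of taxa these analyses use, and what makes
reconciliation and split operations fast enough for heuristic search.

Rooting is a genuine open point in phylome pipelines: the gene trees are
delivered rooted, but the rooting rule is part of the upstream
reconstruction. `root_tree()` therefore offers both outgroup rooting
(root on the edge above the smallest clade holding all present outgroup
species) and midpoint rooting (longest leaf-to-leaf path, ties broken
toward the lexicographically smallest leaf pair); which to use is the
caller's choice, midpoint being the default when no outgroup is given.
Polytomies are accepted on input and, where an algorithm needs binary
trees, resolved deterministically left-to-right with zero-length branches,
so repeated runs agree.

## Event labeling and orthology

The species-overlap rule labels an internal node a duplication iff its two
child subtrees share at least one species; the score
$|S_L \cap S_R| / |S_L \cup S_R|$ is reported, and the decision threshold
defaults to 0 (any overlap) because that is the common usage of the
species-overlap method; it is exposed as a parameter since reasonable
pipelines have used small positive values to absorb reconstruction noise.

Orthology follows from the labels: a gene pair is orthologous iff its MRCA
is a speciation. Relation types count, per species, the leaves each side of
the mediating node contributes (1 vs 1, 1 vs many, many vs many). The
catalogue is exhaustive and exclusive — every unordered pair is exactly one
of ortholog or paralog — and the implementation is checked in the suite
against a naive all-pairs MRCA lookup.

TreeKO-style decomposition splits a multi-copy gene tree at every
duplication node: at a duplication the two child subtrees are treated as
alternative histories; at a speciation all combinations of the children's
alternatives are formed. Outputs are relabeled by species. Under the
default threshold the outputs are provably single-labeled; the function
asserts this and aborts otherwise (possible only with a positive
threshold). Duplicate topologies are *kept* by default because support
counting downstream weights by occurrence; `dedup = TRUE` collapses them.

## Reconciliation, dating, merging, rates

`reconcile_lca()` implements the standard LCA mapping; a node is a
duplication iff it maps to the same species-tree node as one of its
children, and the total count is the gene-tree parsimony cost. The suite
checks this against brute-force enumeration of all valid reconciliations
on small trees.

Duplication *dating* deliberately uses the species-overlap labels, not the
reconciliation labels: the two disagree on discordant trees, and the
pipeline's lineage assignments should be consistent with the event calls
its orthology stage made. A duplication is dated to the branch ending at
the LCA of the species below it.

Because each gene of a family seeds its own tree, one evolutionary event
is reported once per covering tree. Merging treats two events from
different trees as redundant iff their unordered pairs of descendant
leaf-id sets are identical after restricting both to the intersection of
the two trees' leaf universes, with all restricted sides non-empty. The
restriction step is our formalization of "merge redundant events": it
makes truncated views of the same event (one tree missing a few leaves)
merge, while events from unrelated families (disjoint ids) never do. The
stricter unrestricted rule is available (`rule = "exact"`). Merging is a
connected-components construction and is idempotent.

Per-lineage rates divide merged duplication counts by *informative* genes:
trees that could have observed the branch (at least one species below it
and one outside; for terminal branches, presence of the species; for the
root, species in at least two of its child subtrees). The alternative
denominator — all trees — is a flag, because the choice is a convention,
not a fact of the data; rates on branches with no informative tree are
reported as `NA`, never 0. Both a per-tree and a per-merged-event
"fraction of genes with a duplication" are attached, since the two
denominators answer different questions.

## Supertrees and gene-tree support

Two optimality criteria are implemented over rooted candidate topologies:

* **Duplication parsimony**: total LCA-reconciliation duplications of the
  raw (multi-copy) gene trees — the input convention of gene-tree
  parsimony tools.
* **Split fit (SFIT)**: per source topology, the candidate is pruned to the
  source's species and the fit is `shared / max(source splits, candidate
  splits)`; the score is the mean over sources sharing at least 4 species.
  SFIT consumes the *decomposed single-labeled* topologies, matching the
  TreeKO preprocessing convention. The `max` normalization is one of two
  defensible readings of "most congruent in terms of bipartitions"; the
  `shared / source` variant is a flag. The choice moves scores, not optima,
  on congruent collections.

Search is NNI hill climbing (first improvement, deterministic preorder
neighbor order) from one greedy taxon-addition start plus `n_starts`
random starts, with a full SPR round whenever NNI stalls; equal-score
final candidates are broken by lexicographic Newick. Scores of identical
(taxon set, split set) sources are computed once and weighted, which is
exact. For six or fewer species `enumerate_supertree()` scores every
rooted topology and serves as the oracle; the suite requires the heuristic
to match it.

Gene-tree support of a species-tree bipartition is the percentage of
topologies containing it after restriction to their own taxa; a topology is
eligible only if both restricted sides keep at least two species
(`eligibility = "strict"` instead requires all taxa). The eligibility rule
for incomplete trees is documented and switchable because the plain
definition ("percentage of trees supporting each bipartition") does not fix
it.

## The likelihood engine

Empirical exchangeability matrices (JTT, WAG, MtREV, LG, Blosum62, DCMut)
are taken at run time from phangorn's model data; `Poisson` (uniform
exchangeabilities and frequencies) is included because it admits closed
forms used throughout the tests: identity probability
$p_{ii}(t) = \tfrac{1}{20} + \tfrac{19}{20}e^{-20t/19}$ and pairwise
distance MLE $\hat d = -\tfrac{19}{20}\ln(1 - \tfrac{20}{19}p)$. The rate
matrix $Q_{ij} = s_{ij}\pi_j$ is normalized to one expected substitution
per site at stationarity, and $P(t) = e^{Qt}$ is computed from the
symmetrized eigendecomposition.

Among-site rate variation is the k-category discrete gamma (mean of each
equal-probability bin; the category rates average exactly 1) plus invariant
sites: the per-column likelihood is
$p_{inv}\,\pi_x\,[\text{column constant at } x] + (1 - p_{inv})\,
\frac{1}{k}\sum_c L(\text{lengths} \times r_c)$. The same mixture drives
the sequence simulator, so inference and simulation share conventions
exactly. Gaps and ambiguity codes (X, B, Z, ?) are fully missing states.
The pruning recursion is a small compiled kernel with per-site rescaling;
a 16-bit popcount table and indicator-gather at tip edges keep the cost
dominated by the few internal-edge matrix products.

Branch lengths are optimized by cyclic Brent searches (bounded, length
cap 10 substitutions/site, log-likelihood non-decreasing across cycles);
$\alpha$ is optimized in log-space on $[0.02, 100]$ and $p_{inv}$ on
$[0, 0.99]$ by alternating univariate searches rather than joint Newton —
slower but robust to the strong $\alpha$–$p_{inv}$ correlation. AIC model
selection re-optimizes branch lengths, $\alpha$ and $p_{inv}$ per model
(two alternation rounds, two coarse branch cycles with a 0.01
branch-length tolerance: AIC differences between amino-acid models at
these alignment sizes are orders of magnitude larger than the residual
optimization error), with `params = branches + 2` and ties broken by
candidate order.

## Topology tests

All tests resample the per-site log-likelihood matrix (RELL) — replicates
re-sum resampled columns, with no re-optimization. Conventions:

* **KH** compares each topology with the observed maximum-likelihood one;
  the p-value is the proportion of *centered* replicate differences that
  are at least the observed difference. The non-strict comparison makes an
  exact tie give p = 1 (the symmetric degenerate case), while dominated
  topologies approach 0; the choice only matters on degenerate data.
* **SH** centers every topology's replicates at its own mean and compares
  the observed difference against the replicate-wise maximum, which makes
  SH ≥ KH by construction.
* **AU** resamples at ten scales $r \in \{0.5, \dots, 1.4\}$, records the
  proportion of replicates each topology wins, and fits
  $1 - BP(r) = \Phi(d\sqrt r + c/\sqrt r)$ by iterated weighted least
  squares with binomial variance weights; $p_{AU} = 1 - \Phi(d - c)$.
  All-zero or all-one BP curves are degenerate and reported as p = 0 / 1
  with a flag rather than fitted. Each scale draws from its own seed
  stream, so adding scales does not perturb existing ones.

## The synthetic-data generator

The generator exists to give every downstream stage a ground truth. A
birth–death species tree conditioned on the species count (time units,
ultrametric) hosts gene families: one gene lineage enters at the root;
along each species-tree branch it duplicates at rate $\lambda_d$ per
lineage per unit length and dies at rate $\lambda_l$; at speciations every
surviving lineage splits into both children; at the tips each copy is
retained with probability `sampling_prob`, emulating transcriptome-style
incompleteness (a gene absent from an assembly, not from the genome).
Optionally one uniform-random NNI perturbs the finished tree with
probability `topology_error_p`, modeling gene-tree reconstruction error;
planted events always describe the pre-perturbation tree. Families with
fewer than three retained leaves, or no retained copy in the seed species
(a phylome tree exists only because its seed was observed), are
resimulated and counted.

Defaults: 8 species, birth 1 / death 0.5 (moderate extinction), 100
families, $\lambda_d = 0.3$, $\lambda_l = 0.1$, full sampling, no topology
error, 300-column WAG alignments with $\alpha = 1$, $p_{inv} = 0.1$, and
0.5 substitutions/site per time unit. These are ordinary
invertebrate-phylogenomics magnitudes: duplication rates of a few tenths
per gene per branch reproduce the regime where roughly a third to a half
of families show at least one duplication, and $\alpha \approx 1$ with a
small invariant fraction is typical of protein alignments.

What the generator does **not** emulate: incomplete lineage sorting (no
coalescent), horizontal transfer, indels (alignments are gapless unless
whole sequences are dropped), alignment error, or model misspecification
beyond the NNI perturbation. Tests passing on these simulations therefore
demonstrate correctness of the algorithms under their stated assumptions,
not robustness to every artifact of real transcriptome data — the NNI
error channel and the dropout channel are the two deliberate, controllable
departures from clean data.

## Validation design and problem sizes

The acceptance suite runs each stage at sizes chosen to keep the full run
in tens of minutes on one core while leaving no statistical ambiguity:
event recovery on 200 families (exact precision/recall under no dropout —
with dropout, complementary losses make some duplications genuinely
unobservable, which is why the clean regime is the correctness check);
reconciliation against brute force on 100 random small trees; supertree
recovery at 8–12 species and 100 gene trees across ten seeds plus
exhaustive-enumeration equality at six; support saturation at 100% and its
monotone decay as topology error rises through 0 / 0.2 / 0.5; rate
recovery on 500 families against planted values within Monte-Carlo error;
likelihood closed forms at $10^{-10}$–$10^{-6}$ tolerances and brute-force
equality at $10^{-8}$; WAG recovery by AIC in at least 8 of 10 seeds at
2,000 columns; KH type-I error within [0.03, 0.07] at nominal 0.05 over
500 null datasets of 10,000 sites; and bit-exact enforcement of the
homology-hit thresholds (1e-5, 30%, 200) on a boundary-case fixture.

## Known limitations

* At most 30 species (integer bitmasks); the intended scale is phylome
  studies of a few dozen taxa at most.
* The supertree search is heuristic; optimality is guaranteed only where
  enumeration is feasible (≤ 6–7 species), and verified statistically
  (truth recovery) above that.
* TreeKO decomposition is combinatorial at speciation nodes; trees with
  very many nested duplications can explode. At simulated duplication
  rates this is immaterial; pathological families should be decomposed
  with `dedup = TRUE` or skipped.
* The AU implementation follows the standard multiscale-bootstrap
  construction but is not guaranteed to agree numerically with any
  particular external implementation's fitting details.
* No coalescent machinery: discordance from incomplete lineage sorting is
  outside the model.
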