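---
title: "Benchmarking network-based PPI prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking network-based PPI prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppibench)
```

## The problem

Interactome maps — the networks of binary physical protein–protein
interactions (PPIs) of an organism — are highly incomplete: the unmapped
pair space is hundreds of times larger than the mapped link set. Link
prediction promises a cheap way to prioritize candidate interactions for
experimental testing, but the many available scorers rest on very different
structural assumptions, and their relative merit on sparse, noisy PPI
networks is not obvious. `ppibench` provides, in one package: the classical
and advanced network scorers, a standardized cross-validation harness with
imbalance-aware metrics, an index of how predictable a network is at all,
consensus (stacking) models, and analytics that reveal *which* pairs a
method favors. Everything runs on synthetic PPI-like graphs generated in
code, so the full pipeline is testable without external data.

## Scorers

All scorers operate on the simple graph (self-loops dropped) and return a
`score_table` over requested candidate pairs. Throughout, `Γ(i)` is the
neighborhood and `k_i` the degree of node `i`, and `A` the adjacency matrix.

**Local similarity indices** (`local_similarity_scores`): CN
`|Γ(i)∩Γ(j)|`, resource allocation `Σ_z 1/k_z`, Adamic–Adar `Σ_z 1/ln k_z`,
Jaccard `|Γ(i)∩Γ(j)|/|Γ(i)∪Γ(j)|`, preferential attachment `k_i·k_j`, and
CAR-based resource allocation `Σ_z |γ(z)|/k_z`, where `γ(z)` counts links
from the common neighbor `z` back into the common neighborhood. A common
neighbor of a non-self pair necessarily has degree ≥ 2, so the Adamic–Adar
logarithm never vanishes; the implementation asserts rather than guards.

**Katz** (`katz_scores`): `((I − βA)^{-1} − I)_{ij}`, the damped count of
walks of all lengths. The series converges iff `β < 1/λ_max(A)`; the
default `β = 0.5/λ_max`, recomputed per graph, guarantees convergence
without tuning. A `β` at or beyond the spectral radius bound is rejected as
divergent.

**L3** (`l3_scores`): degree-normalized paths of length three,
`Σ_{u,v} A_iu A_uv A_vj / √(k_u k_v)`. Interacting proteins tend to have
*complementary*, not similar, interfaces: a protein typically binds
proteins that resemble its partners' partners, which length-3 paths capture
and common neighbors do not. For non-adjacent candidate pairs the length-3
walk count equals the path count (a degenerate walk would need the `i–j`
edge itself). `SIM` (`sim_scores`) combines L3 with the Jaccard index as
`L3·(1 + JC)`; the exact published composition of this integration is not
public, so tables are flagged `surrogate = TRUE`.

**Neighborhood-level L3** (`mps_t_scores`): ranks `(i,j)` by
`MaxSim = max(max_{l∈Γ(j)} JC(i,l), max_{u∈Γ(i)} JC(u,j))` — high when one
endpoint's neighborhood resembles the neighborhoods of the other's partners
— with the degree product as a lexicographic tie-breaker. The tie-break is
folded into one real score as `MaxSim + 1e-9·PA/(1+max PA)`: genuine
`MaxSim` values are ratios of small integers, whose nonzero differences are
far above `1e-9`, so the composite preserves the lexicographic order.

**Spectral reconstruction and the RNM-style ensemble**
(`spectral_reconstruction_scores`, `rnm_scores`): the adjacency matrix is
eigendecomposed (optionally after adding a diagonal ridge `ε`, a diagonal
noise model) and pairs are scored by the rank-`r` reconstruction
`Σ_{k≤r} λ_k x_k(i) x_k(j)`, modes ordered by `|λ_k|`. The ensemble
averages the percentile ranks (midpoint ties) of the spectral score and the
L3 score with weights `(0.5, 0.5)`; percentile ranking makes it invariant
to monotone rescaling of either component. `ε` defaults to
`0.01 × mean degree`. The published method this emulates is specified only
at the level of its ingredients (diagonal noise + spectral noise + L3), so
these tables are likewise marked surrogates.

**Stochastic block model** (`sbm_reliability_scores`): nodes are
partitioned into groups; the probability that a link exists depends only on
the endpoint groups. The link reliability is the posterior mean
`R_ij = ⟨(l_{σiσj}+1)/(r_{σiσj}+2)⟩` over partitions `P` weighted by
`exp(−H(P))`, with `H(P) = Σ_{r≤s} ln(r_rs+1) + ln C(r_rs, l_rs)` (`l_rs`
observed, `r_rs` possible links between groups). Sampling uses a Metropolis
chain with single-node group moves and free group count. The chain state is
a group-label assignment, and a partition with `k` blocks corresponds to
`n!/(n−k)!` assignments; moves that create or empty a group therefore carry
a multiplicity correction in the acceptance ratio so that the chain targets
set partitions exactly. Without the correction, reliabilities are biased
toward fragmented partitions by roughly 0.01–0.03 on 5-node graphs —
detectable against exhaustive enumeration. Defaults: 2000 samples, 2000
burn-in steps, thinning 10.

**Embeddings** (`embedding_scores`): NNMF (`A ≈ WH` by 500 multiplicative
updates, node vector = averaged row of `W` and column of `H`, seeded
uniform initialization), GLEE-style unnormalized Laplacian eigenmaps, and
the symmetric normalized Laplacian variant; both Laplacian variants are
provided because published embedding pipelines differ on this point. Pairs
are scored by cosine similarity of endpoint vectors; zero vectors score 0.

**Diffusion** (`act_scores`, `rwr_scores`, `simrank_scores`): average
commute time `CT = 2m·R_eff` via the Laplacian pseudoinverse (score
`1/CT`; cross-component pairs score 0 so tables stay complete); random walk
with restart (default restart 0.15, column-stochastic transitions, walkers
stranded on isolated nodes teleport to the source, symmetrized visiting
probability `q_i(j)+q_j(i)`); and SimRank (decay 0.8, fixed point from the
identity, tolerance `1e-6`).

## The evaluation protocol

`kfold_edge_split` partitions the observed link set `E` into `k = 10`
probe sets of near-equal size (differing by at most one). Per fold, the
probe links are removed; scorers see only the residual training graph. The
test universe is the union of the probe set and *every* non-link absent
from training (`build_candidate_universe`) — evaluation is deliberately
imbalanced, as in real prediction. Self-pairs are excluded by default
because most scorers ignore self-interaction prediction; a flag includes
them.

`rank_candidates` orders by descending score with lexicographic pair-order
tie-breaks, making every downstream metric deterministic.
`compute_metrics` reports AUROC (tie-corrected rank-sum estimator on the
raw scores), AUPRC as average precision (step interpolation — trapezoidal
interpolation is optimistic under heavy imbalance), P@k (`k = 500`;
divided by `k`, so the maximum is below 1 when fewer than `k` positives
exist), truncated average precision AP@k, and NDCG with binary relevance
over the full ranked list (truncated NDCG is available since either
convention appears in practice).

`combine_zscores` standardizes AUPRC, P@500 and NDCG to z-scores across
methods (sample standard deviation) and sums them:
`score = z_AUPRC + z_P@500 + z_NDCG`. AUROC is excluded from the
combination: on sparse networks it is systematically inflated and can rate
a method with AUPRC near 0.01 as "almost perfect". A metric with zero
spread contributes zero for every method, with a warning. `benchmark_run`
orchestrates the whole loop and excludes a scorer that fails on any fold
from the scorecard (rank N/A) without aborting the run.

## Network predictability

`structural_consistency` measures whether a network's unobserved links
resemble its observed structure. A random fraction `p_H = 0.1` of links is
removed; the residual adjacency matrix is eigendecomposed; first-order
perturbation corrections `Δλ_k = x_kᵀ ΔA x_k` produce the reconstruction
`Ã = Σ (λ_k + Δλ_k) x_k x_kᵀ`; all pairs absent from the residual graph
are ranked by `Ã`; and `σ_c` is the fraction of the removed links recovered
in the top `|ΔE|` — by construction the precision at `|ΔE|` of that
ranking, which the implementation asserts. Repetitions (default 10) are
summarized by mean and standard deviation, since a single removal is noisy
at small sizes. Degenerate eigenvalues make the per-vector first-order
formula approximate; a warning is raised when the smallest spectral gap
falls below `1e-8`. Dense decomposition is the default; above a few
thousand nodes a truncated decomposition (`n_modes` leading modes via
Arnoldi iteration) is available, with the caveat that discarded modes can
carry recoverable structure.

## Stacking and consensus

Four consensus constructions are provided. The supervised model stacks 21
topological predictors (pairwise: CN, JC, AA, RA, PA, shortest-path length
with unreachable encoded as the node count, L3, Katz truncated at walk
length 3; node-based as order-invariant min/max of degree, local
clustering, core number, PageRank, eigenvector centrality; global: density,
mean clustering, degree assortativity) into a ridge-regularized logistic
regression, with negatives sampled from non-links at a 1:1 ratio. The
published predictor list (36 features) is not public; this registry is a
documented stand-in and the column set is versioned so an exact list can be
swapped in. The classifier is a contract — any learner emitting
probabilities qualifies.

The unsupervised rules aggregate component score tables over a common
universe: mean percentile rank, maximum percentile rank, and Dowdall
(reciprocal-rank points `1/r`, a Kemeny-consensus approximation; the cRank
alternative is omitted because its algorithm is not described in the
sources available here). Percentile rank maps the best candidate to 1 and
the worst to 0 (`1 − (r−1)/(N−1)`, midpoint ties) — the endpoint convention
is an interpretation, fixed and documented. All rules are unanimous (a pair
ranked first everywhere stays first) and invariant to monotone rescaling.
Whether any of them beats the best individual method is an empirical
question; on the synthetic benchmarks the package reports the comparison
rather than asserting a winner.

## Prediction-pattern analytics

`degree_difference_stats` and `top_prediction_degree_profile` summarize
the degrees of proteins in a prediction list (both multiset and
unique-protein averaging are reported, as published figures rarely state
the convention). `network_separation` computes
`s_αβ = ⟨d_αβ⟩ − (⟨d_αα⟩ + ⟨d_ββ⟩)/2`; the distance averages follow the
nearest-neighbor convention of the separation measure's original
definition for network modules, although descriptive prose often says
"average shortest distance" — the all-pairs reading is available via
`convention = "all_pairs"`. Unreachable pairs are excluded from means and
surfaced through a coverage fraction rather than capped.
`prediction_overlap` reports the Jaccard index of two top-k lists and
Cohen's kappa of the in-list indicators over the shared universe.

## Synthetic interactomes

`dmc_generate` grows graphs by duplication–mutation–complementation: a
random node is duplicated with all its links; each redundant link pair
loses one member with probability `q_mod` (either copy, equally likely);
the duplicate pair is joined with probability `q_con`. This mimics the gene
duplication and subfunctionalization that shaped real interactomes and
reproduces their signature sparsity, heavy-tailed degrees, and abundance of
length-3 paths between non-adjacent pairs. Defaults `q_mod = 0.3`,
`q_con = 0.2` are calibrated so that a 300-node graph has mean degree near
12, the density scale of curated human interactome maps. What DMC graphs do
*not* emulate: study bias (real maps oversample well-studied proteins),
assay-specific false negatives, and functional module annotations — so
passing benchmarks here demonstrates correctness of the machinery and
qualitative method ordering, not absolute performance on any real
interactome.

`er_generate` (uniform `G(n,m)`) provides structureless controls;
`degree_preserving_randomize` (double-edge swaps that reject self-loops
and multi-edges) isolates degree-sequence effects;
`planted_partition_generate` provides ground-truth block structure for the
SBM and embedding scorers. All generators draw from a private, seeded RNG
stream and never touch global RNG state.

## Numerical choices and problem sizes

Ties everywhere are broken by canonical (lexicographic) pair order, so
every ranking, file, and metric is reproducible across platforms. The
package's own test and verification workloads use: exhaustive brute-force
oracles on all non-isomorphic connected graphs up to 7 nodes; exact
partition enumeration (Bell(5) = 52) against the SBM sampler at 5000
samples; 300-node DMC graphs with 10-fold cross-validation over 20
generator seeds for the method comparison; and a five-point density grid
(q_mod 0.7→0.3, 10 seeds, 3 removal repetitions each) for the
predictability trend. These sizes were chosen as the smallest at which the
qualitative orderings are stable across seeds.

## Known limitations

* The advanced scorers are principled surrogates built from documented
  mechanisms, not bit-level reimplementations of the corresponding
  published methods; every such table carries `surrogate = TRUE`.
* Dense linear algebra bounds the practical graph size for spectral
  scorers and `structural_consistency` to a few thousand nodes; the
  truncated eigendecomposition trades fidelity for reach.
* The candidate universe is materialized explicitly (`O(n²)` pairs), which
  is the regime the evaluation protocol itself assumes; genome-scale
  ranking of tens of millions of pairs would require streaming scorers.
* Identical singleton sets are a degenerate input for network separation
  (no cross-partner other than the protein itself).
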