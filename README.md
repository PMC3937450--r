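# netsi

Stability indicators for inferred networks, built on the
Hamming–Ipsen–Mikhailov (HIM) distance.

## The problem

Co-expression and relevance networks are routinely reconstructed from
high-throughput data (transcriptomics, miRNA profiling, …), but without a
gold standard there is no way to ask "is this network *right*?". A weaker,
answerable question is "is this network *reproducible*?": if the inference
is repeated on resampled subsets of the same data, how far do the
reconstructions drift? `netsi` quantifies exactly that, for any inference
method that maps a samples × features matrix to a weighted undirected
network with link strengths in [0, 1].

## The indicators

Networks on the same node set are compared with the HIM distance

    HIM_ξ(A, B) = sqrt( H² + ξ·IM² ) / sqrt(1 + ξ)

where

* **H** is the normalized Hamming distance, the mean absolute entrywise
  difference of the adjacency matrices — a *local* edit distance (fraction
  of mismatched links for binary graphs);
* **IM** is the Ipsen–Mikhailov spectral distance: each network's Laplacian
  eigenvalues λ_i define vibrational frequencies ω_i = √λ_i, smoothed into
  a Lorentzian spectral density ρ(ω) = K Σ_i γ/((ω−ω_i)² + γ²) normalized
  to unit mass on [0, ∞); IM is the L2 distance between the two densities —
  a *global* structural distance, blind to node relabeling. The width γ is
  calibrated per node count so that IM(empty, complete) = 1;
* ξ (default 1) weights the spectral component; both H, IM and HIM lie in
  [0, 1], with 1 attained by the empty-vs-full pair.

Given a resampling plan (leave-one-out, repeated k-fold with the test
portion discarded, or r random subsets of s samples), the **NetSI** family
summarizes an ensemble of reconstructions:

* **S** — mean distance between the full-data network and each resampled
  network (with range and 95% studentized bootstrap CI);
* **S_I** — mean distance over all pairs of resampled networks;
* **S_w** — per-edge coefficient of variation of the link weight across
  resamples (edge-weight stability ranking);
* **S_d** — per-node coefficient of variation of the weighted degree
  (node-degree stability ranking).

Smaller is more stable. Edges/nodes never wired in any resample have both
mean and range zero; their score is *void* and they are flagged separately
rather than ranked.

Ten inference methods are included: `cor` (absolute Pearson), `wgcna`
(|r|^β, soft power β = 6), `bicor` (biweight midcorrelation), `tom`
(topological overlap), `mic` (maximal information coefficient), `aracne`
(mutual information + data-processing-inequality pruning), `clr` (MI with
per-node background z-scores), and permutation-FDR gated `cor_fdr`,
`wgcna_fdr`, `mic_fdr` (edgewise permutation p-value threshold).

Synthetic generators reproduce the benchmark inputs: `modular_network()`
(50-node families of c bridged cliques, c = 1…10), and
`block_correlation_matrix()` + `sample_gaussian()` (block-correlated
Gaussian expression data via Cholesky sampling), plus a linear-Gaussian
surrogate `surrogate_expression()` for turning any network into data.

## Worked example

Twenty features with two strong correlation blocks (1–5 at ρ = 0.9, 6–10
at ρ = 0.7, 11–15 at ρ = 0.3), 100 samples; how stable is a plain
correlation network under repeated 4-fold resampling?

```r
library(netsi)
sigma <- block_correlation_matrix()
x     <- sample_gaussian(sigma, m = 100, seed = 42)
rep   <- netsi_run(x, method = "cor", scheme = "kfold", k = 4,
                   instances = 5, seed = 7)
rep
#> <netsi_stability> method cor, metric him (xi = 1)
#>   S   = 0.0425  CI (0.0372; 0.0493)  range (0.0247; 0.0625)  [20 distances]
#>   S_I = 0.0453  CI (0.0443; 0.0465)  range (0.0233; 0.0662)  [190 distances]
#>   edge ranking: 190 scored + 0 void; node ranking: 20 scored + 0 void

head(rep$edges, 5)
#> # A tibble: 5 × 5
#>   from  to      score void   rank
#> 1 v1    v5    0.00745 FALSE     1
#> 2 v1    v2    0.00782 FALSE     2
#> 3 v1    v4    0.00816 FALSE     3
#> 4 v4    v5    0.00868 FALSE     4
#> 5 v2    v4    0.00955 FALSE     5
```

The reconstruction moves by about 0.04 HIM units under resampling (S), the
resampled networks are mutually about as far apart (S_I), and the most
stable edges are exactly the links inside the strongest designed block
(features 1–5) — the edge ranking recovers the design. `autoplot(rep)`
shows the two distance distributions; `glance(rep)` returns the one-row
summary; `tidy(rep)` the raw distances.

Distances are also available directly:

```r
him_distance(empty_network(10), full_network(10))
#> # A tibble: 1 × 4
#>       h    im   him    xi
#> 1     1 1.000 1.000     1
```

A command-line wrapper (`inst/cli/netsi`) exposes the same operations:
`netsi infer`, `netsi distance`, `netsi stability`, `netsi simulate-network`,
`netsi simulate-data`, `netsi rank-edges`, `netsi rank-nodes`.

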