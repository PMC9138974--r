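---
title: "Integrated information for spike trains: models, approximations, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated information for spike trains: models, approximations, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phispike)
```

## The measure

Integrated information Φ quantifies the information a system generates
beyond what its parts generate independently. The classical definition for
a partition of the units into subsets $M_1,\dots,M_r$ is a difference of
conditional entropies between the parts and the whole,

$$\Phi = \sum_{k=1}^{r} H(M_{t,k}\mid M_{t+\Delta t,k}) - H(X_t \mid X_{t+\Delta t}),$$

minimized over partitions: the minimum information partition is the
system's informational weakest cut. `phispike` implements this plug-in
entropy form only as a small-system oracle (`phi_discrete`, ≤ 10 binary
nodes), because empirical joint distributions over $2^N$ states are
hopeless for realistic recordings.

The workhorse is the autoregressive estimator. Binarized states $X_t$ are
summarized by the equal-time covariance $\Sigma(X)$ and the lag-$\Delta t$
cross-covariance; $\Sigma(E_S)$ denotes the covariance of the residuals of
the least-squares prediction of a subset $S$'s future from its own past,
$\Sigma(E_S) = S_{00} - S_{01}^\top S_{00}^{-1} S_{01}$. Then

$$\Phi_{\mathrm{raw}}(M) = \tfrac12\ln\frac{\det\Sigma(X)}{\det\Sigma(E_X)}
 - \sum_{k=1}^{r}\tfrac12\ln\frac{\det\Sigma(M_k)}{\det\Sigma(E_{M_k})},$$

normalized by $L(M) = \tfrac12\ln\!\left[\min_k (2\pi e)^{|M_k|}
\det\Sigma(M_k)\right]$ to diminish the influence of unequal subset sizes.
For Gaussian data this equals the entropy form; for binarized spikes it is
an approximation, which is why `phi_discrete` exists as an independent
cross-check (the two agree within 0.05 on weakly coupled binary pairs, and
the estimator converges to the analytic value on simulated Gaussian VAR(1)
data — both are tested).

The bipartition form is generalized to $r$ subsets by summing the
per-subset term over all parts and keeping the min-over-parts form of
$L(M)$; this is the only reading under which the same expression serves the
atomic and community partitions. Division by $L(M)$ (rather than
multiplication) follows from its explicit role as a normalization. Natural
logarithms are used throughout, as implied by the $(2\pi e)$ factor.

## Partition approximations

* **mib** (`mib_search`): exhaustive search over all $2^{N-1}-1$ unordered
  bipartitions, minimizing the *normalized* value (unnormalized
  minimization is available behind a flag). Enumeration is capped at 15
  units by default — a hardware statement, not a method constant — and is
  normally preceded by top-15 selection.
* **atomic** (`atomic_partition`): all singletons; $O(N)$ extra work,
  ignores information generated by clusters.
* **louvain** (`louvain_partition`): communities of the correlation graph.
  Edges are $|r_{ij}|$ for Pearson correlations of the binary bin sequences
  that pass a two-sided t-test at $\alpha = 0.05$ (no multiple-comparison
  correction across pairs — deliberately matching the plain per-edge
  threshold convention), zero otherwise. Absolute values are used because
  the modularity null model assumes non-negative weights; Spearman is
  available as an option.

### The Louvain optimizer

`louvain` is implemented from scratch: greedy single-node moves using the
standard modularity-gain expression, sweeps until no move gains more than
1e-12, aggregation into super-nodes, recursion, and then a final refinement
pass of single-node moves on the original graph. Because the greedy pass is
visit-order dependent, the optimizer restarts from 8 deterministically
seeded visit orders and keeps the best assignment. On small graphs
(`n ≤ 8`) this reaches at least 95% of the exhaustive maximum over all
Bell(n) partitions in our tests, where single-run two-phase Louvain (ours,
and igraph's) can stall in a local optimum. The convention
$m = \tfrac12\sum_{ij}A_{ij}$ makes the modularity and gain formulas
mutually consistent. Single-community results and empty graphs fall back to
the atomic partition with a warning, since Φ over one subset is degenerately
zero.

## Degenerate data: the removal loop

Sparse recordings produce nearly constant bin sequences, whose covariance
blocks are numerically singular. `residual_covariance` declares a block
rank-deficient when its determinant is non-positive or its condition number
exceeds 1e12 (the failure is otherwise criterion-free in practice);
`robust_phi` reacts by removing the neuron with the lowest Bernoulli
variance $p(1-p)$ over the analyzed window — the window that actually
failed, not the whole session — and retrying, one neuron per attempt, until
a valid value emerges or fewer than two neurons remain. Ties break to the
lower original index; the removal history is attached to the result. The
same variance ranks the top-15 selection. The metric is order-free, so it
misses long on/off runs; that known weakness is not corrected here.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `bin_size` | 0.03 | s | empirical compromise: fine enough for spike patterns, coarse enough that bins are not almost all off |
| `lag_bins` | 1, or `sweep_dt` grid 1–40 | bins | 1–40 bins at 0.03 s spans 0.03–1.2 s, enclosing the 50–500 ms information-processing window and reported optima (0.36–0.56 s) |
| `n_periods` | 8 | — | per-session temporal resolution of the analysis pipeline |
| `alpha` | 0.05 | — | per-edge significance for the connectivity graph |
| `n_hypotheses` | 15 | — | Bonferroni family size; 0.05/15 = 1/300 ≈ 0.0033 (conventionally printed 0.0034), parameterized because the family decomposition is context-dependent |
| `cap` | 15 | neurons | brute-force bipartition limit |
| `top_k` | 15 | neurons | the 15-neuron approximation and its Louvain/atomic hybrids |

Covariances use the unbiased $n-1$ denominator, and the regression carries
no intercept after per-neuron mean removal (the standard covariance
formulation; whether the original computation subtracted means is unstated,
and mean subtraction is the defensible default). Determinants are computed
in log space via pivoted factorization. If $L(M) \le 10^{-9}$ — possible for
low-variance binary data, where $\ln[(2\pi e)\,p(1-p)]$ crosses zero near
$p(1-p) \approx 0.059$ — the raw value is returned with a
`normalization_degenerate` flag rather than dividing by a vanishing number.

## The synthetic world

The generators emulate the statistical shape of hippocampal CA1 tetrode
sessions: 15–56 simultaneously recorded units, 15–20 minute sessions,
sparse spiking. Defaults: 16 neurons, 960 s, on-probability 0.1 per 0.03 s
bin (≈ 3.3 Hz).

`gen_coupled` runs a binary linear-threshold network: neuron $i$ fires at
bin $t$ with probability
$\mathrm{clip}(b + \sum_j w_{ij}\,s_j(t-\Delta)/\deg_i)$, with
within-community weights `coupling`, between-community weights
`between_coupling`, and delay `delay_bins`. This was chosen over
Hawkes or biophysical neuron models because the acceptance surface needs
controllable second-order structure, not biophysical realism; at low rates
the Gaussian approximation of the binary process is accurate enough for Φ
to respond monotonically to the coupling (tested on a 2-node sweep). Spike
times sit at bin centers so binarization at the generating bin size
round-trips exactly; with zero coupling the dynamics reduce draw-for-draw
to the independent Bernoulli generator under the same seed.

`gen_session_with_rewards` concatenates 8 blocks whose coupling follows a
seeded random permutation of an increasing schedule $c_p$, and plants
reward events as a Poisson process whose rate grows with $c_p$ (3× spread
from least- to most-coupled period at `phi_reward_link = 1`; constant rate
at 0 — the null). One design decision deserves emphasis: the per-period
baseline is compensated to $b_p = b\,(1-c_p)$ so the mean-field stationary
rate $b_p/(1-c_p)$ is flat across periods. Without this, coupling raises
overall activity, which inflates $\det\Sigma(M_k)$ and hence $L(M)$, and
the planted link — clearly present in raw Φ — cancels out of the
*normalized* Φ. Compensation makes the coupling manipulate correlational
structure only, which is the property the generator is documented to plant.

What a green test does **not** establish: the generators have no refractory
periods, place fields, theta rhythmicity, bursting, or nonstationary
drift; neuron counts and rates are homogeneous within a session. Passing
the planted-structure tests shows the estimators and optimizers work where
the truth is known, not that real recordings satisfy their assumptions.

## Scaling of stochastic acceptance checks

The stochastic acceptance criteria run at sizes fitted to a CI-scale time
budget (the whole suite runs in ~3 minutes on one CPU): null and
structure-recovery checks use 10⁴-bin sessions, and the power/level check
of the Φ–reward correlation uses 20 seeds per condition with 8 sessions ×
8 periods of 60 s each (64 period records, the same pooled-record scale the
permutation-null example prescribes). 480 s sessions are the shortest at
which the planted link behaves as documented — over very short periods the
min-variance term in $L(M)$ is noisy enough to mask it — so the scale-down
stops there rather than at the paper-length 960 s.

## Known limitations

* The discrete-entropy oracle is restricted to ≤ 10 nodes by design.
* Louvain restarts mitigate but cannot eliminate order-dependence on
  adversarial graphs; the seed is always recorded.
* Φ normalization by $L(M)$ is fragile when the least-variable subset is
  near the $\ln[(2\pi e)\,\sigma^2] = 0$ crossing; the warning flag should
  be checked in downstream analyses.
* No fast minimum-information-partition search (Queyranne-style) and no
  spectral/SBM community alternatives; the partition interface accepts any
  `phi_partition`, so both can be plugged in externally.
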