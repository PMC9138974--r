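# phispike

Integrated information (Φ) for spike-train recordings, with the partition
approximations that make it computable on real neural data.

## The problem

Integrated information quantifies how much information a system of
interacting units generates *above and beyond its parts* — the information
lost when the system is cut into independent subsets. For multi-neuron
spike recordings it is an attractive, task-independent marker of how well a
network integrates information, e.g. across learning. Two obstacles make
the textbook definition unusable on recordings of tens of neurons:

1. The minimum information partition must be searched over all set
   partitions — `Bell(N)` of them (`bell_number(25)` =
   4,638,590,332,229,999,353). Even the bipartition-only restriction
   (`count_bipartitions(N)` = 2^(N−1) − 1) is only tractable up to ~15
   units.
2. Plug-in entropy estimates are unstable for sparse binary data.

`phispike` implements the standard practical answer — the autoregressive
estimator Φ_AR of Barrett & Seth — together with three partition
approximations used for spike data:

* **mib** — exhaustive minimum-information-bipartition search (brute force,
  ≤ 15 neurons, usually combined with top-15 neuron selection);
* **atomic** — every neuron its own subset (fastest, ignores cluster
  structure);
* **louvain** — subsets are the communities of a significance-thresholded
  spike-correlation network, found by a from-scratch Louvain modularity
  optimizer (two-phase, flat refinement, seeded restarts).

## The estimator

Spike times are binarized into on/off states over 0.03 s bins, giving state
vectors X_t. With Σ(X) the equal-time covariance and Σ(E_X) the residual
covariance of the least-squares prediction of X_{t+Δt} from X_t,

    Φ_raw(M) = ½ ln[det Σ(X) / det Σ(E_X)]
             − Σ_k ½ ln[det Σ(M_k) / det Σ(E_{M_k})]

for a partition M = {M_1, …, M_r} (natural logs; the classical bipartition
formula generalized to r subsets), normalized by
L(M) = ½ ln[min_k (2πe)^{|M_k|} det Σ(M_k)] to diminish the influence of
subset sizes. Rank-deficient covariances (near-constant neurons) trigger
iterative removal of the lowest-Bernoulli-variance neuron (`robust_phi`).
The lag Δt is chosen to maximize average Φ (`sweep_dt`); session-level
analysis splits each session into 8 periods, normalizes Φ by the neuron
count used, and Spearman-correlates it with the reward rate under a
Bonferroni-corrected threshold (`period_phi`, `correlate_phi_rewards`).

Seeded synthetic generators (`gen_independent`, `gen_coupled`,
`gen_session_with_rewards`) provide null, coupled, community-structured and
reward-linked spiking data, so the whole pipeline is testable without any
recordings.

## Worked example

```r
library(phispike)

spec <- generator_spec(n_neurons = 16, duration_s = 960, coupling = 0.4,
                       base_rate = 0.12, communities = c(8, 8),
                       between_coupling = 0.05, seed = 42)
session <- gen_session_with_rewards(spec, phi_reward_link = 1)
binned  <- binarize(session, 0.03)
binned
#> binned_matrix: 16 neurons x 32000 bins (bin 0.03 s, start 0.000 s), on-fraction 0.104

robust_phi(binned, method = "mib", lag_bins = 1, top_k = 15)
#> phi_result: phi = 0.00132486 (raw 0.00212057, L = 1.601), 15 neurons, r = 2, lag 1 bins
robust_phi(binned, method = "atomic", lag_bins = 1)
#> phi_result: phi = 0.0883596 (raw 0.0190949, L = 0.2161), 16 neurons, r = 16, lag 1 bins
robust_phi(binned, method = "louvain", lag_bins = 1)
#> phi_result: phi = 0.0825994 (raw 0.0179757, L = 0.2176), 16 neurons, r = 11, lag 1 bins
```

The atomic partition gives the largest value (it can miss weak spots that a
finer community partition exposes), the Louvain partition sits just below
it, and the 15-neuron bipartition value is an order of magnitude smaller —
a smaller system integrates less information even after normalization.

```r
rec <- period_phi(session, list(method = "atomic", lag_bins = 1))
rec[, c("period_index", "phi_normalized", "n_neurons_used", "reward_rate")]
#>   period_index phi_normalized n_neurons_used reward_rate
#> 1            0    0.008361186             16  0.10000000
#> 2            1    0.018130564             16  0.19166667
#> 3            2    0.027547246             16  0.21666667
#> ...
correlate_phi_rewards(rec, n_hypotheses = 15)
#> correlation_report: rho = 0.4791, p = 0.2297 (n = 8) ns at alpha 0.003333
```

Per-period Φ and reward rate co-vary positively here (the generator plants
the link), but 8 periods from a single session cannot clear a Bonferroni
threshold of 0.05/15; pooling sessions — as the analysis pipeline does —
provides the power (see `tests/testthat/test-acceptance.R`, criterion 8).

## Command line

```sh
inst/cli/phi-spike simulate --seed 1 --out data/
inst/cli/phi-spike run --spikes data/spikes.csv --events data/events.csv \
    --method atomic15 --lag auto --out results/
```

Subcommands: `simulate`, `binarize`, `phi`, `sweep-dt`, `run`, `correlate`.
All outputs are CSV/JSON; identical configuration and seed give
byte-identical outputs.
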