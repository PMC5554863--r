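# comdyn — cohesive and disjoint community dynamics in temporal networks

`comdyn` is an R toolkit for asking not just *how often* the nodes of a
temporal network change community, but *how*: do groups of nodes move between
communities together (**cohesive** switches), or do nodes drift off on their
own (**disjoint** switches)? The distinction matters wherever coordinated
reconfiguration and independent, noise-like reconfiguration have different
interpretations — the motivating case is dynamic functional brain networks
during motor learning, where whole-brain coherence networks are tracked
across time windows of an fMRI session.

## What it computes

A temporal network is an ordered stack of `T` weighted adjacency matrices
(layers) on `N` shared nodes. Communities are found by maximizing the
multilayer modularity

```
Q = 1/(2μ) Σ_{ijlr} [ (A_ijl − γ P_ijl) δ_lr + δ_ij ω 1(|l−r|=1) ] δ(g_il, g_jr)
```

with the Newman–Girvan null `P_ij = k_i k_j / 2m` per layer, structural
resolution `γ`, ordinal temporal coupling `ω`, and a Louvain-style greedy
optimizer run as an ensemble (default 100 optimizations) because the
landscape is nearly degenerate. From each community trajectory `g` (an
`N × T` label matrix) the package scores every transition: a node whose label
changes is grouped with all other nodes making the same source-to-destination
move. Per node, over the `T − 1` transitions:

* **flexibility** — fraction of transitions at which the node switches;
* **disjointedness** — fraction at which it switches *alone* (no other node
  makes the same i→j move);
* **cohesion matrix / cohesion strength** — pairwise co-switch rates and
  their row sums (how many partners a node moves with, on average).

Every switch is either disjoint or cohesive, so flexibility decomposes
exactly into the two rates. Statistical reference comes from a **temporal
null model** (the same layers in random order, re-detected from scratch), and
group comparisons use t-tests, repeated-measures ANOVA, permutation tests
(with BH false-discovery-rate control) over a `(γ, ω)` resolution grid.
Behavioural learning rates are estimated by a robust (least-absolute-residual)
fit of the double-exponential movement-time model
`MT = D1 e^{−tκ} + D2 e^{−tλ}`, whose fast rate κ is "the learning rate".

The package also builds the networks themselves: windowed, band-averaged
Morlet wavelet coherence (default band 0.06–0.12 Hz, 80-sample windows) from
multivariate time series, and ships a synthetic-data generator that plants
community trajectories with *known* cohesive and disjoint events, realizes
them as weighted networks or band-limited time series, and emits the exact
ground-truth event log.

## Worked example

```r
library(comdyn)

spec    <- plant_spec(seed = 42)          # N = 30, T = 10, K = 3 communities
planted <- plant_trajectory(spec)         # trajectory + ground-truth events
net     <- realize_network(planted$trajectory, spec)
net
#> <multilayer_network> 30 nodes x 10 layers (mode: coherence)

ens     <- optimize_ensemble(net, gamma = 1, omega = 1, n_opt = 20, seed = 7)
metrics <- ensemble_metrics(ens)
glance(metrics)
#> # A tibble: 1 × 6
#>   n_nodes n_runs mean_flexibility mean_disjointedness mean_cohesion mean_cohesion_strength
#> 1      30     20            0.106              0.0809        0.0254                 0.0685

nulls <- null_distribution(net, metric = "cohesion_strength",
                           n_null = 10, n_opt = 10, seed = 8)
sprintf("observed %.3f vs null %.3f +/- %.3f",
        mean(metrics$cohesion_strength), mean(nulls$value), sd(nulls$value))
#> "observed 0.069 vs null 0.717 +/- 0.152"

curve <- generate_learning_curve(d1 = 2, kappa = 0.1, d2 = 1, lambda = 0.01,
                                 noise_sd = 0.05, seed = 1)
fit_double_exponential(curve$mt, curve$trial)
#> <learning_fit> MT = D1 exp(-t kappa) + D2 exp(-t lambda)
#>   D1 = 2.064, kappa = 0.0928, D2 = 0.9449, lambda = 0.009196
#>   sum |resid| = 2.797
```

Reading the numbers: each node switches community at ~11% of transitions
(`mean_flexibility`), three quarters of those switches are lone moves
(`mean_disjointedness` 0.081 of 0.106), and a node co-switches with ~0.07
partners per transition (`mean_cohesion_strength`) — close to the rates the
generator planted (p_disjoint = 0.1, one 3-node group move at 15% of
transitions). On this synthetic process the temporal null shows *more*
cohesive reconfiguration than the intact ordering: shuffling strongly
distinct layers forces whole blocks to relabel between consecutive windows,
whereas the planted process changes slowly. The learning fit recovers the
generating parameters (κ = 0.093 vs true 0.10) from a noisy curve.

`autoplot()` works on trajectories, cohesion matrices, metric tables and
learning fits; `tidy()`/`glance()` on fitted objects. A thin CLI over the
same functions lives at `inst/cli/comdyn.R` (subcommands `simulate`,
`connect`, `detect`, `metrics`, `null`, `fit-learning`, `run`), and
`run_pipeline()` executes a whole simulate → detect → metrics → null →
learning run from one YAML config with a single master seed.

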