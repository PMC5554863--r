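---
title: "Methods: cohesive and disjoint community dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohesive and disjoint community dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comdyn)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices behind them,
and what the synthetic test bed does and does not establish about real data.

## The multilayer community model

A temporal network is an ordered stack of `T` symmetric, non-negative,
zero-diagonal `N × N` weight matrices sharing one node set — here, typically
windowed coherence networks over brain regions. Community structure is
estimated jointly across layers by maximizing multilayer modularity

$$Q = \frac{1}{2\mu}\sum_{ijlr}\Big[(A_{ijl} - \gamma P_{ijl})\,\delta_{lr}
      + \delta_{ij}\,\omega\,\mathbb{1}(|l-r|=1)\Big]\,
      \delta(g_{il}, g_{jr}),$$

where $P_{ijl} = k_i k_j / 2m$ is the Newman–Girvan null of layer $l$
(strengths $k$, total weight $2m$), $\gamma > 0$ is the structural
resolution, $\omega \ge 0$ the ordinal coupling between a node and itself in
consecutive layers, and $2\mu$ the total intra-layer weight plus total
coupling weight $2\omega N(T-1)$. Two conventions deserve note:

* **The null's denominator.** The null is implemented with the standard
  $2m = \sum_{ij} A_{ij}$ (total weight), which is the convention under which
  mass conservation $\sum_{ij} P_{ij} = \sum_{ij} A_{ij}$ — the property the
  null model exists to provide — holds exactly, and under which the
  single-community partition of any single layer scores exactly zero.
  Descriptions of this null occasionally paraphrase $m$ as an "average"
  weight; the implementation follows the convention that preserves mass.
* **The normalization $2\mu$.** Comparisons of Q are only meaningful within a
  fixed normalization; the widely used total-weight-plus-coupling convention
  is implemented and reported alongside Q.

The $i = j$ null terms are part of the sum (as in static Newman–Girvan
modularity), which is what makes the two-disjoint-edges closed form
($Q = 0.5$ for the natural partition) come out exactly.

### Optimization

`louvain_multilayer()` maximizes Q by greedy local moves over *node-layers*
in one global label space: every node-layer starts as its own singleton,
sweeps in randomized order move each node-layer to the community with the
largest modularity gain, and converged sweeps alternate with community
contraction (super-node) sweeps. Plain Louvain stops after contraction
converges, which on coupled temporal stacks can leave single node-layer
improvements on the table; the optimizer therefore *iterates* — after each
contraction phase it re-sweeps at node-layer granularity and re-enters
contraction if anything moved — until no single node-layer reassignment
improves Q by more than `1e-10`. That tolerance is also the move threshold;
ties are broken toward the incumbent community, then the lowest candidate
label. The returned trajectory is thus a genuine local maximum at node-layer
granularity, and its labels are directly comparable across layers without
post-hoc matching.

Because the modularity landscape is nearly degenerate, all dynamic metrics
are averaged over an ensemble of optimizations (`optimize_ensemble()`,
default `n_opt = 100`; per-run seeds derive deterministically from one master
seed). Metrics are averaged across runs, never computed on a consensus
partition.

## Switch classification and the three metrics

At each of the `T − 1` transitions, nodes whose label changes are grouped by
their (source, destination) label pair: a group of two or more is one
*cohesive* event, a singleton is one *disjoint* event. Per node,
`flexibility` is the fraction of transitions with any change,
`disjointedness` the fraction with a lone change, and the cohesion matrix
holds pairwise co-switch rates whose row sums (diagonal excluded) give
`cohesion_strength`. Since every change lands in exactly one event,
flexibility = disjointedness + cohesive rate, identically; community splits
and merges are purely cohesive (a split's two halves each move as a group;
nothing moves alone).

**Grouping rule.** Requiring identical (source, destination) pairs — not
merely a shared destination — is the reading consistent with the disjoint
definition ("no other node makes the same i→j move") and with group moves
between two communities. The laxer destination-only variant is available via
`rule = "dest-only"` on every metric for sensitivity analysis; the two differ
exactly when nodes from different sources converge on one destination at the
same transition.

Trajectories with `T = 2` are allowed (denominator 1). `T = 1` is an error:
there is no transition to score.

## The temporal null model

`temporal_permute()` reorders layers uniformly at random, preserving each
layer bit-exactly; interlayer coupling stays ordinal in the permuted order.
`null_distribution()` re-runs the *full* detection ensemble on each permuted
network (the null permutes the network, not the trajectory labels) and
records the whole-network ensemble-averaged metric, giving the reference
distribution for observed-vs-null contrasts. Permutations are sampled with
replacement across the ensemble: at `T = 25` there are `25!` orderings and
collisions are negligible. Defaults are scaled to 20 × 20
(nulls × optimizations) for routine use; the 100 × 100 study scale is one
argument away (`scale = "paper"` in `run_pipeline()`).

On strongly modular synthetic stacks whose planted structure changes slowly,
the null typically shows *more* reconfiguration than the intact order —
shuffling makes consecutive windows maximally dissimilar. The direction of
the observed-vs-null contrast is therefore a property of the data, not of the
machinery.

## Statistical procedures

Group tests wrap the classical machinery: pooled-variance two-sample t,
paired t, one-way repeated-measures ANOVA in closed form
(`F = MS_condition / MS_error`, error = subject × condition interaction;
cross-checked against `aov()` in the tests), and Pearson correlation.
`permutation_test()` uses the difference-of-means statistic (label shuffling
unpaired, sign flipping paired) with the add-one estimate
`p = (1 + #{|T*| ≥ |T|}) / (1 + n_perm)`, which is never anti-conservative at
any `n_perm`. `bh_fdr()` implements the Benjamini–Hochberg step-up rule and
returns both the rejection mask and adjusted p-values.

`grid_contrast()` runs the per-node permutation test at every cell of a
`(γ, ω)` grid (the conventional sweep is 0.91–1.10 in steps of 0.01 around
the default resolution 1) and controls FDR **per grid cell across nodes** by
default; pooling the whole node-by-grid table is available via
`fdr_scope = "pooled"`, since which scope the convention intends is genuinely
ambiguous. A node is reported *consistent* when rejected in all grid cells
(`consistency_frac = 1`); the fraction is exposed because "consistent across
the parameter range" admits laxer operationalizations.

## The learning-rate model

Movement times across trials are modelled as
$MT_t = D_1 e^{-t\kappa} + D_2 e^{-t\lambda}$ with $t$ the trial number
starting at 1; $\kappa \ge \lambda \ge 0$ (the model is symmetric under
swapping its two terms, so the ordering is a normalization, applied after
fitting) and $\kappa$ is the learning rate. Fitting minimizes the sum of
absolute residuals (LAR) — robust to the occasional aberrant trial — via
iteratively reweighted `nlsLM` with weights $1/\max(|r|, 10^{-4}\,s)$
($s$ the median absolute residual), multistarted from a deterministic grid
($\kappa \in \{0.01, 0.05, 0.1, 0.3\}$, $\lambda \in \{0.001, 0.01\}$, with
amplitudes at their conditional least-squares values, which are closed-form
given the rates), followed by a Nelder–Mead polish of the exact L1 objective.
The data are internally rescaled to unit mean so the procedure is
scale-equivariant up to solver precision.

Degenerate inputs: exactly constant curves short-circuit to
$D_1 = 0, \kappa = 0$ with a `no_learning` flag (a zero learning rate means
no behavioural change); more generally, when the fitted fast term's total
drop across the observed trials is numerically nil, $\kappa$ is unidentified
and reported as 0. When $\kappa \approx \lambda$ the two rates are not
separately identifiable; `model = "single"` fits the collapsed form
$D_1 e^{-t\kappa} + D_2$.

A calibration note from the package's own tests: at the generator's reference
conditions (100 trials, 5% multiplicative noise), the median relative error
of $\hat\kappa$ sits near 5%. That is a statistical property of LAR — its
efficiency under Gaussian noise is roughly 2/π of least squares — not a
solver artefact; a variance-matched weighted least-squares fit does better on
clean Gaussian noise, but LAR is the method of record because it is robust to
the contaminated trials real curves contain (under 10% contamination it beats
least squares in ~9 of 10 draws).

## Wavelet coherence networks

`wavelet_band_coherence()` computes magnitude-squared wavelet coherence
between every pair of series: analytic Morlet CWT ($\omega_0 = 6$, the field
default; configurable), smoothing in time (Gaussian of width equal to the
scale) and across scale (0.6-octave boxcar), coherence as the smoothed
cross-spectrum magnitude squared over the product of smoothed powers, then
averaged over all time points and over scales whose equivalent Fourier
frequency lies in the requested band (default 0.06–0.12 Hz). Without
smoothing the ratio is identically 1; with it, duplicated series still score
1 and independent noise scores well below. The scale grid uses 12 voices per
octave with one octave of margin on each side of the band so that in-band
scales are smoothed against real neighbours.

Numerical conventions: the diagonal is forced to 0 (degree sums never count
self-edges); edge-affected time points inside the cone of influence are
*included* — the windows of interest are only ~80 samples, and excluding the
COI would discard most of the window; this is a documented limitation, shared
with any short-window coherence estimate. Windows shorter than 3 cycles of
the band's lower edge trigger a warning. Zero-variance series are an error
naming the offending node. Windowing is contiguous with a configurable step;
trailing samples that do not fill a window are dropped. Whether band
averaging should use whole-window cross-spectra instead of time-and-band
averaging is underdetermined by convention; time-and-band averaging was
chosen for simplicity and determinism.

## The synthetic test bed

`plant_spec()`/`plant_trajectory()` generate trajectories with *known*
events: the first layer is a balanced K-partition; at each transition one
cohesive event (probability `p_cohesive`, `group_size` co-members moving to a
uniformly chosen other community) and per-node lone moves (probability
`p_disjoint`) are planted. A lone move is only planted toward a destination
that no other node is entering from the same source, so the emitted log is
exact ground truth for the classifier — a design choice that slightly
suppresses the realized lone-switch rate when K is small and many nodes try
to move at once (with K communities a source has only K − 1 usable
destinations per transition). At the defaults this suppression is negligible;
rate-calibration checks use K = 6 where the realized rate matches the nominal
one to binomial precision.

Defaults (`N = 30, T = 10, K = 3`, `w_in/w_out = 0.9/0.1`, edge noise 0.05,
`p_cohesive = 0.15` with groups of 3, `p_disjoint = 0.1`) describe a strongly
modular, slowly reconfiguring process: most transitions are quiet, lone moves
outnumber group moves, and detection at `γ = ω = 1` recovers the planted
trajectory almost perfectly (mean adjusted Rand index > 0.97 in the
acceptance run). A `preset = "paper-like"` switches to `N = 112` nodes and
`T = 25` windows, the scale of a whole-brain windowed analysis.
`realize_network()` draws truncated-Gaussian edge weights around block means;
`realize_timeseries()` gives every community one band-limited latent signal
per layer span plus white noise at a stated SNR, so the coherence pipeline
can be exercised end to end.

What passing tests on this generator establishes: the metric definitions, the
optimizer, the null model, and the statistics behave as specified on networks
with planted, strongly identifiable structure. What they do not establish:
performance on real fMRI coherence networks, whose community structure is far
weaker and whose noise is structured (physiological cycles, motion,
hemodynamics); with weak structure, detection variance — not the metric
machinery — dominates, which is exactly why metrics are ensemble-averaged and
referenced to the temporal null.

## Problem sizes and tolerances

The shipped tests run at deliberately small scale — trajectories up to
`N = 10, T = 8` against brute-force oracles (1,000 random instances),
exhaustive modularity enumeration at `N = 4, T = 2` (all 4,140 joint
partitions), planted recovery at `N = 30, T = 10` over 20 realizations,
permutation calibration with 1,000 draws of 1,000 permutations — sizes chosen
so the whole suite completes in minutes while each check retains its
statistical force. Exact identities (oracle equality, layer-multiset
preservation, BH masks) are asserted identically; floating-point identities
at `1e-12`–`1e-15`; modularity agreement with brute force at `1e-12`; and
Monte-Carlo comparisons at 2–3 standard errors of the relevant estimate.
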