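---
title: "Methods: continuous-time information flow in developing spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous-time information flow in developing spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`infoflow` quantifies how directed information flow emerges, locks in, and
specialises in developing networks of spiking units — dissociated neural
cultures recorded on multi-electrode arrays, or simulated networks. The
pipeline is: preprocess spike trains; estimate pairwise transfer entropy
(TE) rates in continuous time; test each rate against surrogates and build
a Bonferroni-thresholded functional network per session; detect per-node
and population bursts and average TE locally within bursts; and correlate
edge weights, per-node flows, burst positions, and transmitter/receiver
role ratios across sessions.

## The estimation problem

For a pair of point processes, the TE rate from source $Y$ to target $X$ is

$$\dot T_{Y \to X} \;=\; \lim_{\tau\to\infty} \frac{1}{\tau} \sum_{i=1}^{N_X}
 \ln \frac{\lambda_{x \mid x_{<t}, y_{<t}}[x_i]}
          {\lambda_{x \mid x_{<t}}[x_i]},$$

the sum over target spikes of the log ratio of the target's instantaneous
firing rate conditioned on both histories versus its own history alone.
Working directly on interspike intervals sidesteps time binning entirely: a
history at time $t$ is the vector of the $l$ most recent inter-event
intervals (the first component being the time back to the most recent
spike). With the default target length $l_X = 4$ and source length
$l_Y = 2$, a history spans several mean interspike intervals while
retaining the microsecond precision of the raw data — a regime no
discrete-time (binned) estimator can reach, since matching the data's time
precision would require history vectors of tens of thousands of bins.

### Nearest-neighbour realisation

Both conditional-rate terms are density ratios between history
distributions *at target spikes* and *at randomly placed times*
($N_U = 50\,N_X$ uniform samples by default). The package estimates them
with a shared-radius digamma scheme of the Kozachenko–Leonenko/KSG family:
for target spike $i$, the radius $\varepsilon_i$ of the $k$-th nearest
neighbour (max-norm, $k_{\mathrm{global}} = 10$) is found within the joint
(target ⧺ source, dimension $l_X + l_Y$) at-spike sample, neighbours within
$\varepsilon_i$ are counted in the joint at-random sample ($n^{JR}_i$), the
target-only at-spike sample ($n^{TS}_i$), and the target-only at-random
sample ($n^{TR}_i$), and the local contribution is

$$\mathrm{local}_i \;=\; \psi(k) - \psi(n^{JR}_i + 1) - \psi(n^{TS}_i)
 + \psi(n^{TR}_i + 1),$$

with $\dot T = \sum_i \mathrm{local}_i / \tau$. Sharing one radius across
all four terms cancels the ball-volume and sample-size terms exactly. This
matters more than it may appear: interspike-interval history samples are
*not* i.i.d. — consecutive spike histories overlap in $l_X - 1$
components, and random samples falling in the same interspike gap share
every component but the first, so the random cloud concentrates on
one-dimensional line segments. A plain difference of two cross-sample
divergence estimates is biased by several nats per second on independent
1 Hz Poisson pairs under exactly these degeneracies, while the
shared-radius form stays within a few hundredths of a nat per second of
zero (and is unbiased on genuinely i.i.d. samples). The standalone
`knn_divergence()` estimator retains the classical ratio form and is
accurate on i.i.d. samples; the TE/AIS paths use the count form throughout.

Per-spike locals sum to $\dot T \tau$ by construction (to within floating
point), which is the identity burst-local averaging relies on. Estimates
are invariant under common time rescaling (rates scale inversely) and time
offsets.

### Active information storage

AIS — how much a process's own past predicts its present — uses the
target-only analogue: radius within the at-spike sample of dimension
$l_X$, counts in the random-history pool, scaled by $N_X/\tau$. The raw
value is bias-corrected by subtracting the mean over surrogate sets in
which the "spike" histories are re-drawn at fresh uniform times, giving a
corrected value centred on zero for memoryless (Poisson) trains. A small
residual negative bias of roughly 1% of the firing rate remains, traceable
to the structural difference between overlapping spike histories and
line-degenerate random histories; it is immaterial for the embedding-length
selection AIS is used for, which compares AIS *across* lengths on the same
trains.

### Jitter

Recordings sampled on a fixed clock (25 kHz, i.e. a 40 µs grid) contain
exactly tied intervals, which nearest-neighbour estimators must not see.
`jitter_spike_times()` adds independent Uniform(±20 µs) noise — half the
grid pitch — and the estimators refuse un-jittered tied data outright
rather than mishandling zero distances.

## Surrogate significance testing

The null is conditional independence of target spiking from the source
history. Every surrogate leaves the target process untouched. The default
construction rotates the source train circularly by a random offset
(uniform over the central 90% of the window) and recomputes source
histories coherently at the target spikes *and* at the random reference
points. Preserving that temporal coupling to a single (rotated) source
realisation is essential: constructions that re-pair or re-draw source
histories — including resampling them from a spike-anchored pool
conditioned on similar target histories, which is kept as
`method = "history_resample"` — change the sample's internal duplication
and alignment structure and shift the surrogate distribution upward at
realistic sample sizes, destroying false-positive calibration. With source
rotation, p-values on independent Poisson pairs are uniform and the
fraction of pairs exceeding the 95th percentile of their own 100-surrogate
distribution sits at 5% as it should; a deterministic 5 ms relay exceeds
every surrogate.

P-values come from a Gaussian fit to the `N_surrogates = 100` values,
$p = 1 - \Phi((\hat T - \mu)/\sigma)$: family-wise thresholds such as
$0.01/3422 \approx 2.9\times10^{-6}$ are far below $1/N_{\mathrm{surr}}$
and unreachable by counting. Functional networks zero every
non-significant TE and use $n_{\mathrm{tests}} = n(n-1)$ over the retained
nodes; the count actually used is recorded on the network object.

## Bursts and burst-local TE

Single-node bursts: scanning spikes in order, a burst opens when the span
from a spike back to its $k$-th predecessor is below $\alpha$, and runs
until an interspike interval exceeds $a\alpha$ (ending at the earlier
spike of that interval). $\alpha$ defaults to half the node's mean
interspike interval, computed per node — spans of $k$ spikes shorter than
half the mean ISI are unambiguously "bursty" — with a recording-wide
variant available (`per_node_alpha = FALSE`). Population bursts are an
event sweep over the count of simultaneously bursting nodes: open when the
count exceeds $\beta$, close when it drops below $\gamma$, boundaries
placed exactly at the crossing endpoints. Presets: culture
($k{=}2, a{=}3, \beta{=}15, \gamma{=}10$) and model
($k{=}1, a{=}1.5, \beta{=}2, \gamma{=}1$) for the much more stereotyped
simulated dynamics.

Burst position is the rank (1 = earliest, ties by node label) of a node's
first spike inside a population burst, averaged over bursts it joins. The
ranking statistic is a design choice — first-spike rank reproduces the
"leader node" semantics of the burst-propagation literature.

Burst-local TE sums the per-spike local contributions over target spikes
inside population bursts and divides by their number (nats/spike); its
significance reuses the surrogate machinery verbatim, averaging each
surrogate's locals over the same in-burst spikes. Downstream role analyses
gate on at least 10 significant burst-local values per recording, the same
gate applied to lock-in correlations (at least 10 significant TE values in
both sessions).

## Embedding-length selection

One consensus $l_X$ (then $l_Y$) serves all nodes and sessions so that
estimator bias is matched across comparisons. Starting at 1, the length
grows while the mean bias-corrected AIS (for $l_X$; surrogate-mean-
subtracted TE over ordered pairs for $l_Y$) increases significantly at
$p < 0.05$ under a paired two-sided t-test across nodes (pairing matches
"increase across the electrodes"; Welch's unpaired test is available via
`paired = FALSE`). The shipped defaults $l_X = 4$, $l_Y = 2$ make the
selection step optional.

## The synthetic developmental protocol

`simulate_network()` generates the package's reference synthetic data: 59
Izhikevich neurons (tonic-spiking constants $a{=}0.02, b{=}0.2, c{=}-65,
d{=}6$), all-to-all excitatory pulse coupling without self-connections or
delays (a presynaptic spike kicks every other membrane potential by the
synaptic weight, making the coupling independent of the integration step),
and additive exponential-window STDP ($A_+ = A_- = 4\times10^{-4}$,
$\tau_\pm = 20$ ms) with weights clipped to $[0, g_{\max} = 10]$.
Integration uses the classic two-half-step membrane update at
$dt = 0.5$ ms over 550 s.

Constants the protocol does not pin were fixed once: the tonic drive
(37.5, ±0.7 uniform per-neuron spread) is calibrated so an uncoupled
neuron fires near 100 Hz — about $5\times10^3$ spikes per 50 s window,
matching the order of spike counts per node per analysis hour in dense
culture recordings — and a white-noise current (SD 1.5) plus the drive
spread desynchronise the initial tonic phases. Initial weights are
Uniform(0, 0.6): small enough that the early network fires near-
independently, large enough that the causal potentiation feedback (a
presynaptic kick advances the postsynaptic phase, so potentiation of the
causal direction outpaces depression) saturates within the 550 s budget.
Under these defaults the 200–250 s window shows no population bursts, the
400–450 s window shows the first few, and the 500–550 s window is
dominated by periodic network-wide events in which nearly all neurons
participate — far more regular than biological culture bursts, as expected
of a homogeneous all-excitatory model. The median spike count per neuron
per 50 s window is ≈5.2×10³ and stable across seeds.

The synapse model is a design choice with consequences. An optional
exponential synaptic-current filter (`synaptic_tau`) spreads each spike's
depolarisation over a few milliseconds, but at the small plasticity
magnitudes of the protocol the resulting weaker pre/post timing causality
cannot complete the developmental transition within 550 s, so the default
is instantaneous coupling. The price is the character of the late state:
instead of quiescence-separated avalanches that recruit the network as a
wave, the mature network settles into a fast (~40 Hz) near-synchronous
oscillation in which every cycle is a network-wide event. Burst
*positions* are still well defined and stable, but their relation to
information flow differs from the avalanche regime: a strongly-driven
node is pulled to the front of each cycle, so high inward flow associates
with *early*, not late, positions. The positional-role sign structure of
avalanche-type bursting (late bursters as receivers, early bursters as
transmitters) is therefore not reproduced by this generator, and the
acceptance test that asserts it documents the discrepancy rather than
hiding it.

What the generator also does *not* emulate: multi-unit (per-electrode)
aggregation, inhibitory populations, conduction delays, rate
heterogeneity spanning orders of magnitude, and the irregular burst
timing of real cultures. Passing the end-to-end tests on this generator
therefore demonstrates that the pipeline recovers directed flow structure
and burst gating from spiking dynamics of this class, not that it
reproduces every statistic of culture data.

## Longitudinal statistics

Lock-in statistics are Spearman correlations with average-rank ties:
between session pairs over all ordered node-pair TE values (zeros for
non-significant entries), over per-node mean outgoing/incoming flows, and
over burst-local role ratios $\mathrm{out}/(\mathrm{in}+\mathrm{out})$.
Two-sided p-values use full permutation enumeration for $n \le 7$ and the
$t$-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ above (exhaustive
enumeration beyond ~10 observations is not computable; at the sizes where
the approximation takes over it is accurate to well below the decision
thresholds used). Mean-TE comparisons between sessions use the two-sided
pooled-variance Student's t-test on the full TE vectors, with Bonferroni
factors supplied by the caller (family sizes — session pairs per culture,
panels per figure — are context-dependent and therefore explicit
arguments, not hidden defaults). Families of such tests are summarised by
the binomial significance-count test: $P(\mathrm{Bin}(n, 0.05) \ge k)$
under the null of uniform p-values, starred at 0.05/0.001 after the
caller's correction factor.

Distribution summaries report the mean TE over all pairs (zeros included),
the significant-edge count, quartiles of significant values after removing
points more than 10 SDs above the mean (a display-only exclusion), and a
Gaussian-kernel density with bandwidth 10% of the data range, computed
only when at least 10 significant values exist. A log-normality check of
significant TE values is deliberately limited to a descriptive normality
test on logs (`shapiro.test` on `log(values)` by the user); the package
takes no position on distributional family.

## Problem sizes in the shipped tests

The test-suite calibration studies use deliberately modest sizes chosen
once as part of the study design: 1 Hz Poisson pairs over 300 s windows
(about 300 target spikes, 15 000 random samples per estimate) for the
200-pair false-positive study; 5 ms relay pairs over 200–300 s for
directionality; and, for the end-to-end developmental check, the full
550 s/59-neuron simulation with TE estimation on a 12-neuron subsample
over 5 s sub-windows (n_u_factor 20, 10 surrogates), with burst positions
taken from the full 59-node windows. The full-resolution analogue — all
3422 ordered pairs per window with 100 surrogates each — is the same code
at larger parameters.

## Known limitations

* Raw TE point estimates on null pairs carry a residual bias of order
  −0.02 nats/spike from history-sample dependence; inference is by
  surrogate comparison, which shares the bias, and reported point
  estimates for model selection subtract the surrogate mean.
* The Gaussian surrogate fit extrapolates far into the tail at Bonferroni
  thresholds; this is the standard trade-off accepted in exchange for
  feasible surrogate counts.
* Burst-position ranks compress when nearly all nodes join every burst
  (late synchronous regimes); correlations against position remain
  meaningful but their magnitudes shrink.
* The history-resample surrogate is conservative under the null with this
  estimator realisation; use it only where a strict null-preserving
  construction conditioned on target context is specifically wanted.
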