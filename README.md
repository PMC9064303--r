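# infoflow

Continuous-time estimation and longitudinal analysis of directed
information flow in developing spiking networks.

## The problem

As neural cultures (and model networks) mature, their spontaneous activity
reorganises from near-independent tonic firing into network-wide
population bursts, and with it a capacity for directed information
transfer emerges. Quantifying that emergence requires estimating, for
every ordered pair of recording nodes, the **transfer entropy (TE) rate**

$$\dot T_{Y \to X} \;=\; \lim_{\tau\to\infty}\frac{1}{\tau}
 \sum_{i=1}^{N_X} \ln\frac{\lambda_{x\mid x_{<t},\,y_{<t}}[x_i]}
                          {\lambda_{x\mid x_{<t}}[x_i]}
 \quad [\mathrm{nats/s}],$$

the sum over target spikes of the log ratio of the target's instantaneous
rate conditioned on (target, source) histories versus its own history
alone. `infoflow` estimates this binlessly on interspike-interval history
embeddings with max-norm k-nearest-neighbour statistics (a shared-radius
digamma scheme that keeps null estimates centred), tests every pair
against source-rotation surrogates with a Gaussian-fit p-value, and
assembles Bonferroni-thresholded directed functional networks per
recording session.

On top of the estimator, the package provides the full longitudinal
analysis used to study development: active information storage (AIS) and
data-driven embedding-length selection; per-node and population burst
detection with mean burst positions; burst-local TE (nats/spike) with
surrogate significance; edge- and node-level lock-in correlations between
sessions; transmitter/receiver role ratios and their correlation with
burst position; mean-TE comparisons and binomial significance-count
summaries. A built-in simulator of 59 Izhikevich neurons developing under
additive STDP from tonic firing to periodic population bursting generates
synthetic recordings so that every stage of the pipeline is testable
without any external data.

For whom: anyone analysing multi-electrode-array spike trains (one event
per line: node id, spike time) or simulated point-process data who wants
directed functional networks and burst-resolved information flow, with
calibrated significance.

## Worked example

Simulate a short developing network, estimate TE with significance on a
few node pairs of the late (bursting) window, and build the functional
network:

```r
library(infoflow)

out  <- simulate_network(sim_config(seed = 1))
wins <- extract_windows(out)      # early / mid / late 50 s windows

# late window: crop to 5 s, jitter, keep 6 nodes
late <- crop_recording(wins$late, 500, 505)
late <- jitter_spike_times(late, seed = 1)
rec  <- recording(late$trains[as.character(1:6)], "demo", day = 3)

params <- estimator_params(n_u_factor = 20, n_surrogates = 20, seed = 1)
res <- estimate_te_network(rec, params = params)
net <- build_functional_network(res, alpha_family = 0.01)
net
summarize_te(net)$mean_te
```

Output:

```
<functional_network> 6 nodes, 27/30 significant edges (density 0.9) at family alpha 0.01 (per-test threshold 0.00033)
[1] 8.414127
```

In the late bursting regime nearly every ordered pair carries a
statistically significant flow, and the mean TE (8.4 nats/s here) is
large because the model neurons fire near 100 Hz — per-spike quantities
are of order 0.1 nats/spike. The same call on the early window yields a
sparse or empty network: development manifests as orders-of-magnitude
growth in the number of significant edges.

Burst-resolved roles, on the same window:

```r
ann <- detect_bursts(late, default_burst_params(late, "model"))
nrow(ann$population_bursts)      # population bursts in 5 s
head(sort(ann$mean_position), 3) # earliest-bursting nodes
```

```
[1] 88
       4       34       38 
23.12791 23.62500 24.00000 
```

`burst_local_te()` then averages each pair's per-spike TE contributions
over in-burst spikes, and `position_role_correlation()` correlates the
resulting per-node inward/outward totals with mean burst position —
late bursters receive, early bursters transmit.

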