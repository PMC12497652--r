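# tinda

Temporal interval network density analysis of discrete brain-state
sequences.

## What problem this solves

Dynamic network studies of M/EEG commonly summarize a recording as a
sequence of `K` mutually exclusive network states (e.g. the most-probable
path of a hidden Markov model at 250 Hz, with visits lasting tens of
milliseconds). First-order summaries — transition matrices, occupancies,
lifetimes — cannot see slow structure that unfolds over many visits and
variable delays. `tinda` asks whether the states activate in a consistent
global **cycle** and, if so, over what timescales and at what rate.

For each reference state *m*, every interval between its reactivations is
split evenly in half, and each other state's fractional occupancy (FO) is
contrasted between the halves:

    A[m, n] = < FO_T1(n) − FO_T2(n) >_m

`A[m, n] > 0` means *n* tends to follow *m*. Arranging the states at
equally spaced phases *q* on the unit circle, the **cycle strength**

    S = −β · Σ_{m ≠ n} A[m, n] · sin(q_m − q_n)

projects every edge onto the tangential direction; β normalizes by the
theoretical maximum so `S ∈ [−1, 1]` (+1 = perfectly clockwise graph, 0 =
stochastic). The state ordering is optimized to maximize S (exhaustive for
K ≤ 8, annealed search above), and significance comes from a label-shuffle
permutation null with re-optimization per permutation. Downstream tools:

* per-edge group t-tests with Bonferroni correction over the K²−K edges
  and signed circle-graph export (JSON/GraphML),
* interval-duration percentile binning to localize the timescales carrying
  the cycle,
* a constrained sequential 4-metastate Poisson decoder yielding cycle
  durations and rates,
* cross-model state matching (linear assignment) and circular
  phase-difference comparison of two cycles,
* a semi-Markov simulator with controllable rotational bias, heavy-tailed
  dwell times and dwell-gated bias, so every stage is verifiable without
  restricted neuroimaging data.

Intended users: anyone with discrete state time courses — HMM paths,
microstate sequences, sleep stages, behavioral syllables — who wants to
test for and quantify cyclical ordering.

## Worked example

```r
library(tinda)

cfg    <- simulation_config(K = 8, n_subjects = 10, T = 10000, rho = 1, seed = 42)
cohort <- simulate_semi_markov(cfg)   # or read_cohort("manifest.yaml")
fit    <- tinda(cohort, n_perm = 500, seed = 1)
print(fit)
#> TINDA fit: 10 subjects, K = 8 states
#> Optimized cycle order: 1 -> 2 -> 3 -> 4 -> 5 -> 6 -> 7 -> 8
#> Cycle strength: group mean over subjects S = 0.1405 (group-mean matrix S = 0.1405)
#> Label-shuffle permutation test: p = 0.001996 (500 permutations)
```

The generator planted a clockwise bias along the order 1..8 (`rho = 1`) and
the fit recovers exactly that ordering; `S = 0.14` is the net clockwise flow
on the optimized circle, and no label-shuffled null out of 500 reached the
observed value (add-one p = 1/501). Timescales and rate:

```r
ts <- per_bin_cycle_analysis(cohort, fit$layout, n_perm = 200, seed = 1)
print(ts)
#> Per-duration-bin cycle analysis (5 bins)
#>   bin 1: mean interval 126 ms, S = 0.1607, p = 0.004975
#>   bin 2: mean interval 244 ms, S = 0.1703, p = 0.004975
#>   ...
#>   bin 5: mean interval 970 ms, S = 0.0696, p = 0.004975

rate <- cohort_cycle_rate(cohort, fit$layout)
head(rate, 3)
#>   subject_id w_samples mean_cycle_duration_ms cycle_rate_hz n_completed_cycles
#> 1      sim01        17               362.9358      2.755308                109
#> 2      sim02        17               345.5652      2.893810                115
#> 3      sim03        17               366.4815      2.728651                108
```

Here every bin carries the cycle (the generator's bias is
duration-independent, so S is significant in all five bins and fades only
where intervals outlast the cycle period), and the decoder reports the
cohort cycling at roughly 2.7–2.9 Hz — about 360 ms per full traversal of
the four cycle quadrants. With `dwell_gate` set, the generator confines the
bias to long dwells and the per-bin S profile becomes monotonically
increasing (see the methods vignette).

A thin command line wraps the same pipeline:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/tinda-cli.R", package = "tinda"))') \
    report --manifest cohort/manifest.yaml --out results --seed 7
```

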