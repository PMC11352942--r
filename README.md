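# eegworkload

Detecting mental workload from multichannel EEG with band-power
indicators, an mRMR-based indicator evaluation statistic, and few-channel
classifiers — for researchers building or auditing EEG workload monitors
(the motivating application is air traffic control), and for anyone who
needs a fully synthetic, ground-truth-known testbed for such pipelines.

## What it computes

Per 2-second epoch and channel, Welch band powers in the five canonical
rhythms (δ, θ, α, β, γ) feed a catalogue of 26 spectral indicators —
13 conventional δ/θ/α/β energies and ratios plus 13 γ-bearing ones. Each
indicator is scored over the channel set *S* (59 cortical channels by
default) by

&nbsp;&nbsp;&nbsp;&nbsp;D = (1/|S|) Σ<sub>xᵢ∈S</sub> I(xᵢ; c),&nbsp;&nbsp;
R = (1/|S|²) Σ<sub>xᵢ,xⱼ∈S</sub> I(xᵢ, xⱼ),&nbsp;&nbsp;
**Φ = D − R**,

where c is the workload level and I(·;·) is plug-in histogram mutual
information (equal-frequency bins, bits). High Φ means channels
individually track workload without merely duplicating each other.
Min–max normalisation f(x) = (x − x_min)/(x_max − x_min) puts scores on
[0, 1]. The same greedy mRMR rule then screens *channels* per subject,
top lists are aggregated into cross-subject frequencies (threshold 0.8),
and the surviving candidates are searched exhaustively as singles, pairs
and triples with a depth-limited decision tree under
leave-one-subject-out (LOSO) cross-validation. A synthetic EEG generator
(1/f background + band-limited oscillations, γ/β power rising with
workload on a centro-parietal cluster, per-subject channel heterogeneity,
fully seeded) supplies ground-truth data for every stage.

## Worked example

```r
library(eegworkload)
library(dplyr)

cfg <- sim_config(n_subjects = 3, duration_per_condition = 60,
                  sampling_rate = 128, seed = 42)
cohort <- simulate_cohort(cfg)

bp <- bind_rows(lapply(cohort, function(s) {
  rec <- prune_channels(s$recording, cfg$utility_channels)
  band_powers(segment_epochs(rec, epoch_length = 2))
}))
ind <- compute_indicators(bp)
ev  <- evaluate_indicators(ind)
head(tidy(ev), 5)
#> # A tibble: 5 × 8
#>   indicator_id name                   uses_gamma     D     R     phi  rank score
#>          <int> <chr>                  <lgl>      <dbl> <dbl>   <dbl> <int> <dbl>
#> 1           25 gamma/(delta+beta+the… TRUE       0.151 0.196 -0.0454     1 1
#> 2           26 gamma/(delta+beta+the… TRUE       0.151 0.196 -0.0454     2 1
#> 3           24 gamma/(theta+beta+alp… TRUE       0.149 0.196 -0.0472     3 0.984
#> 4           21 gamma/(alpha+beta)     TRUE       0.148 0.196 -0.0487     4 0.972
#> 5           22 gamma/(theta+beta)     TRUE       0.146 0.197 -0.0509     5 0.953
```

The γ-bearing ratio indicators top the ranking — exactly the channels/bands
the generator modulates (γ amplitude doubling per workload level on
CP2–CP6 and TP7). Φ is negative only because the redundancy average
includes the self-information diagonal, a constant offset that never
reorders indicators. Screening channels with the top indicator and scoring
the candidate triples:

```r
ind_top <- filter(ind, indicator_id == ev$indicator_id[1])
rankings <- lapply(unique(ind$subject), function(sub) {
  greedy_mrmr_channels(filter(ind_top, subject == sub), k = 10)
})
freq <- aggregate_frequency(rankings, top_k = 10, threshold = 0.8)
head(tidy(freq), 6)
#> # A tibble: 6 × 4
#>   channel n_subjects frequency candidate
#> 1 CP2              3     1     TRUE
#> 2 CP3              3     1     TRUE
#> 3 CP4              3     1     TRUE
#> 4 CP5              3     1     TRUE
#> 5 CP6              3     1     TRUE
#> 6 TP7              3     1     TRUE

combos <- enumerate_combinations(head(freq$channel[freq$candidate], 6), 3)
res <- evaluate_combinations(combos, ind_top,
         scheme = label_scheme("zero_low_med_high"),
         cfg = model_config(grid = data.frame(max_depth = 10, min_leaf = 10,
                                              split = "gini"), seed = 1))
head(tidy(res), 3)
#> # A tibble: 3 × 5
#>   combo        size min_accuracy mean_accuracy n_perfect
#> 1 CP2+CP3+CP4     3         0.88         0.924         0
#> 2 CP2+CP3+CP6     3         0.88         0.924         0
#> 3 CP2+CP3+TP7     3         0.88         0.924         0
```

All six informative channels are recovered at frequency 1.0, and the best
three-channel tree classifies the 4-class workload labels of a held-out
subject at 0.88+ accuracy (chance 0.25). `autoplot()` methods exist for
evaluations, frequency reports, LOSO reports and combination results;
`run_pipeline(pipeline_config(...))` executes the whole chain into a
hashed, reproducible run directory, and `inst/cli/eegworkload.R` wraps it
for the shell.

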