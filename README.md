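# boutwin

Behaviour-specific sliding-window selection for animal-borne inertial
sensor data, using the **median bout length** of each behaviour as the
biologically informed window size.

## The problem

Supervised behaviour recognition from collar-mounted IMUs (50 Hz streams
of tri-axial acceleration, gravity, rotation rate and an attitude
quaternion) conventionally slices the signal into fixed-length sliding
windows, computes summary features per window, and trains a classifier.
The window length is usually one ad-hoc value shared by every behaviour.
But behaviours occur in *bouts* — uninterrupted homogeneous runs with
characteristic durations — and a window suited to a 1.2 s walking bout is
a poor match for a 7 s eating bout. `boutwin` is for ethologists and
movement-ecology practitioners who want to test, and exploit, the
relationship between bout duration and optimal window size on their own
labelled recordings (or on simulated ones).

## The method

For each behaviour *b*, a One-vs-All binary classifier (gradient-boosted
trees) is trained on 160 features per window — 5 statistics
(mean, sd, min, max, median) × 32 channels (13 raw + 3 derived + 16
gradients) — over a grid of window sizes
*w* ∈ {15, 32, 60, 81, 100, 149, 200, 300} samples, with
subject-independent 3-fold cross-validation, SMOTE balancing of the
training folds, and windows labelled by their last sample. Each run is
scored by ROC AUC = P(score⁺ > score⁻) (ties ½). The response is
summarised per behaviour by ordinary least squares:

    AUC(w) = β₀ + β₁·w + β₂·w² + ε

whose local maximum ŵ* = −β₁/(2β₂) (clamped to the grid range) is
compared with the behaviour's median bout length. The package reports
ŵ* − median per behaviour and the mean AUC at the bout-matched grid
window versus the grid window farthest from the bout median.

Because raw collar studies are rarely shareable, the package includes a
synthetic study generator (`simulate_study()`) with behaviour-specific
signal families (static postures, continuous and intermittent gaits,
bursts) and log-normal bout-length distributions parameterised by their
medians.

## Worked example

```r
library(boutwin)

cfg  <- two_gait_demo_config(seed = 1)   # 6 subjects, 3 behaviours
recs <- simulate_study(cfg)
(bs  <- study_bout_stats(recs, sample_rate_hz = 50))
#> # A tibble: 3 × 7
#>   behaviour median_samples mean_samples std_samples n_occurrences median_s
#> 1 fastgait              64         66.5        25.2            44     1.28
#> 2 other                723        787.        332.             49    14.5
#> 3 slowgait             298        305.         82.4            41     5.96
```

The fast gait's bouts have a median of 64 samples (1.28 s), the slow
intermittent gait 298 samples (5.96 s) — close to their configured
medians of 60 and 300. The bout-matched deployment windows follow
directly:

```r
select_window(64)    # 60   (grid value nearest the bout median)
select_window(298)   # 300
farthest_window(64)  # 300  (the "wrong window" reference)
farthest_window(298) # 15
```

The full experiment then quantifies how recognition responds to window
size (this is the expensive step — a few minutes):

```r
et  <- run_experiment(recs, behaviours = c("fastgait", "slowgait"),
                      n_iterations = 3,
                      classifier = classifier_gbt(nrounds = 30), seed = 1)
opt <- optimise_windows(et, bs)
opt[, c("behaviour", "vertex_samples", "bout_median_samples",
        "difference_samples", "selected_window")]
bout_vs_nonbout_report(et, opt)
autoplot(et)    # AUC vs window size with quadratic fits, per behaviour
autoplot(opt)   # fitted optima against bout medians
```

`vertex_samples` is each behaviour's fitted AUC optimum: for the
short-bouted fast gait it falls near the short end of the grid, for the
long-bouted slow gait in the 200–230 sample range — each strictly closer
to its own bout median than to the other's — and
`bout_vs_nonbout_report()` shows the bout-matched window beating the
farthest window for both behaviours. A YAML-driven version of the same
pipeline (simulate → bouts → features → train → optimize → report) is
available as `run_pipeline()`, with a command-line front end in
`inst/scripts/boutwin.R`.

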