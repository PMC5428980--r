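# actiph — windowed persistent homology for activity signals

`actiph` compares long, noisy physiological time series — typically
minute-level accelerometer activity counts from wearable armbands — by
their *topological* fluctuation structure rather than by scalar summary
features. It was built for cohort studies that ask whether two outcome
groups (e.g. participants who maintain a volitional weight loss vs
those who regain) differ in their movement profiles when power,
entropy, mean activity and whole-signal correlation say little.

## The method

For a discrete signal f(1..n), order sample positions by the
tie-broken key (f(i), i) — equivalent to an infinitesimal perturbation
f(i) + εi — and frame the signal with sentinels f(0) = +∞,
f(n+1) = −∞. Local minima are births and local maxima are deaths of
connected components of the sublevel sets {i : f(i) ≤ t}; pairing each
maximum (ascending) with the largest admissible unassigned minimum
below it realizes the elder rule and gives the 0-dimensional
persistence diagram {(f(a_σ(k)), f(b_k))}. Points far from the
diagonal y = x are pronounced excursions; near-diagonal points are
noise.

Signals are cut into non-overlapping rectangular windows
(default 20 samples; a 7000-minute recording gives 350 windows), one
diagram per window. Two signals are compared window by window, giving
a 350-point distance signal whose mean is the pairwise value. Diagram
distances:

* **modified Hausdorff semimetric** (default)
  d_mH(A,B) = max{ mean_a min_b d(a,b), mean_b min_a d(a,b) },
  Euclidean ground metric — robust to outliers, but *not* a metric
  (no triangle inequality);
* **Hausdorff distance** d_H (suprema instead of averages);
* **q-Wasserstein** W_q, optimal matching under the L∞ ground metric
  with retirement to the diagonal at cost (death−birth)/2, solved
  exactly by the Hungarian algorithm (default q = 1).

At the cohort level, participants labelled from weight trajectories
(failure: w2 > 0.85·w1 or w3 > 0.90·w1; success otherwise; see
`assign_outcome_label()`) form FF / FS / SS pair strata; strata are
compared with an unpaired (pooled-variance) t test, and a random-label
control reruns everything under label permutation. Baseline features
(power, normalized histogram entropy, mean, Pearson correlation) are
included for comparison, as is a synthetic actigraphy cohort generator
with a controllable between-subject heterogeneity effect.

## Worked example

```r
library(actiph)

compute_diagram(c(0, 3, 1, 2))
#> Persistence diagram: 2 point(s)
#>  birth death min_index max_index
#>      1     2         3         4
#>      0     3         1         2
```

The excursion down to 1 and back up to 2 is a small feature
(persistence 1); the global sweep from the minimum 0 to the maximum 3
is the dominant one. On a synthetic cohort (10 failures with inflated
between-subject spread + 6 successes, 2000 minutes each):

```r
spec    <- cohort_spec(n_success = 6, n_failure = 10,
                       signal_length = 2000, seed = 42)
records <- generate_cohort(spec)

ds <- distance_signal(windowed_diagrams(records[[1]]$signal, 20),
                      windowed_diagrams(records[[11]]$signal, 20))
ds
#> Distance signal (modified_hausdorff): 100 window(s), mean 802.4421

ca <- cohort_analysis(records, metric = "modified_hausdorff", window_length = 20)
ca$summary
#>   group  n     mean        sd
#> 1    FF 45 905.2563 711.36175
#> 2    FS 60 603.1221 563.37782
#> 3    SS 15 252.2127  74.90897
ca$tests
#>   comparison        t  df           p
#> 1   FF_vs_SS 3.528993  58 0.000823921
#> 2   FF_vs_FS 2.428606 103 0.016889778
#> 3   FS_vs_SS 2.395037  73 0.019185463
```

Failure–failure pairs are farthest apart (mean 905) and
success–success pairs closest (252): the failure group's movement
profiles vary more between subjects, and the windowed persistence
distance picks that up. Under the random-label control the separation
disappears (mean p over 50 permutation trials ≫ observed p):

```r
random_label_control(records, n_trials = 50, seed = 7, pairs = ca$pairs)
#>   comparison    mean_p n_trials
#> 1   FF_vs_SS 0.1548288       50
#> 2   FF_vs_FS 0.2302212       50
#> 3   FS_vs_SS 0.3294648       50
```

Note the t test treats pair values as independent although pairs
sharing a participant are not; its p-values are comparable against the
random-label control, not calibrated tail probabilities (see the
vignette's calibration note).

A thin command-line wrapper is installed under `exec/`:

```sh
actiph simulate --seed 1 --out-prefix sim
actiph cohort --cohort sim_minutes.csv --labels sim_labels.csv \
       --metric dmh --window-length 20 --blind-trials 100 --out-prefix run
```

(`diagram`, `compare` and `baselines` subcommands operate on single
signals and unlabelled cohorts; exit codes are 0 / 2 validation / 3
configuration.)

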