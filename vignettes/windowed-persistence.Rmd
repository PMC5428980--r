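---
title: "Windowed persistent homology for activity signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed persistent homology for activity signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiph)
```

## The problem

Minute-level activity counts from wearable accelerometers form long,
noisy, strongly circadian time series. Conventional scalar features
(power, entropy, mean) and whole-signal correlation often fail to
separate clinically distinct groups — for instance participants who will
maintain a volitional weight loss from those who will regain — because
the differences live in the *pattern of short-term fluctuations*, not in
any single summary number. `actiph` implements a topological approach:
each short window of a signal is summarized by a 0-dimensional
persistence diagram of its sublevel-set filtration, two signals are
compared window by window with a distance between diagrams, and the
per-pair mean distance feeds an ordinary two-sample analysis over a
cohort.

## The persistence construction

Let \(f(1), \dots, f(n)\) be the signal. Ties are broken by index: we
order sample positions by the lexicographic key \((f(i), i)\), which is
exactly equivalent to perturbing \(f(i) \mapsto f(i) + \varepsilon i\)
with infinitesimal \(\varepsilon\), but no numeric epsilon ever touches
the data. Sentinels \(f(0) = +\infty\) and \(f(n+1) = -\infty\) frame
the signal. A position is a *local minimum* when it strictly precedes
both neighbours under this order, a *local maximum* when both neighbours
strictly precede it; with the sentinels in place the two sets always
have the same cardinality \(r\) and alternate along the signal (the
smallest extremum is a minimum, the largest a maximum).

Sort the minima \(a_1, \dots, a_r\) and maxima \(b_1, \dots, b_r\)
ascending by key. Walking the maxima in that order, the \(k\)-th maximum
is paired with the largest-key unassigned minimum lying strictly below
it whose candidate predecessors do not sit strictly between the two
positions. The diagram is the multiset
\(\{(f(a_{\sigma(k)}), f(b_k))\}_{k=1}^r\): births at minima, deaths at
the maxima where the corresponding sublevel-set component merges into an
older one (the elder rule). Large \(death - birth\) means a pronounced
excursion; points near the diagonal \(y = x\) are small fluctuations,
i.e. noise.

Two consequences of the sentinel formalism are worth stating because an
informal description ("if the extremum counts differ, drop the
largest-\(x\) one from the larger set") could be read differently:

* a strictly *increasing* signal has one pair, `(f(1), f(n))` — the left
  sentinel makes position 1 a minimum and the right sentinel makes
  position \(n\) a maximum;
* a strictly *decreasing* signal has an empty diagram — position 1 can
  never be a maximum (left sentinel \(+\infty\)) and position \(n\)
  never a minimum (right sentinel \(-\infty\)).

We implement the formal definition only; under it the counts are always
equal and the prose drop-rule never has anything to drop. Empty and
length-1 signals return an empty diagram rather than an error so that
windowed pipelines never fail on degenerate content.

The pairing is the literal inductive rule, quadratic in \(r\) in the
worst case; since windows hold ~20 samples, \(r \le 10\) and the cost is
irrelevant. `pair_extrema()` is the plain-R reference implementation;
`compute_diagram()` runs the identical algorithm in C++, and the test
suite checks the two against each other and against an independent
union-find sweep (ascending key order over the sentinel-extended path
graph, elder rule by birth key) on thousands of random signals with
ties.

## Windowing

Signals are cut into consecutive, non-overlapping, rectangular windows
of `window_length` samples (default 20; a 7000-minute signal gives 350
windows). No tapering, no overlap, and any trailing partial window is
dropped — with the canonical 7000/20 configuration there is none.
Windowing keeps paired extrema close in time, keeps per-window diagrams
sparse, and makes the comparison of two signals time-resolved. Window
lengths 15–25 behave similarly in practice; the choice is exposed
everywhere as a parameter. No correction is applied at window
boundaries (a boundary cutting a monotone run creates an artificial
extremum pair on either side); diagnosing that effect is out of scope
here.

## Comparing diagrams

For diagrams \(A\) and \(B\):

* **Hausdorff**:
  \(d_H = \max\{\sup_{a \in A}\min_{b \in B} d(a,b),\;
  \sup_{b \in B}\min_{a \in A} d(a,b)\}\) with Euclidean \(d\).
  Sensitive to a single outlying point.
* **Modified Hausdorff**: each directional supremum is replaced by an
  average,
  \(d_{mH} = \max\{\frac{1}{|A|}\sum_{a}\min_{b} d(a,b),\;
  \frac{1}{|B|}\sum_{b}\min_{a} d(a,b)\}\).
  Robust to outliers; symmetric, nonnegative, zero on identical
  diagrams, but **not** a metric — the triangle inequality fails (the
  tests pin a concrete violating triple), so it is a semimetric and no
  code may assume transitivity-style bounds.
* **q-Wasserstein**:
  \(W_q = \left(\min_\gamma \sum \lVert a - \gamma(a)\rVert_\infty^q\right)^{1/q}\)
  over matchings in which any point of either diagram may instead be
  retired to its nearest diagonal point at \(L_\infty\) cost
  \((death-birth)/2\). Implemented exactly via diagonal augmentation and
  the Hungarian algorithm (\(O((|A|+|B|)^3)\), trivial at window scale);
  an exhaustive enumeration over augmented matchings serves as the test
  oracle. Default \(q = 1\).

The ground metrics deliberately differ — Euclidean inside the Hausdorff
variants, \(L_\infty\) inside Wasserstein — following the definitions
the method was published with, rather than unifying them.

**Empty diagrams** (e.g. a strictly decreasing window) need a policy the
definitions do not give. Ours: two empty diagrams are at distance 0;
when exactly one side is empty the Hausdorff variants measure the
nonempty side against the diagonal (average resp. supremum of Euclidean
point-to-diagonal distances \((death-birth)/\sqrt{2}\)); Wasserstein
needs no special case because the diagonal matching already covers it.
The diagonal is the natural "nothing happened" reference, consistent
with reading near-diagonal points as noise.

One notational remark: the published Wasserstein formula sums
\(\lVert a - f(b)\rVert_\infty\) over bijections \(f\); we read it as
\(\lVert a - f(a)\rVert_\infty\), the standard optimal-matching
convention it cites.

## Cohort analysis

Participants are labelled from weight trajectories: *failure* when less
than 15% of starting weight is lost by the end of the intensive phase
(\(w_2 > 0.85\,w_1\)) or when a completed program ends above 90% of
starting weight (\(w_3 > 0.90\,w_1\)); *success* when both criteria are
met; *indeterminate* when the 15% loss is achieved but no final weight
exists yet. Indeterminate participants are excluded from pairing — the
analyzed cohort consists of definite labels only — rather than coerced
into either group.

Every unordered pair of participants lands in a stratum (FF/FS/SS); the
pair's value is the mean of its 350-point distance signal (or the
whole-signal Pearson correlation for the baseline). Strata are compared
with Student's pooled-variance two-sample t test — the classical reading
of an "unpaired t test" — with Welch available by configuration. Group
summaries use unweighted means and sample (n−1) SDs.

**Calibration caveat.** Pair values sharing a participant are
dependent: 40 subjects generate 780 pair values but carry only 40
independent pieces of information. The t test deliberately treats pair
values as independent, replicating the published procedure, and is
therefore anti-conservative: under a true null (identical group
distributions) it rejects far more often than 5%. The package's own
null experiment (20+20 identical-distribution subjects, 200 seeds)
shows a rejection rate near 50%, and the corresponding acceptance check
documents this honestly rather than passing by construction. The
random-label control is the appropriate empirical calibration *within*
the same procedure: `random_label_control()` permutes the labels
(preserving class sizes by default; proportion-resampling is available)
and reruns grouping and tests on the unchanged pairwise values,
reporting mean p per comparison over trials. A genuine group effect
should vanish under relabelling; the observed-label p should be
extreme relative to the relabelled ones.

## The synthetic cohort generator

`generate_signal()` builds a minute count series as
\(\mathrm{round}(\max(0,\; A\,m\,C(t) + \mathrm{bout}(t) + \epsilon(t)))\)
where \(C(t) = \max(0, \sin(2\pi (t-\phi)/1440))\) is a half-rectified
circadian profile (1440-minute day, near-zero night troughs), \(A\) is
`circadian_amplitude`, \(m\) a subject-level multiplier, bouts occur in
active minutes with probability `bout_rate` and exponential magnitude
(mean \(\tfrac{8}{7} A m\)), and \(\epsilon\) is Gaussian with SD
`noise_scale`\((0.2 + C(t))\), so nights are quiet but not silent.
Rounding and truncation at zero give nonnegative integer counts.

Defaults are fixed once as the study conditions the package emulates:
21 successes + 79 failures, 7000 minutes, `circadian_amplitude = 700`,
`bout_rate = 0.15`, `noise_scale = 50` — chosen so that overall mean
counts land near \(\sim\)290 counts/min, a realistic adult
actigraphy level; phase jitter SD is 45 minutes. The group-structure
control is `heterogeneity_delta`: the subject multiplier is log-normal
with \(\sigma =\) `subject_sdlog` (0.1) for successes and
`subject_sdlog + heterogeneity_delta` for failures, with
\(\mu = -\sigma^2/2\) so that \(E[m] = 1\) in both groups — the failure
group gets a wider *spread* of movement profiles, not a higher mean
level, mirroring the observation that failure-group behaviour varies
more between subjects. At `heterogeneity_delta = 0` the groups are
drawn from one distribution and are exchangeable by construction. A
single root seed drives subject parameters and per-subject signal
seeds.

What the generator does **not** emulate: sleep/wake misalignment
between subjects beyond phase jitter, weekday/weekend structure,
device non-wear gaps, autocorrelated multi-minute bouts, or any
physiologically validated count distribution. Passing tests on this
generator therefore demonstrate that the pipeline recovers
between-subject heterogeneity injected at the subject-parameter level;
they do not certify performance on real armband data.

`generate_weight_trajectories()` draws weight triples that round-trip
through the labelling rule exactly (successes lose 15–25% and finish at
80–90%; failures either miss the 15% target or regain past 90%), which
exercises the labelling and IO paths end to end.

## Numerical and scale choices

* Distances, diagrams and the Hungarian assignment run in C++; all
  numeric comparisons of tied samples use exact lexicographic keys, so
  results are deterministic and reproducible bit for bit.
* Test problem sizes: oracle equivalence uses 10^4 random signals of
  length ≤ 30 (integer-valued and real-valued, tie-heavy); Wasserstein
  brute-force cross-checks use 10^3 diagram pairs with ≤ 4 points at
  \(q \in \{1, 2\}\); the cohort-recovery experiment uses 20+20
  subjects, 2000-minute signals and 100 (effect) + 200 (null) seeds.
  These sizes make the full suite run in a few minutes while leaving
  the statistical conclusions stable across seeds.
* The entropy baseline uses a 16-bin equal-width histogram normalized
  by \(\log(16)\); "power" is the mean squared sample value. Both
  conventions are isolated behind single functions because published
  usage of these feature names varies; neither is asserted against any
  external value.
* Degenerate inputs: empty signals yield empty diagrams; a constant
  window yields the single on-diagonal point \((c, c)\); constant
  signals make correlation undefined (an error, not NA); two constant
  equal samples give t = 0, p = 1 by convention.

## Known limitations

* The pooled t test on dependent pair values is anti-conservative (see
  above); its p-values are comparable *between* metrics and *against
  the random-label control*, not interpretable as calibrated tail
  probabilities.
* Window boundaries fabricate extrema on monotone runs; short windows
  bound the error but do not remove it.
* The modified Hausdorff comparison is a semimetric; algorithms
  requiring a true metric (e.g. metric indexing) must use the
  Wasserstein option.
* The generator's realism limits, listed above.
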