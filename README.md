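# huntdiv

Event-sequence analysis of prey division in group-hunting predators.

Some marine predators — billfish being the canonical case — hunt schools
of small fish in open groups: the group surrounds the school, but
individuals attack one at a time, each making one or more high-speed
passes ("dashes") before a competitor displaces them. With individuals
identified on video, a hunt becomes an ordered log of dashes
(`time, individual, capture`), and questions about how the shared prey
resource is divided become questions about that event sequence. This
package provides the full toolkit for such logs, for behavioural
ecologists working with attack-scored video of group hunts:

* **Dash sequences** — maximal runs of consecutive dashes by one
  individual, the unit of "turn" (`dash_sequences()`,
  `hunt_summary()`, truncation to a scoring-quality subsample).
* **Arrival subgroups** — predators join mid-hunt; waves of arrivals
  are segmented from the normalized appearance-gap statistic
  `r_i = d_i / i` (dash sequences between the first attacks of the i-th
  and (i+1)-th individuals, scaled by the `i` already present). The
  (i+1)-th appearer founds a new subgroup when `r_i >= h` and
  `r_{i+1} <= min(1, r_i)` (`segment_groups()`,
  `group_count_profile()`).
* **Equal-access null model** — under the null that every predator
  present has the same chance of taking the next dash, per-individual
  expectations within an arrival epoch are (epoch dashes)/(number
  present), with Monte-Carlo 2.5/97.5 percentile bands
  (`newly_arrived_access()`, `simulate_access_null()`).
* **Bout-length statistics** — geometric fit of sequence lengths
  (`p_hat = 1/mean`), Cochran–Armitage trend in the termination
  probability across strata of the hunt, and a stratified permutation
  test for inter-individual differences in mean bout length
  (`fit_geometric()`, `termination_trend_test()`,
  `sequence_length_test()`).
* **Attack-order tests** — ABA turn-interruption counts (A returns
  immediately after a single interruption by B) and return-gap
  histograms against a within-epoch permutation null (`aba_test()`,
  `gap_null_bands()`).
* **Prey division** — capture-share (Lorenz-style) curves, uniformity
  and Spearman tests within subgroups, a Monte-Carlo exact test on
  capture efficiencies, capture-rate time trend (`share_curve()`,
  `capture_efficiency_test()`, `capture_rate_series()`).
* **Morphometrics** — calibrated still-frame lengths and the billfish
  length-weight allometry `w = 1.33263e-6 * EFL^3.41344`
  (`calibrate_length()`, `efl_to_weight()`).
* **Synthetic hunts** — a generator with staggered arrivals, motivation
  weights, geometric bouts and known ground truth, so every stage is
  testable without field data (`generate_hunt()`, `null_hunt()`).

## Worked example

```r
library(huntdiv)
s   <- generate_hunt(hunt_config(seed = 2018))  # study-scale synthetic hunt
rep <- run_full_analysis(s$hunt, seed = 2018, fast = TRUE)
print(rep)
```

```
== Hunt summary ==
34 individuals, 678 dashes, 305 dash sequences, 100 captures
mean sequence length 2.2 +/- 0.1 (max 9)

== Arrival subgroups ==
    h n_groups
1 1.0        4
2 1.5        4
3 2.0        3
4 3.0        3

== Newly arrived subgroup access (finest segmentation) ==
  group n_members epoch_dashes observed_mean expected_mean    lo    hi outside
1     1         9          157         17.44         17.44 17.44 17.44   FALSE
2     2        11          142          9.09          7.10  6.00  8.18    TRUE
3     3         3          173          9.33          7.52  4.67 10.67   FALSE
4     4        11          206          7.73          6.06  4.91  7.27    TRUE

== Dash-sequence lengths ==
Geometric fit: p_hat = 0.4499 (n = 305, logLik = -466.54)
termination trend: chi-sq = 25.07, df = 1, p = 5.52e-07
Permutation test: observed = 0.2738, null mean = 0.3309
p = 0.7525 (100 replicates, seed 2018)

== ABA patterns ==
  h1: observed = 7, null mean = 13.0, p = 0.97
  h2: observed = 7, null mean = 13.9, p = 0.99

== Prey division ==
Capture-share curve over 34 individuals, 100 captures
top 50% most frequent attackers hold 76.0% of captures
capture-efficiency test: p = 0.149
Captures per bin: mean 2.13 +/- 0.21 (range 0-7)
linear trend: F(1,45) = 4.02, p = 0.0511
```

Reading the output: the hunt was generated with four planted arrival
waves, and the threshold profile indeed yields 4 subgroups for
`h <= 1.5`. Newly arrived subgroups 2 and 4 attacked above the 97.5th
percentile of the equal-access null during their own epochs (the
generator gives not-yet-attacked individuals a motivation boost), while
subgroup 1's exact match is a statistical necessity — its members were
alone at the school. Bout lengths fit a geometric distribution with
`p_hat ≈ 0.45` and the planted rise of the termination probability over
the hunt is picked up by the trend test (χ² = 25.1). The permutation
test finds no inter-individual differences in mean bout length and the
ABA count is not elevated — correctly, since the generator plants
neither. Half the individuals (the most frequent attackers) took 76% of
the captures, and the capture rate shows no strong linear trend.

With a real event log, replace the generator with
`read_hunt("my_hunt.csv")` (columns `time_s,individual,capture`) and
drop `fast = TRUE` to get study-scale replicate counts (10^6 for access
bands, 10^4 for permutation tests).

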