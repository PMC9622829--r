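---
title: "Event-sequence analysis of prey division in group hunts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-sequence analysis of prey division in group hunts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huntdiv)
```

## The observational unit and the data model

`huntdiv` analyses hunts in which a group of individually identified
predators takes turns attacking a shared school of small prey. The raw
observation is the *dash*: one high-speed pass through the prey school,
scored with a time stamp (seconds from the start of the recording), the
attacker's identity, and whether the dash captured a prey item. A *dash
sequence* is a maximal run of consecutive dashes by the same individual;
it ends when a different individual initiates an attack. The sequence is
defined purely by interruption — there is no elapsed-time rule — because
in this hunting style a predator keeps re-approaching the school until a
competitor displaces it. An optional `max_gap_s` splitter exists for
users whose scoring protocol does impose a time rule, but it is off by
default.

Times may coincide (video frames are discrete); ties keep their input
order under a stable sort. Sequence indices are 0-based and inclusive at
both ends, one convention used everywhere.

## Arrival subgroups from the appearance order

Marine hunting groups are open: predators join while the hunt is under
way. Joiners are detected from the order of first attacks. For the pair
of the i-th and (i+1)-th individuals to appear, `d_i` counts the dash
sequences by already-present individuals strictly between their two
first-appearance sequences. Under equal access a newcomer facing `i`
incumbents waits on average `i` sequences for its first turn, so the
normalized gap is `r_i = d_i / i`. The (i+1)-th appearer founds a new
subgroup when `r_i >= h` and `r_{i+1} <= min(1, r_i)` — a large
normalized gap followed by a small one is the signature of a wave of
arrivals.

Two boundary choices deserve note. First, `d_i` excludes both
first-appearance sequences themselves ("between" is read strictly); the
rule is self-consistent under this choice and it is the one the
segmentation tests pin down. Second, the final appearer can never found
a subgroup: it has no following gap statistic, and a singleton subgroup
would contradict the minimum subgroup size of two that the founding rule
implies. A final *pair* arriving together can still found a subgroup,
because the founding decision for the second-to-last appearer uses only
gap statistics that exist.

The segmentation is a heuristic and the threshold `h` is not estimated:
`group_count_profile()` reports the group count across a grid of
thresholds, and downstream analyses are run per plausible segmentation.
Group counts are non-increasing in `h` (only the first clause depends on
`h`).

## The equal-access null model

The central null hypothesis is that every predator present at the school
has the same chance of performing the next dash. Individuals are deemed
present from the first attack of their arrival subgroup until the end of
the hunt (departures are not modelled). Each observed dash is one
opportunity; within an epoch (the span between consecutive subgroup
arrivals) the per-individual expectation is the epoch's dash count
divided by the number present, so expectations sum exactly to the
observed number of dashes. Percentile bands come from Monte-Carlo
simulation: within an epoch the null counts are a symmetric multinomial,
drawn with `rmultinom`, with 2.5th/97.5th nearest-rank percentiles per
individual and for the mean of each newly arrived subgroup during its
own epoch. The first subgroup's observed and expected group means agree
by construction — its members are the only ones present.

The study-scale default is $10^6$ replicates; the simulation is
vectorised per epoch, and every result records its seed and replicate
count.

Note what this null is *not*: it is a statement about dashes, not about
dash sequences. Because real dashes arrive in geometric bouts, observed
per-individual dash counts are overdispersed relative to the per-dash
multinomial even when all individuals are identical. The calibration
study therefore generates its null hunts with bout length fixed at one
dash and every attacker drawn independently — the data-generating
process the null actually states — and verifies that the 95% band
covers the group means about 95% of the time. Band coverage on
bout-structured data is expected to be somewhat lower; users comparing
individuals (rather than subgroup means, where epoch totals are fixed)
should bear this in mind.

## Dash-sequence lengths

Bout lengths are modelled as geometric on {1, 2, ...} with termination
probability `p`; the maximum-likelihood estimate is `1 / mean(length)`.
A rising `p` over the hunt (shorter bouts later, e.g. as the prey school
shrinks) is detected with the chi-squared test for trend in proportions
(Cochran–Armitage, scores 1..K, df = 1) on terminating dashes over total
dashes per stratum.

Strata split the *ordered dash-sequence list* into K consecutive blocks
of near-equal sequence counts (sizes differ by at most one, larger
blocks first; 297 sequences split 75/74/74/74 at K = 4). An alternative
partition by near-equal *dash* counts is available via
`unit = "dashes"`; the sequence-count partition is the default because
every sequence then lies wholly in one stratum. K defaults to 4 and is a
configuration choice (3 is natural for shorter recordings).

Inter-individual differences in mean bout length are tested by a
stratified permutation test: the statistic is the sample variance
(n − 1 denominator) of per-individual mean lengths among individuals
with at least `min_sequences = 5` sequences (fewer sequences make the
mean too noisy); the null permutes the length values among sequence
slots *within strata*, keeping every individual's number of sequences
fixed, so that a shared time trend cannot masquerade as individual
differences. p-values use the add-one convention (b + 1)/(m + 1), which
makes the test exact at nominal levels that are multiples of
1/(m + 1). The choice of the n − 1 denominator is a convention; the
permutation p-value is invariant to it.

## Attack order: ABA patterns and return gaps

The identity order (one label per dash sequence) is scanned for ABA
triples — an individual returning immediately after a single
interruption by any other individual — counting all overlapping
triples. The broader view is the return-gap histogram: for consecutive
sequence pairs of the same individual, the number of intervening
sequences, with gaps of 40 or more pooled in a terminal bin.

The null shuffles identity labels uniformly within each arrival epoch.
This preserves every individual's number of sequences per epoch and
never places an individual before its subgroup's arrival, and it makes
the null distribution depend on the segmentation, which is why the test
is reported per segmentation. Permuted orders may contain adjacent equal
labels — in real data those would have merged into one sequence. They
are deliberately retained: re-merging would change the slot count and
break the conservation of per-epoch counts the test relies on. For the
same reason the gap histogram carries a bin for gap 0, empty in any
observed order, which collects these artefacts in null replicates so
that total return counts are conserved replicate by replicate.

## Prey division

Per-individual tallies (sequences, dashes, captures, capture
efficiency) feed four summaries:

* a cumulative capture-share curve over individuals sorted by descending
  sequence count (ties by descending captures, then identity, for
  determinism), with the headline `top_share` taken over the
  `ceiling(N/2)` most frequent attackers;
* a Pearson chi-squared test of uniform sequence counts within each
  subgroup (df = N − 1, flagged when expected counts fall below 5);
* a Spearman rank correlation between sequence counts and captures
  (tie-corrected, asymptotic two-sided p);
* a Monte-Carlo exact test on the 2 × N table of captures and
  non-capture dashes: tables with the observed margins are sampled with
  Patefield's algorithm (`r2dtable`) and the p-value is the
  add-one-corrected proportion with table probability no larger than
  observed (a numerical tolerance of 1e−7 on the log-probability guards
  ties against floating-point error).

The capture-rate series bins the hunt into 60-s bins and regresses
per-bin capture counts on bin index by ordinary least squares. The final
partial bin enters the regression with its raw count (its coverage is
reported so a per-full-minute rate can be displayed); a perfectly flat
series is reported as slope 0, F 0, p 1 rather than an undefined ratio.

## Morphometrics

Still-frame pixel lengths are calibrated by a reference object of known
length in the same image, and the mean eye-fork length per individual is
converted to weight once through the published allometry
$w = 1.33263\times10^{-6}\,\mathrm{EFL}^{3.41344}$ (EFL in cm, weight
in kg). Converting the mean length — rather than averaging per-frame
weights — makes the reported weight round-trip the reported length.
Full precision is kept internally; rounding to one decimal happens only
at report time. The reference object's true length is a required input
with no default.

## The synthetic generator

`generate_hunt()` emulates the statistical structure the analyses
assume, with known ground truth: subgroups of configurable size arrive
at fixed times; at each turn the attacker is drawn among those present
with probability proportional to its motivation weight, excluding the
previous attacker (so emitted dash sequences are maximal whenever two or
more individuals are present — a deliberate deviation from naive
weighted sampling, documented here); bout lengths are geometric with a
termination probability that may step across equal time blocks; dashes
capture independently; inter-dash intervals are exponential.

Individuals that have not yet attacked carry a weight multiplier
(`arrival_boost`, default 8). This emulates the elevated motivation of
newly arrived, presumably hungrier predators and produces the tight
clustering of a subgroup's first attacks that real recordings show;
without it, first attacks of simultaneous arrivals straggle across
roughly `i` sequences each and wave boundaries blur. The default
scenario mirrors the scale of a long recorded hunt: 34 individuals in
four subgroups (9/11/3/11) over 2789 s, a mean inter-dash interval of
3.9 s (about 700 dashes in roughly 300 sequences), termination
probability stepping 0.32/0.39/0.46/0.53 across quarters (mean bout
length near 2.4 dashes), and a per-dash capture probability of 0.155.
`null_hunt()` switches every source of heterogeneity off for
calibration work.

What the generator does **not** emulate: departures before the end of
the hunt, spatial structure and prey-school behaviour, observation error
in identity scoring, and any dependence of capture probability on bout
position. Passing calibration and recovery tests on synthetic hunts
therefore validates the statistical machinery under the stated
assumptions, not those assumptions themselves.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed and records it with its
replicate count, so reports reproduce byte-for-byte. Study-scale
defaults are $10^6$ replicates for access bands and $10^4$ for the
permutation and Monte-Carlo tests; `fast = TRUE` in
`run_full_analysis()` divides both by 100. The package's own validation
suite runs its calibration studies at reduced but adequate sizes chosen
for tight Monte-Carlo error at desk scale: 200 null hunts for access
band coverage (bands from 2000 replicates), 600 null hunts for the
size of the variance permutation test (199 permutations each, making
the add-one p-value exact at the 5% level), 200 null hunts for ABA
p-value uniformity (499 permutations each, each hunt contributing one
p-value so the discreteness of any single hunt's null distribution
averages out), and 100/50 hunts for the subgroup-recovery and
motivation-detection power checks.

## Known limitations

* Presence is inferred, not observed: an individual is "present" from
  its subgroup's first attack and until the hunt ends. Early departures
  bias expected counts upward for the leavers and downward for others.
* The subgroup segmentation is a heuristic with a free threshold; the
  package deliberately reports all plausible segmentations instead of
  selecting one.
* The equal-access band is calibrated for subgroup means; per-individual
  bands inherit overdispersion from bout structure (see above).
* Permutation nulls condition on the observed per-epoch identity
  multisets; they test ordering, not attack propensity.
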