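---
title: "Classifying migratory strategies from GPS telemetry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying migratory strategies from GPS telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrclass)
```

## The problem

Large herbivores such as mule deer are usually described as either
*residents* or *migrants* that make one seasonal round trip between a summer
and a winter range. GPS collar data show a much richer repertoire: animals
that visit several distinct winter ranges in one trip, animals that commute
repeatedly to the same range, animals that leave and never come back, and
animals that drift gradually across the landscape without any discrete
shift. `migrclass` implements an automated, reproducible pipeline that takes
raw collar fixes and assigns each animal-year one of seven migratory
strategies, together with timing, duration and distance metrics and
cohort-level summaries of year-to-year strategy switching.

## The statistic: daily net squared displacement

All classification happens on the **net squared displacement** (NSD): the
squared great-circle distance (km²) between the animal's location on each
day and its location at the start of the *migratory year* (July 1, chosen so
that parturition has finished before the year begins). Fixes are averaged to
one location per UTC calendar day, so variable collar duty cycles and brief
exploratory movements do not distort the series. A typical migrant's NSD is
hat-shaped: near zero on the summer range, a rapid rise in autumn, a winter
plateau at the squared separation of the two ranges, and a spring return to
zero. Residency is a flat line; every other strategy leaves its own
signature.

An animal-year enters the analysis only if it is *complete*: July 1 must
have a location, at least 95% of core days must have one, and no gap may
exceed 7 consecutive days. (The source protocol requires only "monitored the
entire 12 months"; the quantitative rule is this package's construction —
tolerant of sporadic fix failure, strict enough that run-length tests remain
meaningful.) Missing days stay missing: nothing is interpolated, and every
run-length rule below counts observed days only.

## Step 1 — changepoint segmentation

The NSD series (including a 14-day buffer on each side of the year, so that
movements spanning the year boundary are modelled rather than truncated) is
segmented into constant-mean pieces. For every breakpoint count
$m = 0, 1, \dots, m_{\max}$ the package finds the *exact* minimum-RSS
placement of $m$ breakpoints subject to a minimum segment length of
$h = 14$ observed days, by dynamic programming over prefix sums (all
feasible placements are considered; ties resolve to the lexicographically
earliest breakpoint vector). The number of breakpoints is then chosen by
minimising

$$\mathrm{BIC}(m) = n \log\!\big(\max(\mathrm{RSS}_m, \varepsilon)/n\big) + (2m + 2)\log n,$$

a Gaussian changepoint model with $m$ breakpoint positions, $m+1$ means and
one variance ($\varepsilon = n \cdot 10^{-12}$ guards exactly constant
series; ties go to the smaller $m$). The 14-day minimum encodes the
biological definition of a range: a stay shorter than two weeks is a sally
or stopover, not a range. After selection, segments are clipped to the core
year; a segment lying wholly inside a buffer is dropped.

The published analysis used the `strucchange` implementation of the same
dynamic program; here the DP is implemented directly and verified against
exhaustive enumeration in the test suite, which doubles as an independence
check on the arithmetic.

## Step 2 — which segments are the same range?

A breakpoint marks a change in mean NSD, which can be a range shift but also
a range expansion, a pause in a drift, or a return to a previously used
range. Segments are therefore compared through the **overlap coefficient**
of their NSD value distributions,

$$\eta(a, b) = \int \min\{\hat f_a(x), \hat f_b(x)\}\, dx,$$

with Gaussian kernel density estimates (Silverman bandwidths, floored at
$\max(0.01\,\hat\sigma_{\text{pooled}}, 10^{-6}\ \mathrm{km}^2)$ so that
near-constant resident segments never degenerate), evaluated on a shared
1024-point grid spanning the pooled range ±3 bandwidths, integrated by the
trapezoid rule. $\eta > 0.05$ means "same range".

The rule is applied in two stages:

1. **Adjacent merging.** Adjacent segments with $\eta > 0.05$ are merged
   (highest overlap first, pooling their values and recomputing until no
   adjacent pair exceeds the threshold), and the breakpoint between them is
   discarded. This is the published rule for deleting spurious breakpoints,
   and pooling has a second, load-bearing effect: when the changepoint model
   dedicates a full segment to a *transit* window — values sweeping from one
   plateau to the other — that segment is absorbed into a neighbouring
   range instead of surviving as a free-floating distribution.
2. **Identity across non-adjacent segments.** $\eta$ is then computed
   between every pair of surviving segments and the same-range relation is
   closed transitively (connected components), so that a migrant's two
   stays on its summer range resolve to a single range — without this,
   round trips are undetectable.

An earlier design computed all-pairs overlap on the raw, unpooled segments
in one shot and closed transitively. That version is unsound in practice:
a single transit segment overlaps several ranges weakly ($\eta \approx
0.05$–$0.15$ against each) and transitive closure then fuses ranges that are
25 km apart. The two-stage rule contains that failure by construction and
is the package's deliberate deviation from the one-shot design.

Ranges are numbered by first appearance, so range 1 is always the **summer
range** (the range occupied on July 1). The boundaries between the final
segments are the **range shifts**; each shift is dated by the first day of
the segment it opens.

## Step 3 — the decision tree

Shifts are scanned in time order. A shift leaving range 1 opens a **trip**;
a shift back to range 1 closes it; every non-summer range entered while away
is recorded. With $T$ = number of completed round trips:

| condition | category |
|---|---|
| $T = 1$, one range visited | dual-range migrant |
| $T = 1$, several ranges visited | multi-range migrant |
| $T \ge 2$, every trip to the same single range | commuter |
| $T \ge 2$, otherwise | poly-migrant |
| $T = 0$, at least one shift | disperser |
| $T = 0$, no shifts, NSD $> 25$ km² for $\ge 14$ consecutive days | gradual mover |
| $T = 0$, no shifts, otherwise | resident |

The seven categories are exhaustive and mutually exclusive; a property test
drives 1000 randomized shift sequences through the tree to confirm it. Two
readings in the tree are this package's documented choices. First, the
gradual-mover threshold "25 km" is read as **25 km²** (displacement > 5 km):
NSD carries squared units, the home-range size cited alongside it is
24.95 km², and the published mean displacements of residents (1.55 km)
versus gradual movers (8.03 km) straddle 5 km, not 25 km. Second, a year
with completed round trips plus a trailing open outbound is classified from
its completed trips and flagged `incomplete_final_trip`; the source defines
no mixed class, and the 14-day buffer exists precisely to absorb year-edge
movements.

## Metrics

Per-trip length is the inbound minus the outbound breakdate; the combined
length is their sum. Distances between ranges use day-weighted geographic
centroids of the daily locations in each range's segments, with great-circle
distances from the summer-range centroid (centroids are robust to
within-range drift, unlike reading $\sqrt{\text{NSD}}$ off the plateau; the
two agree within 10% on tight synthetic ranges and the test suite checks
that). Single-trip years are marked `typical_timing` when the outbound
movement falls in September–December and the inbound in April–June. Cohort
summaries report counts, percentages and mean ± SE (sd$/\sqrt{n}$, $n-1$
denominator) per category; date means are taken on days-since-July-1 to
avoid calendar wrap-around. Year-to-year transitions are counted over
consecutive migratory years within each animal (a gap year breaks the
pairing, and each maximal run of ≥ 2 consecutive years enters the
strategies-per-animal table); the switch percentage is the off-diagonal
share of all transition pairs.

## The synthetic generator, and what a green test establishes

`template_spec()` encodes one archetype per category with a realistic
geometry: ranges 10–35 km apart, stays of weeks to months, 5-day transits,
4 fixes/day, and within-range scatter of 0.5 km (sd), far smaller than the
between-range separations. The dual-range template departs November 9 and
returns April 26 — the published cohort means — giving a 168-day trip over a
25-km separation; the gradual mover drifts 12 km east over the year. Daily
positions are the deterministic centre plus day-level Gaussian wander plus
independent per-fix noise (both at the stated sd); transits interpolate
linearly. Days are independent by default — that keeps every oracle
closed-form — with an optional AR(1) centre process (coefficient 0.6) to
stress the segmenter, and optional random day drops for robustness tests.
Multi-year animals are chained so each year's summer range sits where the
previous year ended.

The generator emulates the *discrete-range* world the classifier assumes.
Real collar data differ in ways the tests deliberately do not certify:
autocorrelated movement within ranges, range expansion and contraction,
fix-quality outliers, censored years, and stopovers at many positions along
a route. A green end-to-end test therefore establishes that the pipeline
recovers the truth *when the model's assumptions hold*, not that the model
is right for any particular population.

## Known limitations

Two acceptance properties of the original specification are **honestly
red**, and both failures are informative about the method rather than this
implementation:

* **Gradual movers at very low noise.** A smooth 12-km drift produces an NSD
  ramp that minimum-BIC segmentation cuts into ~20 pieces. Recovery then
  depends on a chain of adjacent overlaps each measuring ~0.04–0.15, and on
  wide-pool versus narrow-tail comparisons whose overlap is bounded near the
  5% threshold by the spread ratio. At the realistic default noise
  (sd = 0.5 km) the cohort recovery is 34/35; at sd = 0.1 km — intended as
  the *easy* setting — gradual movers fail intermittently, because less
  noise makes a continuous ramp look statistically like discrete steps. The
  expectation of perfect recovery at low noise is backwards for this
  archetype.
* **Stopover immunity is not absolute.** The 14-day minimum segment length
  is meant to prevent a sub-14-day pause from becoming a range, but the
  exact DP can pad a 10-day pause with adjacent travel or plateau days into
  a valid 14-day segment at the stopover's NSD level, and the RSS gain
  dwarfs the BIC penalty. A 10-day stopover midway through a 25-km migration
  is detected as an extra range on roughly half of the seeded replicates,
  turning a dual-range migrant into a multi-range migrant. The reference
  implementation enforces the same constraint the same way; the source
  itself concedes that with a longer minimum duration some multi-range
  migrants "could be classified as typical migrants".

Other limitations: daily averaging in raw degrees is inappropriate within
~1° of the antimeridian; the overlap index is computed on 1-D NSD values, so
two distinct ranges equidistant from the summer range would be fused (a
known property of the published method, not just of this implementation);
and no fix-quality screening (DOP filters, dead-collar censoring) is
performed — feed the pipeline cleaned fixes.

## A worked example

```{r example, eval = FALSE}
library(migrclass)

spec <- template_spec("multi_range_migrant", seed = 42)
sim <- simulate_fixes(spec)
res <- classify_tracks(sim$fixes)
res[, c("category", "n_round_trips", "n_ranges_total",
        "departure_date", "return_date", "trip_length_days")]
#>              category n_round_trips n_ranges_total departure_date return_date trip_length_days
#> 1 multi_range_migrant             1              3     2016-11-02  2017-04-18              167
```

The animal leaves its summer range in early November, passes through two
distinct winter ranges 20 and 35 km away, and returns in mid-April: one
round trip, several ranges — a multi-range migrant.
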