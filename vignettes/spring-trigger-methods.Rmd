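---
title: "Event triggers, structural sensitivity, and empirical dynamic modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event triggers, structural sensitivity, and empirical dynamic modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(springtrigger)
```

## The scientific setting

Nearshore fish spawning at a pier monitoring site produces an egg-abundance
record with a low baseline and one dominant summer peak each year, sampled
irregularly (one vertical tow every 2–5 days). Alongside it, a pier
thermistor provides an essentially continuous sea-surface temperature (SST)
record that is averaged to daily resolution. A natural event-based
hypothesis is that a discrete warming event in late spring — a rapid rise
of a few degrees over days — cues the spawning that culminates in the
summer peak, so that the size of the spring event predicts the size of the
peak.

`springtrigger` implements that analysis end to end, together with the two
things such an analysis needs and usually lacks: a structural-sensitivity
audit that measures how much the headline correlation owes to
non-quantitative modeling choices (season boundaries, window widths,
smoothing), and nonlinear time-series diagnostics (S-map, convergent cross
mapping) suited to short, irregularly sampled ecological records.

## The spring temperature trigger

For a window of length $L$ days whose **last** day lies in the spring
interval (default April 1 – June 18, both traversal endpoints inclusive),
define the window's *rise* as

$$\max_{i < j} \; T_{t_j} - T_{t_i},$$

the largest increase over ordered day pairs among the window's available
daily temperatures. The spring temperature trigger (STT) of a year is the
maximum rise over all admissible window positions. The default window
length is $L = 28$ days (a monthly timescale), configurable everywhere.

Numerical choices:

* The pairwise-maximum rise is the default because a single plotted "rise
  bar" inside a window runs from a local minimum to a later local maximum,
  not necessarily between the window's endpoints. A last-minus-first
  variant (`method = "endpoints"`) is provided.
* Ties between pairs are broken by the earliest start, then the shortest
  span; ties between window positions by the earliest window end. This
  makes results deterministic on data with repeated values.
* Window positions with less than 80% of their days present are skipped
  (`min_coverage`); a year in which every position is skipped is an error
  rather than a silent `NA`, because a trigger from a half-empty window is
  not comparable with one from a full window.
* A monotonically cooling spring yields STT = 0, never a negative value.

The per-year STT is paired with the **peak summer eggs** — the largest
single-tow count in the summer interval (default June 1 – August 31),
ties to the earliest date — and summarized by ordinary least squares and
the Pearson correlation (`fit_trigger_model()`, `predict_peak()`).
Shannon diversity (base $e$) of a peak sample's species counts is provided
for composition summaries (`shannon_diversity()`).

## The synthetic study generator

No machine-readable egg record is distributed with the source study, so
every stage here is exercised on a seeded generator
(`synthetic_params()`, `generate_study()`) that reproduces the *structure*
of such records:

* **SST**: a seasonal sinusoid (mean 17 °C, amplitude 4 °C, maximum in
  mid July — typical of the southern California nearshore) plus AR(1)
  daily residuals (coefficient 0.7, innovation sd 0.3 °C) plus one
  discrete warming event per year.
* **Events** are symmetric triangular excursions: a linear rise of
  `event_duration` days (default 5) followed by an equal fall. A transient
  excursion is the realistic shape for an advective warm event, and it is
  the shape for which time-averaging genuinely destroys the signal; a
  permanent step would survive a monthly mean nearly unchanged and no
  smoothing audit could ever show degradation. The windowed rise of the
  excursion equals its magnitude exactly for any window longer than the
  rise, which keeps truth-recovery tests exact.
* **Event timing** is uniform over day-of-year 150–164 (late May to
  mid June), the late-spring warming onset immediately preceding the
  spawning season. Two consequences are intended: events complete by the
  default spring boundary (June 18), so the pre-registered analysis
  captures them fully; and they sit close to that boundary, so the
  boundary audits have teeth — shifting the spring end earlier cuts
  events off, exactly the structural fragility diagnosed in the source
  study, whose failure year had its egg peak outside the nominal summer.
  A generator with events buried mid-spring would make every audit
  trivially flat and teach nothing.
* **Eggs**: a latent daily curve — baseline 20 eggs/tow plus one Gaussian
  peak per year (sd 12 days, center uniform over day-of-year 171–235) —
  whose height is `coupling_intercept + coupling_slope ×` (that year's
  event magnitude) + noise (defaults 100, 150 eggs/tow per °C, sd 30).
  Event magnitudes are uniform on 1–5 °C, giving peaks of roughly
  250–850 eggs/tow, the observed order of magnitude. Tows sample the
  latent curve at seeded 2–5 day gaps; counts are rounded (a Poisson
  observation model is a flag; rounding keeps noise-free recovery exact).
* **Null variant** (`null_model = TRUE`): peak heights are driven by
  freshly drawn magnitudes with the same marginal distribution,
  independent of the injected events — the correct null for audit
  calibration because every marginal property of both series is
  preserved while the coupling is severed.

One integer seed governs three derived streams (truth, SST noise, tow
dates), so the SST and egg generators are individually deterministic and
mutually consistent, and identical parameters give bit-identical output.

What the generator does **not** emulate: multi-species composition
dynamics, red-tide or optical forcing, observation error in temperature,
multiple events per spring, and secular trends. Tests passing on this
generator therefore certify the *machinery* — estimators, audits,
determinism — not the ecological truth of any particular dataset.

## The structural-sensitivity audits

Each audit recomputes the trigger-to-peak correlation while varying one
structural choice, and returns a tidy table in which undefined cells
(fewer than 3 years, zero variance, empty shifted intervals) are marked
invalid rather than dropped:

* `window_width_scan()` — correlation versus window length $L$.
* `boundary_scan()` — a 2-D surface over integer shifts of the spring end
  date and the summer start date; the (0, 0) cell equals the unshifted
  analysis exactly.
* `anytime_trigger_scan()` — drops both season definitions: the annual
  peak anywhere in the year, and the trigger window's last day anywhere
  from January 28 to the day before that peak.
* `smoothing_scan()` — the analysis after centered moving averages of
  width 1–31 days. Smoothing windows with under 50% of their days present
  yield no value, so sparse stretches are never silently biased.
* `lagged_crosscorr()` — the linear benchmark: winter-day SST against the
  egg collection nearest to $t + d$ (within ±2 days by default) for
  delays 0–180 days.
* `seasonal_aggregate_corr()` — the coarse-scale benchmark: mean
  December–February SST versus mean March–August eggs (winter belongs to
  the preceding December; February 29, when it exists, belongs to
  winter).
* `annual_variable_matrix()` — pairwise correlations among STT, peak
  summer eggs, mean summer eggs, and mean winter SST.

The formal statement of the overfitting hazard is a superset property:
enlarging the searched grid can only raise the maximum correlation found.
On null data the package's acceptance checks quantify it — the maximum
|ρ| over the joint width × boundary grid exceeds the single
pre-registered configuration's |ρ| in every replicate, and its median by
a wide margin. No multiple-testing correction is applied to scan maxima,
deliberately: the audits *exhibit* the selection effect rather than
correct it.

The default boundary grid (±21 days) is a local neighborhood around the
published boundaries; the audit's point is sensitivity to *small*
redefinitions, not a global search.

## Empirical dynamic modeling on irregular samples

Delay embedding requires lagged copies of the observable, which irregular
sampling rarely provides exactly. `build_embedding()` therefore uses lag
tolerances: with nominal lags of 7 and 14 days and a ±1 day tolerance, a
collection at $t$ becomes an embedding row when collections also exist
6–8 and 13–15 days earlier (nearest to the nominal lag wins; ties to the
earlier date), giving a 3-dimensional state
$(x_t, x_{t-7}, x_{t-14})$ co-registered with the daily covariate at $t$.

**S-map** (`smap_forecast()`, `theta_scan()`): each row's own-time value
is predicted from its lagged coordinates by a locally weighted linear
map, with weights $w_i = \exp(-\theta\, d_i / \bar d)$ on the candidate
rows ($d_i$ = Euclidean distance in the lagged coordinates, $\bar d$
their mean). Rows within the exclusion radius of the target date are left
out (default: the target's own date only; a Theiler-style radius is an
argument). Weighting follows the sequential locally weighted global
linear map convention — design rows scaled by $w$ — and rank-deficient
local systems fall back to the SVD minimum-norm solution. At $\theta = 0$
the procedure reduces, by construction, to leave-one-out global linear
regression, which the tests verify to $10^{-8}$; improvement of forecast
skill at $\theta > 0$ beyond a small margin (default 0.02) flags
state-dependent, i.e. nonlinear, dynamics.

**CCM** (`ccm()`, `convergence_summary()`): to ask whether temperature
leaves a causal signature in egg dynamics, the egg embedding is used to
predict temperature. For each target row, candidate neighbors are
restricted to rows within 90 days of the target's *seasonal phase*
(circular day-of-year distance, `proximity_mode = "doy"`); libraries of
10–80 points are drawn 50 times at random from that pool, the $k = 4$
nearest library rows predict the covariate with weights
$u_i = \exp(-d_i/d_1)$, and skill is the Pearson correlation between
predicted and observed covariate, averaged over draws per library size.
Convergence — skill rising with library size by more than a margin
(default 0.1) with a positive trend — is the causal signature; the
proximity constraint prevents shared seasonality from producing it
spuriously.

Two readings of "within 90 calendar days" are possible: absolute date
distance and day-of-year distance. Both are implemented. Day-of-year is
the default because it is the reading under which the constraint does its
stated job (same season, any year) *and* the only one arithmetically
consistent with the conventional library sizes: for a multi-year record
sampled every 2–5 days, absolute-date pools hold only ~25–45 rows and
could never supply an 80-point library, while seasonal-phase pools hold
~200. Lag coordinates are used raw (no standardization), matching the
use of raw counts; z-scoring and uniform neighbor weights are flags.

## Problem sizes and reproducibility

The package's own verification uses 7-year synthetic studies (matching
the study design), 100-replicate Monte-Carlo calibrations for the
recovery and null-fragility properties, 300-point logistic/AR(1) series
for the S-map discrimination, and 400-point coupled logistic pairs for
CCM convergence — sizes at which every check completes in minutes on one
core while leaving the Monte-Carlo margins wide. The CCM inner loop
(library draws, neighbor search) is implemented in C++ (Rcpp), as is
conventional for EDM tooling; it consumes R's RNG stream, so every draw
is reproducible from `set.seed()`. `run_analysis()` re-runs with the same
configuration and seed are byte-identical, which the tests verify by
checksum.

## Known limitations

* With ~7 year-level observations, any correlation — including the
  audited ones — has very wide sampling error; the package reports $n$
  everywhere and refuses $n < 3$.
* The STT is a maximum statistic and is therefore positively biased under
  noise; comparisons should always be made against the null-calibrated
  scans, not against zero.
* `anytime_trigger_scan()` excludes years whose annual peak precedes
  January 29, as no admissible window exists for them.
* The generator's single-event, single-peak structure cannot represent
  multi-modal spawning years; a year with two comparable peaks would
  stress the peak-eggs definition in ways these tests do not cover.
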