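---
title: "Segmenting caching-forager telemetry with the Path Identification Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting caching-forager telemetry with the Path Identification Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piitrack)
```

## The problem and the model

Foragers that cache food — large felids on ungulate kills, canids, bears,
hoarding rodents and corvids — do not move like the grazers most
segmentation methods were built for. Feeding is intermittent: the animal
stays near a concentrated food source for days, leaves to bed or drink some
distance away, and returns. Step length and turn angle alone are weakly
informative about this behavior, because both resting-near-a-cache and
traveling can produce large or small values of either.

`piitrack` therefore scores each fix on four axes and sums them into a
composite movement index. For a fix $t_0$ flanked by valid fixes $t_{-1}$
and $t_{+1}$ with step lengths $d_1, d_2$ and chord $c$:

$$S_{t_0} = \tfrac12\!\left(\frac{d_1}{\Delta t_1} + \frac{d_2}{\Delta t_2}\right),
\qquad
TA_{std} = \frac{|\theta|}{180},
\qquad
M_{str} = \frac{d_1 + d_2}{c},
\qquad
M_{fid} = w\,\bar d_{i,j},$$

where $\bar d_{i,j}$ is the mean distance from the fix to all other valid
fixes within the spatial radius and temporal window, and $w$ is the number
of those neighbors divided by the maximum possible for the window. After
per-animal standardization to $[0,1]$ the index is the partial sum

$$M = (1 - S_{std}) + TA_{std} + M_{str,std} + M_{fid,std} \in [0, 4].$$

$M$ is smoothed through time with a centered moving average whose width
comes from the index's own autocorrelation structure, yielding the Path
Identification Index (PII), and the PII is thresholded into three classes.
The key assumptions are: projected planar coordinates in meters; fixes on a
(nearly) regular nominal schedule; and behaviors of interest expressed at
the high and low extremes of the index. Behaviors that land mid-range can
be reached through multiple distinct component combinations and are lumped
as "search".

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `nominal_interval` | 240 | min | Six fixes/day collar schedule; all gap and window logic is expressed in multiples of it. |
| fidelity `radius` | 100 | m | The conventional clustering distance for documenting kill/cache sites of large carnivores. |
| fidelity `window` | ±8 weeks | min | Long enough that den-site clustering (used up to ~8 weeks before young travel) registers as fidelity, separating it from multi-day kill clusters. |
| `max_possible_neighbors` | 672 | fixes | $2 \times 8\,\text{weeks} / 4\,\text{h}$, the fixed weight denominator (see below). |
| straightness percentile | 0.90 | — | The straightness distribution is extremely right-skewed (chords shrink toward 0 at recursions); the top decile is capped at 1. |
| smoothing `window` | auto (odd, ≥ 3) | fixes | First non-positive ACF lag; 15 in fixed "paper mode" (≈ 2.5 days at 4-h fixes). |
| thresholds | 1.4 / 1.8 | index units | Directed < 1.4 ≤ search ≤ 1.8 < cache. User-settable: groups feeding together (e.g. a female with offspring) shorten cache bouts and justify a lower cache threshold. |
| `d_max` | per animal | m | Availability radius: the largest observed single-interval step, i.e. what was reachable during one movement. |
| `min_pairs` | 20 | pairs | Below this, logistic subsets separate or fit unstably; no coefficient is reported. |

## Numerical and boundary choices

These are the places where the method as stated leaves room, and what this
implementation fixes, in one place so results are reproducible:

- **Chord floor.** $M_{str}$ is unbounded as $c \to 0$ (an exact return).
  When $c <$ 1 m the raw value is the sentinel `Inf` ("capped high"), which
  standardizes to 1 — consistent with capping the top decile — and is
  excluded from the 90th-percentile computation itself.
- **Percentile rule.** Linear-interpolation quantile (R type 7), fixed and
  documented; on the grid $1..100$ the 90th percentile is 90.1.
- **Turning is standardized once.** $|\theta|/180$ already maps to $[0,1]$;
  dividing again by a per-animal maximum would shrink the range and double
  count the rescaling, so the per-animal max applies to speed and fidelity
  only.
- **Fixed fidelity denominator.** The weight denominator is
  $2 \cdot \text{window} / \text{interval}$ (672), *not* truncated at record
  boundaries: truncation would inflate fidelity at the ends of the record.
  Edge fixes are instead slightly biased low, which is the conservative
  direction for cache detection.
- **Coincident-fix pathology.** Perfectly coincident in-window fixes give
  $\bar d = 0$ and hence fidelity 0, indistinguishable from an isolated
  fix. Implemented as the formula states; GPS jitter makes exact
  coincidence vanishingly rare in real data.
- **Gap policy.** Geometry metrics are defined only when both adjacent gaps
  are ≤ 2 nominal intervals; the first and last valid fixes are undefined
  (no $t_{-1}$/$t_{+1}$). Missed fixes contribute no fidelity neighbors and
  are not imputed.
- **Off-grid jitter.** A timestamp within tolerance (15 min) of the grid is
  on-grid; within 2× tolerance it is snapped; beyond that the fix is
  excluded from metric computation and reported.
- **ACF with gaps.** The standard biased (1/n) estimator on the regular
  grid, with undefined entries mean-imputed *for ACF estimation only* (the
  imputed count is disclosed, and the 5% band uses the defined count).
  Inside smoothing windows, undefined values are excluded, never imputed.
- **Smoothing edge policy.** A fix whose (possibly truncated) window holds
  fewer than half the nominal window count of defined values stays
  undefined, rather than being averaged over thin support.
- **Window parity.** The window is forced odd (a centered window needs a
  middle fix); even first-zero lags round up; minimum 3.
- **Class boundaries.** Cache requires PII strictly greater than the high
  threshold; the search interval is closed on both sides; ties go to
  search.
- **Circadian ties.** Times are assigned to the nearest nominal schedule
  hour on the circular 24-h clock; exact midpoints go to the earlier hour.
- **Percent rounding.** Accuracies round half-up to whole percents
  (116/155 → 75%, 60/62 → 97%), matching how such tables are printed.
- **Selection model.** An ordinary (unconditional) binomial logistic on the
  stacked used/available records — the simplest reading of "a binary
  logistic regression on paired use vs. availability"; the pair structure
  is retained in the data model so a conditional variant could be added. Separation is detected via the
  glm warning, a near-zero residual deviance, or an absurd coefficient
  magnitude, and flagged instead of reported.
- **Raster convention.** Row 1 is the northernmost row; cell centers at
  half-cell offsets from the lower-left corner; disc membership by
  cell-center-within-radius; nodata cells excluded; a sub-cell disc falls
  back to the center cell. Only ESRI ASCII grids are read/written — a
  deliberate scope narrowing, since no raster-format package is assumed
  and the format is trivial text.

## What the simulator emulates — and what it does not

`simulate_forager()` is a semi-Markov (explicit dwell-time) state machine,
because dwell structure — days at a cache — *is* the phenomenon. The default
configuration states a world resembling a cougar collar program:

- schedule: 6 fixes/day at 4-h intervals, 180 days, fix success 0.89
  (within the 85–93% range typical of selected study animals);
- a hunt cycle `directed → search → cache → search → …` with mean dwells of
  12, 6, and 18 fixes (2 days travel, 1 day hunting, 3 days on a kill; a
  kill roughly weekly);
- directed travel near 10 m/min (≈ 2.4 km per 4 h) with tight turns
  (wrapped-normal, σ = 10°); search near 3 m/min with wide turns (σ = 60°);
- cache episodes anchored at a point with 50 m jitter, interrupted with
  probability 0.25/fix by 1–2-fix rest excursions 0.5–3 km away that return
  to the anchor — the leave-and-return signature;
- a `den` state (available, not in the default cycle) for denning
  scenarios: a 2-month anchored episode suppressing directed movement.

Speed draws are lognormal and turns wrapped-normal; these are documented
config choices, not claims about any species. All randomness flows from one
seed; outputs carry their config.

Not emulated: terrain- or memory-driven movement (no home range emerges),
prey density, GPS positional error (coordinates are exact), habitat-driven
fix failure (misses are i.i.d. Bernoulli), and multi-animal interaction. A
green end-to-end test therefore establishes that the pipeline recovers
*well-separated* slow-clustered vs. fast-straight regimes through its own
metrics, smoothing and thresholds — not that real animals meet the default
thresholds, which is what field verification is for. Covariate selection is
emulated two ways: endpoint re-weighting by $e^{\beta z}$ in the walk
(`couple_selection()`, for sign-level properties), and direct generation of
used/available pairs with a known logistic contrast
(`simulate_selection_pairs()`, for calibrated parameter recovery — with
equal-variance Gaussian covariates the retrospective sampling makes the
true slope exactly $\beta$).

## Design choices that were genuinely open

- **Availability disc at $t_{-1}$, used value at $t_0$** — availability is
  what was reachable when the movement began. The used value is the single
  30-m cell at $t_0$ (configurable neighborhood radius defaults to 0).
- **Pairs spanning missed fixes are skipped**, as are fixes without labels:
  they could not enter any circadian × behavior subset.
- **FSR accounting** reconstructs the scheduled grid from first to last
  observed fix; success is valid fixes over that span.
- **Window selection default is per-animal** (first non-positive lag); the
  fixed 15-fix window is an explicit override, kept as "paper mode" so
  published-style runs are one flag away.
- **Duplicate-fix reconciliation** (e.g. satellite-relayed vs. downloaded
  records) is out of scope; duplicates are a hard data error.

## Known limitations

- Mid-range PII is behaviorally ambiguous by construction; do not
  over-interpret the search class.
- The index inherits whatever bias missed fixes induce (fidelity has no
  missed-fix correction), and fidelity at record edges is biased low by the
  fixed denominator.
- Unconditional logistic on paired data ignores within-pair correlation;
  standard errors in very autocorrelated subsets are optimistic.
- Thresholds are expert-set, not learned; change-point or hidden-Markov
  approaches are deliberate non-goals here.
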