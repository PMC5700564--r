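# piitrack

Behavioral segmentation of GPS telemetry for **caching foragers** — predators
(cougars, wolves, bears) and hoarders whose movement signature is *site
recursion*: they kill or store food, leave to rest or tend young, and return
to feed over days. Classic step-length/turn-angle analyses read these
movements as noise; `piitrack` segments them into **directed**, **search**,
and **cache/den** classes using the Path Identification Index (PII).

The package is aimed at movement ecologists with collar programs on a fixed
schedule (e.g. 6 fixes/day at 4-h intervals) who want per-fix behavioral
labels, cache-site detection they can score against field visits, and
behavior-stratified resource-selection analyses.

## The method

At each interior fix `t0` (with valid neighbors `t-1`, `t+1`) four metrics
are computed:

- **speed** `S = (d1/Δt1 + d2/Δt2) / 2` (m/min), the mean of the two step
  speeds;
- **turning** `TA = |turn angle| / 180` ∈ [0, 1];
- **straightness** `M_str = (d1 + d2) / c`, the two step lengths over the
  chord — 1 for straight travel, large for out-and-back recursion;
- **site fidelity** `M_fid = w · d̄`, the mean distance to valid fixes
  within 100 m and ±8 weeks, weighted by the fraction `w` those neighbors
  make of the maximum possible in-window fixes (672 at 4-h fixes).

Each is standardized to [0, 1] per animal (by its maximum; straightness by
its 90th percentile, with the top decile capped at 1) and summed with speed
entering as its complement:

```
M = (1 − S_std) + TA_std + Str_std + Fid_std      ∈ [0, 4]
```

Low `M` is fast, straight movement through rarely visited terrain; high `M`
is slow, tortuous movement in a revisited cluster. `M` is smoothed with a
centered moving average whose window is the first lag at which the index
autocorrelation reaches zero (typically 11–15 fixes, ~2–2.5 days; `15` is
the documented fixed "paper mode" window), giving the **PII**. Thresholds
(defaults 1.4 / 1.8) cut the PII into directed (< 1.4), search ([1.4, 1.8]),
and cache (> 1.8) classes. A paired step-selection module compares the
covariate at each used fix with the mean over the availability disc of
radius `d_max` (the animal's largest 4-h step) at the previous fix, fitting
binary logistic coefficients in the nine circadian × behavior subsets to
expose statistical nonstationarity of selection.

A semi-Markov caching-forager simulator (`simulate_forager()`) with
ground-truth states, rest excursions, fix failures, and optional covariate
coupling makes the whole pipeline testable without collar data.

## Worked example

```r
library(piitrack)

sim <- simulate_forager(sim_config(seed = 42, duration_days = 120))
print(validate_trajectory(sim$trajectory))
#> Trajectory validation: animal SIM01
#>   scheduled slots: 720   valid fixes: 636   FSR: 0.883
#>   - 74 gap run(s) totalling 84 missed fixes

run <- run_pii(sim$trajectory, window = "auto")
print(run)
#> PII run: animal SIM01, window 13 fixes, thresholds (1.40, 1.80)
#> directed   search    cache     <NA>
#>      241      107      359       13
#> 70 segments
print(run$scaling)
#> Scaling constants (SIM01): max speed 15.631 m/min, straightness p90 2.234, max fidelity 1.6615
head(run$segments)
#>      label start_seq end_seq n_fixes duration_hours
#> 1 directed         2      16      15             60
#> 2   search        17      19       3             12
#> 3    cache        20      31      12             48
#> ...
```

The window was chosen automatically as the first non-positive ACF lag (13
fixes ≈ 2.2 days here). Scoring the labels against the simulator's
ground-truth states:

```r
merged <- merge(run$labels, sim$truth[, c("seq", "state")], by = "seq")
table(truth = merged$state, pii = merged$behavior)
#>           pii
#> truth      directed search cache
#>   cache           0      6   289
#>   directed      195      7     1
#>   search         46     94    69
```

Cache recall is 0.98 and directed recall 0.96; misclassifications
concentrate in the transitional search class, as expected for a smoothed
index. Evaluation against field-verification tables
(`evaluate_classification()`) reports per-animal and pooled confusion
tables with whole-percent accuracies.

## Command line

```sh
inst/cli/piitrack simulate --seed 5 --days 120 --out-dir demo
inst/cli/piitrack pii --fixes demo/fixes.csv --paper-mode --out-dir demo
inst/cli/piitrack evaluate --labels demo/SIM01_pii.csv --truth verif.csv --out-dir demo
inst/cli/piitrack stepselect --fixes demo/fixes.csv --labels demo/SIM01_pii.csv \
    --raster demo/raster.asc --out-dir demo
```

`--paper-mode` sets the documented defaults at once (100 m fidelity radius,
±8 week window, thresholds 1.4/1.8, fixed 15-fix smoothing window). Logs go
to stderr; data go to files.

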