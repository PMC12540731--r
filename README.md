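# spindlekin

Quantitative analysis of chromosome congression from live-cell
kinetochore and spindle-pole tracks, together with the immunofluorescence
intensity readouts that accompany it, and a synthetic spindle generator
for testing the whole pipeline against known ground truth.

## The scientific problem

During early mitosis most chromosomes reach the metaphase plate quickly,
but a subpopulation lingers near the spindle poles ("polar chromosomes").
Their congression depends on the kinesin CENP-E, and — when CENP-E is
inactive — on how close they sit to a centriolar pole: Aurora A kinase
forms an activity gradient around centrosomes (working radius of a few
µm) that keeps outer-kinetochore substrates phosphorylated and blocks
the stabilization of end-on microtubule attachments. `spindlekin`
implements the measurement pipeline for this biology:

* **geometry** — a per-frame spindle coordinate frame from the two pole
  positions: the equatorial plane is the line through the pole–pole
  midpoint perpendicular to the pole axis; all distances and angles for
  a sister-kinetochore pair derive from it.
* **congression** — classification of each pair as *polar* (closer to a
  pole than to the spindle centre, with both sisters more than 3 µm
  from the plane) or *aligned*; the alignment event (first crossing of
  the pair midpoint within 2 µm of the plane); residence time at the
  pole from bipolarization; congression velocity (net midpoint
  displacement over the last 6 min before the crossing); polar
  chromosome counts per cell and per pole; mitosis duration.
* **intensity** — background-subtracted, CENP-A-normalized kinetochore
  intensities and pole intensities, with a 1-µm pole exclusion zone;
  per-cell centriolar/acentriolar pole ratios, polar/aligned ratios,
  and the intensity-versus-distance gradient regression.
* **stats** — group summaries with 95% CIs for mean and SD, one-way
  ANOVA with two-sided Tukey HSD (Tukey–Kramer for unbalanced groups,
  star convention `*` < 0.05 … `****` < 0.0001), and OLS with a
  two-tailed slope t-test and R².
* **synthetic_spindle** — a generative model with per-pole centriole
  counts: Aurora activity `A(d) = A_pole exp(−d²/2σ²)` (σ = 1.5 µm,
  amplitude 4-fold lower at acentriolar poles), a congression-initiation
  hazard `h(d) = h_max · max(0, 1 − αA(d)/A_thr)` when CENP-E is
  inactive (`h = h_max` when active), constant-velocity congression
  after initiation, and matched intensity samples.
* **io_cli** — CSV schemas for tracks, events and intensities, and a
  command-line entry point (`exec/spindlekin`).

## Worked example

Simulate twenty CENP-E-inhibited cells whose spindles carry one
centriole at one pole and none at the other (a "1:0" spindle), then run
the full congression and intensity pipeline:

```r
library(spindlekin)
library(dplyr)

cfg <- analysis_config()
co  <- simulate_experiment(spindle_preset("cenpe_inhibited_1v0"),
                           n_cells = 20, root_seed = 42)
res <- analyze_cohort(co$cells, cfg)

summarize_group(res$cells$n_polar)
#>       n  mean    sd ci_mean_lo ci_mean_hi ci_sd_lo ci_sd_hi
#>      20   5.2  2.80       3.89       6.51     2.13     4.09
```

On average 5.2 polar chromosomes per spindle, very unevenly split
across the two poles:

```r
res$cells |>
  summarise(
    centriolar  = mean(ifelse(centrioles_pole_1 >= 1,
                              n_polar_pole_1, n_polar_pole_2)),
    acentriolar = mean(ifelse(centrioles_pole_1 == 0,
                              n_polar_pole_1, n_polar_pole_2)))
#>   centriolar acentriolar
#> 1        4.1         1.1
```

Polar chromosomes accumulate at the centriolar pole (≈ 4 per cell)
while the acentriolar pole retains ≈ 1 — congression initiates freely
where the Aurora gradient is weak. The intensity pipeline shows the
same asymmetry and the spatial gradient directly:

```r
samples <- pole_exclusion_filter(co$intensities, cfg)
bind_rows(lapply(split(samples, samples$cell_id), pole_ratio)) |>
  summarise(mean_ratio = mean(ratio))
#>   mean_ratio
#> 1      4.158    # centriolar / acentriolar pole signal, ~4-fold

gradient_regression(samples)
#>    slope intercept         p r_squared se_slope     n
#>   -0.330      2.22 1.03e-244     0.927  0.00448   428
```

The normalized kinetochore phospho-signal falls off with distance from
the nearest pole (negative slope, two-tailed slope test). Kinematics of
the pairs that started polar and aligned during imaging:

```r
res$pairs |>
  filter(initial_classification == "polar", !censored) |>
  summarise(n = n(),
            mean_velocity  = mean(congression_velocity, na.rm = TRUE),
            mean_residence = mean(residence_time))
#>    n mean_velocity mean_residence
#> 1 71         0.884           5.80
```

(The window-averaged velocity is below the instantaneous congression
speed because the 6-min window can include time before initiation.)

The same analyses run from the shell:

```sh
exec/spindlekin simulate --preset cenpe_inhibited_1v0 --n-cells 20 --seed 42 -o sim
exec/spindlekin analyze --tracks sim/tracks.csv --events sim/events.csv \
    --intensities sim/intensities.csv --condition cenpe_inhibited_1v0 -o out
exec/spindlekin report -o out
```

## Vignette

`vignettes/spindlekin-methods.Rmd` documents the generative model, its
parameters and their rationale, the operational definitions used by the
analysis, numerical conventions and known limitations.
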