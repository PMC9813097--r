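# okrplast

Simulation and analysis of homeostatic plasticity of the optokinetic
reflex (OKR) in larval *Xenopus*.

The OKR rotates the eyes to follow large-field visual scene motion.
Thirty minutes of continuous oscillatory motion ("optokinetic training")
changes the response: animals with large initial amplitudes end up
smaller, animals with small ones end up larger. Plotting each animal's
amplitude change Δ = E − I (entrained minus immediate peak-to-peak
response, in degrees) against its immediate amplitude I reveals a linear
rule

    Δ = m (I − x₀)

whose slope *m* measures how strongly plasticity depends on initial
performance and whose x-axis zero-intercept *x₀* (the homeostatic
*setpoint*, = −b₀/m) is the amplitude at which training changes nothing.
`okrplast` implements the full measurement chain behind this analysis:

* **Synthetic cohorts** — triangular stimulus profiles (4 or 8 °/s; 10
  or 20 s cycles), per-animal eye-movement recordings at ~30 fps whose
  per-cycle amplitudes relax geometrically towards a setpoint
  (`stimulus_profile()`, `simulate_animal()`, `simulate_group()`), with
  fast phases, timestamp jitter and tracker noise.
* **Videooculography** — phantom video rendering and moment-based
  ellipse-fit eye tracking (`render_frames()`, `fit_ellipse()`,
  `track_eyes()`).
* **Signal preprocessing** — 200 Hz resampling, 4 Hz zero-phase
  Butterworth filtering, analytic cycle segmentation, conjugate
  averaging, velocity-based artifact exclusion and per-cycle
  peak-to-peak amplitudes (`process_recording()`).
* **Plasticity statistics** — immediate/entrained five-cycle means, the
  pooled Δ-vs-I setpoint regression with confidence band
  (`regress_change()`, broom-style `tidy()`/`glance()`, `autoplot()`),
  variability homogenization metrics, population per-cycle averages,
  and exact Wilcoxon / Mann-Whitney / Kruskal-Wallis + Dunn tests.
* **Morphometry** — serial-section volume estimation (per-slice label
  area × slice thickness, summed) and the dendrite/soma volume ratio
  (`stack_volume()`, `dendrite_soma_ratio()`).

A methods vignette (`vignettes/okr-plasticity-methods.Rmd`) documents
the model, its parameters, numerical choices and known limitations.

## Worked example

Simulate the mature-animal cohort (37 animals across the four stimulus
paradigms, 30-min sessions), push every recording through the pipeline,
and fit the setpoint regression:

```r
library(okrplast)

cohort    <- simulate_group("old", seed = 1)   # nested tibble of traces
summaries <- analyze_cohort(cohort)            # per-animal I, E, delta
fit       <- regress_change(summaries)
fit
#> <okr_setpoint_fit> n = 37 animals
#>   slope              -0.612
#>   R-squared           0.807
#>   setpoint (x0)       7.288 deg
```

One seeded cohort scatters around the generating rule (slope −0.59,
setpoint 6.4°); averaging over 20 seeded replicates with
`recover_group()` recovers the generating parameters to within a few
percent. Training homogenizes the population — the SD of the entrained
amplitudes drops well below the SD of the immediate ones:

```r
variability_metrics(summaries)
#> # A tibble: 5 × 4
#>   paradigm     n sd_immediate_deg sd_entrained_deg
#>   <chr>    <int>            <dbl>            <dbl>
#> 1 1            7             4.57             1.86
#> 2 2           10             4.24             2.98
#> 3 3           10             4.84             2.41
#> 4 4           10             1.11             1.91
#> 5 pooled      37             5.53             2.71
```

and the small-stimulus paradigm shows a significant paired amplitude
*increase* (the hallmark of the bidirectional, homeostatic mechanism):

```r
with(subset(summaries, paradigm == 4),
     wilcoxon_signed_rank(entrained_deg, immediate_deg))
#> # A tibble: 1 × 5
#>   statistic p_value method   exact     n
#>       <dbl>   <dbl> <chr>    <lgl> <int>
#> 1        53 0.00586 wilcoxon TRUE     10
```

`autoplot(fit)` draws the Δ-vs-I scatter with the fitted line, its 95%
confidence band and the setpoint;
`plot_population_average(population_cycle_average(summaries), period_s = 20)`
shows the per-cycle population time course.

A thin command-line wrapper (`inst/cli/okr`) exposes the same stages as
subcommands (`simulate`, `render`, `track`, `preprocess`, `analyze`,
`morpho`, `reproduce`) for shell pipelines; see `?okr_cli`.

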