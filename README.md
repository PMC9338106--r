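# mfresponse

Simulation and kinematic analysis of **manual following responses** in an
interception task.

When people reach to tap a moving target, visual motion appearing near the
planned movement endpoint pulls the hand in the motion's direction. The
paradigm implemented here measures that pull: participants tap a 2-cm target
that moves rightward at 30 cm/s into a 6-cm interception zone, while a square
centered on the zone — a filled *tile* or an open *frame*, with sides of 7,
37 or 67 cm — translates left or right at 20 cm/s for 100 ms shortly after
the target appears. The two square types carry identical edge-motion signals
but opposite surface interpretations, and the square's size sets how far the
moving edges are from the endpoint (3.5 / 18.5 / 33.5 cm).

Since the raw marker recordings of such experiments are typically not
deposited, the package pairs the analysis with a **synthetic 500-Hz
trajectory generator** whose injected response is known exactly, so the whole
pipeline is validated by parameter recovery.

The headline statistic is computed per participant and condition:

* **response curve** R(t) = v̄ₓ(rightward trials) − v̄ₓ(leftward trials),
  on the 2-ms velocity grid over the first 300 ms after the square's motion
  onset (velocities by direct forward differencing, trials aligned to their
  own recorded motion onset);
* **response magnitude** = mean of R(t) for t ∈ [150, 200] ms;
* group summaries as across-participant means ± SEM, plus the per-participant
  tile-vs-frame magnitude pairing.

The package provides, module by module:

* `mfr_geometry()`, `build_schedule()`, `target_position()`,
  `square_position()`, `nearest_edge_distance()`, `generate_scene()` — the
  task paradigm: geometry, randomized interleaved schedules (25 trials per
  condition cell and direction per 300-trial block), ideal stimulus
  kinematics;
* `response_model()`, `noise_model()`, `reach_model()`, `simulate_trial()`,
  `simulate_session()` — the generator: minimum-jerk baseline reaches ending
  ~662 ms after target onset, a raised-cosine following-response velocity
  bump, marker noise, dropped-sample gaps, square-motion timing issues,
  optional marker miscalibration;
* `fit_calibration()`, `apply_calibration()`, `lateral_velocity()`,
  `detect_tap()` — kinematics: exact four-point screen homography, direct
  2-ms differentiation, the 1-mm/2-cm deceleration tap rule with hit
  classification;
* `exclude_trials()`, `response_curve()`, `response_magnitude()`,
  `analyze_session()`, `group_summary()`, `pairing_slope()` — the response
  analysis;
* `run_end_to_end()`, configuration and delimited-text I/O, and plotting
  helpers.

## Worked example

```r
library(mfresponse)

bundle <- run_end_to_end(list(seed = 1))   # 12 participants x 600 trials
bundle$group$magnitudes
#>   kind side_cm mean_cm_s   sem_cm_s n_participants
#>  frame       7  3.088513 0.09095180             12
#>   tile       7  3.189075 0.10262558             12
#>  frame      37  2.642037 0.08505887             12
#>   tile      37  2.833854 0.11388526             12
#>  frame      67  1.466958 0.11965019             12
#>   tile      67  1.621457 0.10512767             12

mean(bundle$hit_rates)                     # fraction of targets hit in the zone
#> [1] 0.7185897

pairing_slope(bundle$group$pairing, seed = 3)$slope
#> [1] 0.9996827
```

The group-mean magnitudes decrease with square size (3.14 > 2.74 > 1.54 cm/s
pooled over kinds) and are statistically indistinguishable between frame and
tile — the injected model's size-graded, kind-blind response, recovered by
the analysis. About 72% of taps hit the target inside the zone, and the
tile-vs-frame pairing slope is consistent with 1.

The numbered drivers under `analysis/` run the same stages as a narrative
workflow and write their tables under `results/`:

```sh
Rscript analysis/01_paradigm.R          # geometry checks, schedule, scene
Rscript analysis/02_simulate.R          # one participant, taps, hit rate
Rscript analysis/03_response_analysis.R # full 12-participant group analysis
Rscript analysis/04_figures.R           # time courses and magnitude figures
```

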