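# whisknovelty

Novelty detection for active whisker (vibrissal) sensing by internal-model
noise cancellation.

An actively whisking animal — or whiskered robot — moves its own sensors,
so the whisker signal `z(t)` mixes two components:

```
z(t) = r(t) + x(t)
```

where `r(t)` is *reafference* (deflection caused by the whisking movement
itself) and `x(t)` is *exafference* (transients from whisker–object
contacts, the events worth detecting). Only `z` is observable, and the
reafferent background easily swamps contact transients.

The package implements the classic adaptive-noise-cancellation answer: an
adaptive filter predicts the reafferent component and a comparator
subtracts the prediction,

```
e(t) = z(t) - yhat(t),       yhat(t) = sum_i w_i(t) p_i(t),
w_i <- w_i + beta * p_i * e        (LMS rule)
```

where the components `p_i` are tap-delay-line samples of the filter input
and `e(t)` is the novelty signal — ideally just the exafference. The filter
input can be wired three ways, and comparing them is the point of the
package:

* **motor** — an efference copy of the whisking command (a *forward
  model* of the plant),
* **sensory** — the sensory signal's own delayed past (a *signal model*;
  an extra decorrelation delay keeps it from cancelling the contacts
  themselves),
* **sensorimotor** — both at once.

This architecture is a standard computational reading of the cerebellar
microcircuit (tap-delay components as parallel-fibre signals, weights as
parallel fibre–Purkinje synapses, the negated novelty signal as the
climbing-fibre teacher); the package implements and evaluates the signal
processing, not the anatomy.

## What is inside

* **signals** — `whisk_ts` time-series carrier; whisking drives
  (`make_sine`, `make_whisk_sawtooth`, `make_bandpass_noise`),
  `lowpass_downsample` pre-processing, `periodogram`/`spectral_peaks`,
  delimited-text I/O (`read_timeseries`/`write_timeseries`).
* **plant** — second-order linear reafferent dynamics (`linear_plant`,
  `default_plant`) with an optional bilinear motor–state cross term
  `k·u[t-1]·r[t-1]` (`bilinear_plant`, `simulate_reafferent`); Bernoulli
  contact schedules rendered through an impulse-response transient
  (`generate_contact_schedule`, `render_exafferent`); ARX least-squares
  identification (`identify_linear_plant`) and contact-response recovery
  (`infer_contact_response`).
* **cerebellum** — the adaptive filter: `adaptive_filter_config`,
  step-wise `assemble_components`/`filter_predict`/`lms_update`, and the
  compiled whole-record `run_novelty_scheme`.
* **evaluate** — contact-referenced SNR (`compute_snr`,
  `snr_improvement`), threshold-crossing detection (`detect_contacts`),
  and the seeded scenario grid (`run_scenario_grid`,
  `aggregate_scenarios`, `plot_scenario_grid`).
* **cli** — `exec/whisknovelty.R`, a thin command line
  (`simulate` / `identify` / `run` / `grid` / `report`) over the same
  functions, driven by a YAML config
  (see `inst/extdata/example-config.yaml`).

The default plant is the zero-order-hold discretization of a unit-gain
second-order system with natural frequency 20 Hz and damping ratio 1.0 at
200 Hz (`a = (-1.0670, 0.2846)`, `b = (0.1313, 0.0863)`): a servo-actuated
whisker column that tracks its drive closely across the 2–4 Hz whisking
band. Every coefficient is overridable. The default contact transient is a
synthetic 15 Hz decaying cosine (200 ms, 50 ms decay) scaled to 3× the
reafferent RMS under a rat-like sawtooth drive; both are stand-ins for
robot-identified responses that are not publicly available.

## Worked example

One periodic-whisking trial with a strongly nonlinear plant (`k = 0.05`),
400 s at 200 Hz:

```r
library(whisknovelty)

plant <- default_plant()
u     <- make_sine(3, sqrt(2), 400, 200)            # unit-RMS 3 Hz drive
sched <- generate_contact_schedule(400, 200, 0.999, seed = 2)
r     <- simulate_reafferent(bilinear_plant(plant, 0.05), u)
x     <- render_exafferent(sched, default_contact_response(plant),
                           length(r$values))
z     <- compose_sensory(r, x)

compute_snr(z, sched)
#> <snr_result> 1.06 dB (signal var 1.417, noise var 1.111; eval from 320 s)

for (m in c("sensory", "motor", "sensorimotor")) {
  run <- run_novelty_scheme(u, z, adaptive_filter_config(m))
  cat(sprintf("%-13s improvement: %5.1f dB\n", m,
              snr_improvement(run$e, z, sched)))
}
#> sensory       improvement:  25.7 dB
#> motor         improvement:   9.9 dB
#> sensorimotor  improvement:  27.1 dB
```

In the raw signal the 78 contacts are barely above the self-generated
background (≈1 dB). Because the plant is nonlinear and the drive periodic,
the forward model (motor input) can only cancel the component linear in
the drive and leaves the harmonics, while the schemes with sensory input
cancel the periodic background wholesale — the signature scenario in which
a pure forward model breaks down.

The full scenario grid (stochastic/periodic whisking × linear/nonlinear
plant, 10 trials of 400 s each, ~10 s of compute):

```r
grid <- run_scenario_grid(duration_s = 400, n_trials = 10, base_seed = 1)
aggregate_scenarios(grid)
#>      whisking    k       scheme mean_improvement_db sd_improvement_db n_trials
#>      periodic 0.00        motor              43.235             1.101       10
#>      periodic 0.00 sensorimotor              42.014             3.050       10
#>      periodic 0.00      sensory              37.669             1.670       10
#>      periodic 0.05        motor              10.090             0.135       10
#>      periodic 0.05 sensorimotor              27.401             0.810       10
#>      periodic 0.05      sensory              25.869             0.907       10
#>    stochastic 0.00        motor              28.772             0.799       10
#>    stochastic 0.00 sensorimotor              28.350             0.825       10
#>    stochastic 0.00      sensory               7.753             0.837       10
#>    stochastic 0.05        motor               4.416             0.760       10
#>    stochastic 0.05 sensorimotor               6.302             4.142       10
#>    stochastic 0.05      sensory               0.339             1.749       10
```

Every scheme improves on the raw signal in every cell; the motor-only
forward model wins under stochastic whisking, the sensory-only signal
model catches up when whisking is predictable, and only the sensorimotor
wiring stays within a standard deviation of the best scheme everywhere.

From a shell, the same experiment is:

```sh
Rscript exec/whisknovelty.R grid \
    --config inst/extdata/example-config.yaml --out out/
```

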