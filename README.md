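# flimsim

Realistic Monte Carlo simulation and power analysis of time-correlated
single-photon-counting (TCSPC) fluorescence lifetime data as measured from
biosensors in biological tissue.

Fluorescence lifetime imaging (FLIM) promises readouts independent of
sensor expression, but tissue measurements also contain autofluorescence,
photomultiplier afterpulse and background — all of which bias and blur the
lifetime estimate as sensor brightness changes.  `flimsim` simulates the
full measurement (sensor decay sampled photon-by-photon, instrument
response function blur with laser-cycle wrap-around, additive noise
sources with realistic counts and fluctuation) and provides the analysis
stack needed to reason quantitatively about such experiments:

* **Histogram simulation** — double-exponential FRET-sensor decay
  $F(t) = F_0 (P_1 e^{-t/\tau_1} + P_2 e^{-t/\tau_2})$ (defaults:
  the FLIM-AKAR PKA sensor, $\tau_1 = 2.14$ ns, $\tau_2 = 0.69$ ns) on a
  256-channel / 12.5 ns cycle, with autofluorescence ($F_{auto} = 4560
  \pm 5\%$), afterpulse ($0.32\%$ of sensor photons) and background
  ($F_{bg} = 3484 \pm 5\%$); GaAsP PMT and hybrid-detector presets.
* **Lifetime metrics** — empirical lifetime
  $\sum F(t)\,t / \sum F(t)$ and fixed-$\tau$ double-exponential fitting
  with IRF convolution, SHG and background terms by Gauss–Newton least
  squares.
* **Power analysis** — minimum detectable difference
  $MDD = z\sqrt{2}\,STD/\sqrt{n}$ ($z = 2.80$ at 80% power, 5%
  significance) as a function of sensor photons and sample size;
  photon-noise vs IRF-noise decomposition; sensor-expression tolerance
  thresholds ($1.96 \cdot SE$) with log-log intersection.
* **Lifetime multiplexing** — two same-color single-exponential sensors
  on a 50 ns cycle, fixed-$\tau$ intensity deconvolution, detection power
  $\beta = 1 - \Phi(1.96 - \Delta I/SE)$ and 5-parameter-logistic power
  curves giving the minimum detectable $\Delta F/F_0$.

## Worked example

How small a change in the PKA sensor's slow-decay fraction $P_1$ can an
experiment with 300,000 sensor photons per measurement detect?

```r
library(flimsim)

cfg <- simulation_config(
  decay = decay_model("double", tau1_ns = 2.14, tau2_ns = 0.69, p1 = 0.5),
  n_sensor_photons = 300000, n_repeats = 100, seed = 42)
g <- run_grid(cfg)
g$summary
#>   p1_sim photons   n n_excluded mean_p1_fit sd_p1_fit mean_lifetime_ns sd_lifetime_ns
#> 1    0.5  300000 100          0      0.4981  0.003434            2.463       0.003438

build_mdd_curves(g, n_list = c(1, 5))
#> (n_pairs = 5 rows)
#>               metric n_pairs photons     std     mdd
#>            fitted_p1       5  300000 0.00343 0.00608
#>   empirical_lifetime       5  300000 0.00344 0.00609
```

Reading: across 100 simulated acquisitions the fitted $P_1$ scatters with
STD 0.0034 and its mean (0.498) sits slightly below the true 0.5 — the
autofluorescence bias.  With five paired measurements per group, changes
of about 0.006 in fitted $P_1$ or 6 ps in empirical lifetime are the
smallest detectable at 80% power — i.e. roughly 300k photons are needed
to resolve a 0.006 change in $P_1$.

A command-line wrapper over the same functions ships in
`inst/cli/flimsim.R` (`simulate`, `grid`, `isolate-noise`, `mdd`,
`multiplex` subcommands); the methods vignette
(`vignettes/flimsim-methods.Rmd`) documents the model, parameter choices
and limitations.

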