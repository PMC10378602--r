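# phasete

Ensemble phase transfer entropy for detecting directed interactions
between trial-based neural signals.

Neuroscientists recording local field potentials from two brain areas over
many repetition trials often need to know not just whether the areas'
band-limited rhythms are coupled, but *which way* the information flows
and *with what lag*. `phasete` implements phase transfer entropy (TE on
the instantaneous phase of a frequency band) in the ensemble setting:
embedded phase samples are pooled across trials, so short nonstationary
trials still yield one well-sampled estimate.

For a source $X$ and target $Y$ with band-limited phases
$\theta^x_t, \theta^y_t$,

$$\mathrm{TE}_\theta(X \to Y) = H(\theta^y_t \mid \theta^{y}_{t-1}) -
H(\theta^y_t \mid \theta^{y}_{t-1}, \theta^{x}_{t-u}),$$

estimated by one of four interchangeable backends — histogram binning
(Scott's circular bin-width rule), Kraskov–Stögbauer–Grassberger
k-nearest-neighbour counting, ordinal (permutation) symbolisation, and a
kernel-matrix Rényi α-order entropy. Directionality is measured by the
differential statistic
$\mathrm{dTE} = \mathrm{TE}(X \to Y) - \mathrm{TE}(Y \to X)$, its
significance by an exact rank test against trial-shuffle surrogates, and
the interaction lag by $\hat\delta = \arg\max_u \mathrm{TE}(u)$ over a
scan grid.

The package also ships:

* a coupled Jansen–Rit-type neural-mass simulator producing beta-band
  signal pairs with known coupling weight, direction and lag, plus
  linear-mixing (volume conduction) and SNR-controlled noise corruption;
* a benchmark harness measuring false positive rate, sensitivity,
  coupling detection threshold (CDT) and lag accuracy per backend over
  coupling/noise/mixing/sample-size/lag sweeps;
* a trial-based LFP pipeline (epoch QC, common average reference,
  time-binned coupling with binomial aggregation) and a synthetic LFP
  generator with planted ground truth;
* a thin CLI (`inst/cli/phasete`) over the same functions.

## Worked example

Simulate 100 coupled pairs (weight 40, lag 20 ms), extract 15–35 Hz
phases, and test the direction:

```r
library(phasete)

sim <- simulate_batch(nmm_config(w_xy = 40, delta_ms = 20, seed = 1), 100)
phx <- extract_phase(sim$x, c(15, 35), order = 15)
phy <- extract_phase(sim$y, c(15, 35), order = 15)

res <- significance_test("bin", phx, phy, u_grid = seq(10, 70, 10),
                         n_surr = 199, alpha_sig = 0.01, seed = 7,
                         unit = "ms")
res
#> dTE[bin] = 0.03100 nats, p = 0.0050 (significant at 0.01), lags 20/60 ms
```

The observed dTE (0.031 nats) is positive — net information flow from X
to Y, matching the simulated direction — and exceeds all 199 surrogate
values, so the exact rank p-value is 1/200 = 0.005. The X→Y lag scan
peaks at 20 ms, the simulated interaction lag; the reverse-direction lag
(60 ms) is meaningless noise, as expected when no Y→X coupling exists.

Against a zero-coupling pair the same pipeline retains the null:

```r
sim0 <- simulate_batch(nmm_config(w_xy = 0, delta_ms = 20, seed = 2), 100)
res0 <- significance_test("bin",
                          extract_phase(sim0$x, c(15, 35), order = 15),
                          extract_phase(sim0$y, c(15, 35), order = 15),
                          u_grid = seq(10, 70, 10), n_surr = 199,
                          alpha_sig = 0.01, seed = 7, unit = "ms")
res0$p_value
#> [1] 0.025
```

See `vignettes/phase-transfer-entropy.Rmd` for the estimators' internals,
the simulator's parameterisation and calibration, the surrogate design,
and the behaviour of each backend worth knowing before use.

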