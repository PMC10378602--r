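---
title: "Ensemble phase transfer entropy: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble phase transfer entropy: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measure

Transfer entropy from a source $X$ to a target $Y$ quantifies how much the
past of $X$ improves the prediction of $Y$ beyond $Y$'s own past,

$$\mathrm{TE}(X \to Y) \;=\; H(Y_t \mid Y^{(d_y)}_{t-1}) \;-\;
  H(Y_t \mid Y^{(d_y)}_{t-1},\, X^{(d_x)}_{t-u}),$$

where $Y^{(d)}_{t-1}$ and $X^{(d)}_{t-u}$ are delay embeddings with
dimension $d$ and delay $\tau$, and $u$ is the interaction lag. With a
length-$T$ series the embedding yields $D = T - \tau(d-1) - u$ usable rows.
`phasete` computes this measure on the *instantaneous phase* of one
frequency band: trials are band-pass filtered with a zero-phase FIR filter
and the phase is the angle of the Hilbert analytic signal, wrapped to
$[-\pi, \pi)$. Working on phases isolates the timing relation of the band's
oscillations from amplitude dynamics, which is the quantity of interest for
rhythmic coupling between brain areas.

Because single trials of neural data are short and nonstationary, all
estimators pool embedded sample points across the repetition trials of a
condition (the *ensemble* approach). Embedding windows never straddle trial
boundaries.

Two facts shape the inference design. First, every practical TE estimator
is biased, so the package always works with the differential measure
$\mathrm{dTE}(X \to Y) = \mathrm{TE}(X \to Y) - \mathrm{TE}(Y \to X)$, each
direction evaluated at its own scanned lag; a positive value means net flow
$X \to Y$. Second, the interaction lag is unknown, so
$\hat\delta = \arg\max_u \mathrm{TE}(X \to Y, u)$ over a scan grid, and the
observed statistic is a maximum over lags -- the surrogate null must
therefore re-run the identical scan.

# The four estimator backends

**Binning (`te_bin`).** Phases are discretised into equal-width circular
bins anchored at $-\pi$; all joint probabilities are relative frequencies
and entropies are plug-in Shannon entropies (natural log, everywhere in the
package). The single bin width follows Scott's rule
$h = 3.5\sigma / N^{1/3}$, where $\sigma = \sqrt{-2\log \bar R}$ is
Fisher's circular standard deviation of the pooled *target* phases; the
circle is covered by $\lceil 2\pi/h \rceil$ bins. One width is reused for
every coordinate of every marginal space of a given direction (the simplest
consistent reading; the alternative of re-deriving $h$ per marginal is a
documented open choice). Embedding dimension is fixed at 1 per channel.

**KSG (`te_ksg`).** Kraskov algorithm 1: the $k$-th nearest-neighbour
distance of each pooled point in the joint space (max-norm) defines a strip
whose strict occupancy counts in the three marginal spaces enter the
digamma average $\psi(k) + \langle \psi(n_{y^-}+1) - \psi(n_{y y^-}+1) -
\psi(n_{y^- x^-}+1)\rangle$. Default $k = 4$. Embedding parameters come
from the Ragwitz criterion: the $(d, \tau)$ minimising the leave-one-out
locally-constant one-step prediction error of the phase series (circular
mean of the $k$ neighbours' successors, wrapped squared error), with every
candidate scored on the same prediction targets and ties broken to the
smallest $d$, then $\tau$. Default grids are $d, \tau \in \{1,\dots,5\}$,
bounded by the 200-sample trials.

**Symbolic (`te_sym`).** Each embedding window is mapped to its ordinal
pattern (ranks within the window, ties broken by order of occurrence) and
TE is computed on the resulting symbol streams by exhaustive counting.
Symbols are invariant under any strictly monotone transform of the phases.
Embedding parameters come from the C--C method: the correlation-integral
statistic $S(d, r, \tau)$ on disjoint subseries, with $\tau$ at the first
local minimum of the averaged $\Delta \bar S(\tau)$ and the dimension
derived from the embedding window minimising
$\bar S_{cor} = \Delta\bar S + |\bar S|$. On strongly periodic phase
series $\Delta\bar S$ can decrease monotonically over the grid; the
selection then falls back to the global minimum, which favours wide symbol
windows -- a behaviour worth knowing about when interpreting symbolic lag
estimates (below).

**Kernel Renyi (`te_kalpha`).** The matrix-based Renyi entropy
$H_\alpha(M) = \tfrac{1}{1-\alpha}\log \mathrm{tr}(M^\alpha)$ of
trace-normalised Gaussian Gram matrices, combined across the four
marginal spaces with the same sign pattern as the Shannon decomposition.
Bandwidths are the median pairwise distance of each space's points; angles
are mapped to $(\cos\theta, \sin\theta)$ before the kernel so Euclidean
distances respect phase periodicity. $\alpha = 3$ by default; integer
orders use a direct matrix-power trace, non-integer orders an
eigendecomposition. The $N \times N$ Gram matrices make this the most
expensive backend by far, hence a hard `guard` (default 6000 points) plus a
`max_points` subsample cap.

All phase distances in the package are wrapped per coordinate,
$\min(|\Delta|, 2\pi - |\Delta|)$: the periodicity of phase is the known
pitfall of naive metrics here.

# Surrogate inference

`significance_test` computes the observed dTE with the lag scan in both
directions, then repeats the identical pipeline on `n_surr` surrogates in
which the *trial pairing* is permuted (never the identity): within-trial
dynamics are preserved, the trial-to-target assignment is destroyed. This
is the standard null for ensemble estimation. The two-sided exact rank
p-value $(1 + \#\{|\mathrm{dTE}_{surr}| \ge |\mathrm{dTE}_{obs}|\})/(1 +
n_{surr})$ includes the observed value, so the test is exactly valid for
exchangeable nulls. A consequence worth stating: when source and target
trials are truly independent, the observed pairing is exchangeable with
the shuffled ones and the test holds its level at *every* sample size.
Inflated false positive rates under this scheme therefore indicate real
cross-channel dependence (for example instantaneous mixing), not sample
size. Aggregation over repeated estimations uses the one-sided binomial
tail (`binomial_aggregate`).

Within the scan drivers, every lag is evaluated on the common valid sample
support (the largest lag's offset), so TE values are comparable along the
scan; standalone `te_*` calls use the exact per-lag row count
$D = T - \tau(d-1) - u$.

# The coupled neural-mass simulator

`simulate_pair`/`simulate_batch` generate ground-truth signal pairs from
two Jansen--Rit-type units (three populations each, second-order synaptic
kinetics, sigmoidal rate function). The classic constants are kept with
the synaptic rate constants and gains scaled by 2.5
($A = 8.125$ mV, $B = 55$ mV, $a = 250\,s^{-1}$, $b = 125\,s^{-1}$,
$C_1 = 135, C_2 = 108, C_3 = C_4 = 33.75$), an exact time rescaling that
moves the autonomous rhythm from the alpha range into the beta band; with
the white-noise pulse-density drive at $p = 320 \pm 100\,s^{-1}$ the
simulated spectrum peaks in the 20--30 Hz range, with the large majority
of the suprathreshold (>2 Hz) power inside 15--35 Hz (asserted by the
simulator's test suite). Integration is stochastic Euler at 1000 Hz with a
discarded 1-s burn-in; output is anti-alias filtered and decimated to
100 Hz, so 2-s trials hold 200 samples and lags of 10--70 ms are 1--7
samples.

Directed interaction enters as
$v_Y(t) = g\,\omega_{X\to Y} Z_X(t - \delta) + n_Y(t)$: the presynaptic
pyramidal pulse density $Z_X$, delayed by $\delta$ and scaled by the
dimensionless weight $\omega \in [0, 70]$, is added to the target's
excitatory drive. The paper-scale weight has no physical units, so the
input gain $g$ is a calibrated constant: it was fixed once, at
$g = 0.32$ mV per unit weight, so that the binning estimator's clean
coupling detection threshold sits near the reference value
($\approx 17.5$) under the reference conditions (100-pair sets, 2-s
trials, $\delta = 20$ ms), and it has not been revisited since.

Corruption follows acquisition physics: symmetric instantaneous mixing
$X' = (1-m)X + mY$, $Y' = (1-m)Y + mX$ emulating volume conduction is
applied first, then white sensor noise at the requested SNR. Note the
order: adding sensor noise *before* mixing would make the two channels
identical at $m = 0.5$ and every directed statistic exactly zero. Also
note what the convex mixing form implies at $m = 0.5$: the two channels
share one common signal and differ only by sensor noise, so the directed
asymmetry of the underlying pair is essentially erased and any
significant dTE there reflects the confound, not the coupling. An
alternative reading of "mixing strength" as a leakage coefficient
($X' = X + mY$) would preserve channel identity at $m = 0.5$; the package
uses the convex form because it is the specified contract, and the
consequences are visible in the benchmark behaviour documented below.

# The benchmark harness and its scales

`run_baseline_suite` measures, per estimator and condition, the false
positive rate at $\omega = 0$ (fraction of sets declared significant), the
sensitivity curve over $\omega$ (significant *and* correctly signed --
a significant wrong-signed dTE is not a true positive), the coupling
detection threshold (first upward crossing of sensitivity 0.8, linear
interpolation, flagged "not reached" past the grid), and the lag accuracy
(exact grid hits). Full scale is 200 sets of 100 pairs drawn from pools of
1000, repeated 20 times with 200 surrogates.

Desk scale, used by the test suite and the acceptance script, divides this
down to 300--400-pair pools, 5--25 sets per condition and 99 surrogates --
the smallest surrogate count whose exact rank p-value can reach the 1%
level (with 50 surrogates the smallest attainable p is $1/51 > 0.01$ and
nothing can ever be declared significant). The neighbour backend runs on a
deterministic subsample of at most 500--800 pooled points and a 4-point
lag grid; the kernel backend on at most 200 points and a 3-point grid (its
Gram-matrix cost grows cubically, which is also why the full-scale
benchmark restricts it to sets of at most 125 trials). These are the
package's own problem-size choices; they keep each benchmark quantity a
Monte-Carlo estimate with known binomial noise rather than a point value.

# Behaviour worth knowing about

Findings from the package's own benchmark runs at desk scale, stated here
because they shape interpretation; each is reproduced by the test suite or
the acceptance script, not asserted from literature:

* The binning estimator detects clean coupling from $\omega \approx 17$
  upward at reference scale and from $\omega \approx 13$--15 with
  300-trial sets; its false positive rate stays at the nominal 1% under the
  exchangeable null at every sample size (see the exchangeability argument
  above).
* The KSG backend is markedly less sensitive on phases at these scales
  (clean detection threshold above 50), and in this implementation it does
  not become more sensitive at larger interaction lags.
* The symbolic backend is the most sensitive clean detector here, but its
  lag estimates are unreliable: ordinal patterns of a near-periodic phase
  stream respond to coupling over a wide, near-periodic range of lags, and
  the scanned maximum tends to land far from the true lag (at desk scale,
  at the upper end of the 10--70 ms grid rather than at the simulated
  20 ms). The wide C--C-selected symbol windows amplify this. Treat
  symbolic lag estimates as uninterpretable; use the binning backend for
  lags.
* Under strong symmetric mixing ($m = 0.5$) the trial-shuffle test
  rejects for a large fraction of zero-coupling sets (binning and symbolic
  alike, symbolic worst), and correctly-signed sensitivity collapses for
  the binning estimator -- both direct consequences of the shared common
  signal described above. Mixing up to $m \approx 0.2$ leaves the
  estimators essentially unaffected.

# The LFP pipeline and the synthetic generator

`epoch_qc` rejects epochs whose 0.5--4 Hz power exceeds 30% of the
0.5--50 Hz total (Welch periodogram: 2-s Hann segments, 50% overlap) or
whose peak amplitude exceeds a threshold (default $6\times$ the ensemble's
median absolute deviation -- the motion-artifact rule must be explicit to
be testable). `common_average_reference` subtracts the across-channel mean
per sample; the adaptive channel-weighting variant used in some recording
pipelines is intentionally simplified to the plain reference, which
preserves the testable contract. `binned_coupling` splits epochs into 14
half-second bins per band ($\theta$ 4--12, $\beta$ 12--30, slow-$\gamma$
30--45, fast-$\gamma$ 55--80 Hz in the recording convention), repeatedly
draws trial subsets, tests each draw's dTE against trial-shuffle
surrogates, and aggregates the flags binomially. Band filters use the
"$3r$" order rule (three times the sampling-rate-to-low-cutoff ratio,
rounded down), applied to full epochs before binning so filter transients
do not sit at bin edges.

`generate_synthetic_lfp` emulates the target recordings structurally:
2000 Hz, ~30 repetition trials, 7-s epochs, a $1/f$ background with
$\theta$/$\beta$/$\gamma$ narrowband components, an imposed directed
phase coupling (band, lag, strength, optional time window) and designated
artifact and delta-dominated trials. What it does *not* emulate: real
electrode noise spectra, cross-channel correlation structure of an
electrode array, behavioural nonstationarity, or any physiological
coupling mechanism -- passing the pipeline's parameter-recovery tests
shows the analysis recovers a known construction, not that it would
detect any particular physiological effect.

# I/O and interface notes

Trial matrices are read and written as delimited text (one trial per row,
a `# phasete fs=... channel_id=...` header line); HDF5 containers are not
supported in this build and raise an informative error. Downstream results
are plain data.frames, written as CSV by the harness. A thin command-line
wrapper over the exported functions ships in `inst/cli/phasete`
(subcommands `simulate`, `estimate`, `benchmark`, `pipeline`).

# Known limitations

* Bivariate only: no conditional/multivariate TE, no amplitude TE.
* Hilbert phases only (no wavelet phase), one band at a time.
* The surrogate scheme is trial-shuffling only; time-shift or
  phase-randomised surrogates are out of scope.
* The lag scan assumes a single dominant interaction lag inside the grid.
* Estimator variance at desk scale is non-trivial; treat single-set dTE
  values as evidence only through their surrogate test, never by
  magnitude.
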