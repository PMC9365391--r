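---
title: "Models and methods behind kymodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kymodiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymodiff)
```

kymodiff analyzes single-molecule experiments in which a fluorescently
labeled DNA-binding protein (for example a chromatin remodeler) diffuses
one-dimensionally along DNA stretched between two optically trapped
beads, imaged by repeated confocal line scans (kymographs), and related
TIRF binding-kinetics and optical-tweezers pulling experiments. This
vignette records the models the package implements, the assumptions
behind them, and the design decisions taken where the procedure was
genuinely open.

## 1. The measurement chain

A kymograph is a photon-count matrix: rows are 100 nm pixels along the
DNA, columns are scan lines separated by the line time (20–50 ms).
Tracking (`track_kymograph`) fits, per scan line, a 1D Gaussian plus
constant offset to the counts and converts the centroid to micrometers.
Design choices:

* **Coordinates.** Pixel indices are 0-based and pixel *k* spans
  `[k*a, (k+1)*a)`, so its centre is `(k + 0.5)*a`. The renderer and the
  tracker share the convention, so the closed tracking loop is exact.
* **Local fit window.** The fit runs inside a window of about two PSF
  standard deviations around the brightest (box-smoothed) pixel rather
  than the whole region of interest: with ~13 signal photons per line, a
  four-parameter fit across remote background pixels is unstable.
* **Fixed PSF width.** By default the Gaussian width is fixed at the
  known PSF value (294 nm); at ~13 photons a free width roughly doubles
  the centroid scatter. `fit_sigma = TRUE` restores the free fit.
* **Missing lines.** Lines with fewer than `min_photons` summed counts,
  or failed fits, are filled by linear interpolation and flagged when the
  gap is at most 3 lines; longer gaps split the trajectory, because the
  MSD definition assumes uniform sampling.

The theoretical localization precision (`localization_precision`) is

$$\sigma^2 = \frac{s^2}{N} + \frac{a^2}{12N} + \frac{8\pi s^4 b^e}{a^2 N^2},$$

with PSF width $s$, photons $N$, pixel size $a$ and background $b$ per
5-pixel window. The background exponent defaults to the established
$e = 2$ form but is exposed as a parameter because typeset versions of
the formula are ambiguous. At the reference operating point
($s$ = 294 nm, $N$ = 12.9, $a$ = 100 nm) the first two terms give
$\sigma \approx 82$ nm; the full three-term value at $b = 0.8$ is much
larger (~280 nm), so the quoted 82 nm is the $b \to 0$ value and the
tests assert that value. Empirically the closed tracking loop on
rendered kymographs yields ~0.13–0.19 µm RMS error, between the two
regimes, as expected for least squares with real background.

## 2. MSD and the diffusion-coefficient ledger

For positions $X_1..X_N$, `compute_msd` evaluates the time-averaged,
overlapping-window MSD

$$\mathrm{MSD}(n) = \frac{1}{N-n}\sum_{i=1}^{N-n}(X_{i+n}-X_i)^2,
\qquad n = 1..N-1 .$$

`fit_diffusion_coefficient` estimates $D$ from the initial portion:
every initial window of 3..`max_lags` lags is fit by ordinary least
squares *with intercept* (the intercept absorbs the localization-noise
offset $2\sigma^2$, without which $D$ would be biased), and the longest
window whose slope is significant (p < 0.05, two-sided t-test) **and**
whose $r^2$ clears the per-condition threshold is selected; $D$ =
slope/2. If no window clears the $r^2$ bar the longest significant
window is used and the trace is screened out by the $r^2$ criterion; if
nothing is significant, the first 25% of the curve is fit (fallback).
Negative slopes clamp to $D = 0$ (immobile). Refinement
(`refinement_rules`) finally rejects outliers above a per-condition
cutoff (0.14 µm²/s for remodeler-scale data, 5 µm²/s for fast small
domains) and low-$r^2$ adaptive fits (threshold 0.8).

Two numerical decisions deserve emphasis:

* **`max_lags = 10` by default.** The slope of a *single* trace's
  time-averaged MSD over long windows has very few effective degrees of
  freedom; the resulting per-trace $\hat D$ distribution is strongly
  right-skewed and its *median* underestimates the truth by ~25% at
  N = 600. Fits restricted to the first ~10 lags are unbiased and match
  the fixed-lags-3–10 estimator widely used as a cross-check in the
  single-particle-tracking literature. This was fixed from that
  statistical argument before the acceptance tests were frozen.
* **Joint p/r² window selection.** Selecting the longest significant
  window regardless of $r^2$ and then screening at $r^2 > 0.8$ rejects
  over half of clean simulated traces; the joint rule reduces rejection
  to the few-percent level actually seen in this kind of analysis while
  keeping both criteria meaningful.

`ensemble_stats` summarizes a condition by the **median** $D$ (the
distribution is non-normal), with uncertainty $\mathrm{SEM}\sqrt{\pi/2}$
(the large-sample standard error of a median under normal efficiency),
the mobile fraction ($D \ge 0.007$ µm²/s, the immobile-reference
regime), and percentile bootstrap CIs (5000 resamples) on both.

## 3. Confined and anomalous diffusion

`fit_anomalous` fits $\mathrm{MSD} = D t^\alpha$ over the first 2 s.
The default estimator is unweighted nonlinear least squares on the
linear scale, initialized from a log–log regression; `method =
"loglog"` gives the pure log–log slope. The two agree on clean
power-law data, but on a *saturating* (confined) MSD the log–log fit
overweights the short-lag free-diffusion regime and inflates
$\alpha$; the nonlinear fit weights the plateau as the raw curve does,
which is what separates free ($\alpha \approx 1$) from nucleosome-
confined ($\alpha \ll 1$) ensembles in practice.

`fit_plateau` fits $\mathrm{MSD}(t) = A(1 - e^{-t/\tau})$ and reports
the plateau $A$, the operational confinement length $\sqrt{A}$, and the
reflecting-interval length $\sqrt{6A}$ — for Brownian motion reflected
in an interval of length $L$ the stationary positions are uniform, so
the MSD plateau is $2\,\mathrm{Var}(X) = L^2/6$. Both lengths are
reported because the operational definition ($\sqrt{A}$) is the one
used with experimental plateaus even though it is not the interval
length. Curves whose fitted $\tau$ exceeds the observed lag range, or
where the fit fails, are flagged non-saturating.

`instantaneous_diffusion` slides a 0.4 s window frame by frame, fits
$D$ on each windowed sub-curve with the same adaptive rule (no outlier
screening), and classifies windows as fast (> 0.04 µm²/s),
slow/immobile (< 0.01 µm²/s) or medium. A 0.4 s window holds only 8
frames at 50 ms, so the per-window estimate has ~50% relative scatter
even on clean data; threshold classifications are therefore reliable in
aggregate (occupancy fractions, long dwells) but not window by window,
and the tests assert aggregate behavior only. Dwells are maximal runs
of slow-classified window midpoints; a dwell spans from the start of
its first window to the end of its last, hence lasts at least one
window.

## 4. Binding kinetics

First-arrival times at a DNA molecule under pseudo-first-order
conditions are exponential with rate $k_\mathrm{bind} C$;
`estimate_kbind` uses the exponential MLE (1/mean) and also returns the
per-basepair normalization, since the on-rate grows linearly with the
number of basepairs offered. `fit_survival` builds the Kaplan–Meier
survival curve (so right-censored dwells contribute correctly — the
package buys the estimator from the survival package) and fits
$S(t) = e^{-t/\tau}$ through the origin of $\log S$, reporting the mean
lifetime $\tau$ and half-life $\tau\ln 2$; a poor $r^2$ on the survival
scale flags non-exponential (e.g. mixture) dwell distributions.
`photobleach_correction` extrapolates apparent off-rates linearly to
zero laser power; a negative extrapolation clamps to zero with a
warning.

## 5. Roadblock encounters

`classify_encounters` opens an encounter when the mobile particle
enters within `radius` of the (stationary) roadblock position and
classifies it on exit: crossover if it leaves on the far side, stuck if
it stays at least `stuck_min_duration` (or to the end of the trace),
reflected otherwise. The paper-style convention that an encounter still
open at the trace end is "stuck" is the default; for closed-loop
recovery the `censored_at_end = "exclude"` option treats such events as
right-censored and drops them, because a trace can end during *any*
encounter type and scoring all of them "stuck" inflates that class by
a few percent systematically. `extend_after_bleach` extends a bleached
roadblock trace at its mean observed position, mirroring the practice
of continuing to use a long-lived roadblock's position after its dye
has bleached.

The colocalization radius default (0.164 µm = 2 localization sigma) and
the stuck threshold (2 s) are documented defaults, not measured
constants: real-data fractions are threshold-sensitive, which is why
the closed-loop recovery on synthetic encounters — not any real-data
fraction — is the package's test surface. In the closed-loop tests the
stuck threshold is raised to 5 s because a diffusive transit through a
2-radius zone at 0.024 µm²/s frequently takes more than 2 s, which
would misclassify slow crossings; true stick events are still caught by
the trace-end rule.

## 6. Force–extension and nucleosome counting

The synthetic pulling curve is a Marko–Siggia worm-like chain
(persistence length 50 nm) whose available contour length depends on
how many nucleosomes remain wrapped. Each wrapped nucleosome
sequesters total contour $c_\mathrm{tot} = 34.6\,\mathrm{nm}/\varphi(5\,\mathrm{pN})$
(so the tether at 5 pN is exactly 34.6 nm shorter per wrapped
nucleosome — the compaction relation used for counting), released in
two stages: a gradual part between 5 pN and the unwrap window (outer-
turn peeling) and an abrupt part $c_\mathrm{abrupt} =
25\,\mathrm{nm}/\varphi(F_u)$ at the unwrap force $F_u \sim U(15, 30)$
pN, producing a ~25 nm distance step. The two-stage split exists
because a single-release model cannot honor both the ~25 nm step and
the 34.6 nm compaction number at once; the split mirrors actual
nucleosome mechanics. The plain Marko–Siggia chain at 5 pN sits at
93.6% of contour length — slightly above the empirical ~92% for lambda
DNA, which includes enthalpic stretching the generator does not model;
only the step geometry matters downstream.

`detect_unwrapping_steps` scans the rising segment inside 15–30 pN with
a two-sided sliding-mean jump statistic (threshold 15 nm, ~60% of a
step). Runs above threshold become events; an event's size is the
difference of median levels just outside the run, corrected for the
smooth baseline drift estimated by pooled regression over quiet
segments (a naive per-sample median-difference drift estimate is too
imprecise: its error, multiplied by the measurement span, biases every
event in a curve by several nm in the same direction). Because
independently drawn unwrap forces can coincide within the detector's
resolution, events carry a multiplicity `round(size/ref)` (`ref` the
refined median single-step size), and the step count is the sum of
multiplicities — this is what makes exact recovery of 40 steps possible
when two nucleosomes happen to pop at nearly the same force.
`count_by_compaction` independently counts nucleosomes from the 5 pN
length difference before/after unwrapping at 34.6 nm per nucleosome.

## 7. The synthetic world, and what a green test establishes

`simulate_trajectory` draws Gaussian increments of variance
$2 D \Delta t$; reflecting walls use elastic fold-back (for the
boundary-only case the whole free path is folded, which is
distribution-exact); observable lifetimes are the minimum of
independent exponential bleaching and unbinding clocks. Roadblock
interactions draw one outcome per *encounter episode* (entry into a
zone of one localization sigma), and the drawn outcome is enforced for
the episode: a "reflect" roadblock is a hard wall, "stick" pins the
particle (by default until the trace ends — the release kinetics of a
stuck roadblock complex are not characterized, so the stuck time is
configurable), and "cross" places a reflecting edge behind the particle
so it exits on the far side. Enforcing outcomes is what makes the
generator's multinomial the ground truth that the classifier must
recover; a merely permeable roadblock would let half the "cross" draws
wander back and no classifier could recover the drawn fractions.

Defaults are the conditions the analysis targets: D in the
0.0003–1.5 µm²/s range with 0.024 µm²/s as the reference mobile value,
50 ms line times, 600-frame traces, 82 nm noise, 0.35 µm reflecting
intervals (the mean internucleosome spacing on a sparse array), binding
at 5 nM with per-molecule lifetimes of seconds to minutes, 40-nucleosome
arrays with ~25 nm steps at 15–30 pN.

The generator emulates the *statistical structure* the analysis
assumes: Markovian Brownian motion, ideal exponential lifetimes,
Poisson photon statistics, stationary roadblocks, i.i.d. localization
noise. It does not emulate instrument drift, bead fluctuations,
spectral crosstalk, dye blinking, multi-particle crossing tracks, or
sequence-dependent friction. A green closed-loop test therefore
establishes that the estimators are correct for the model they assume —
it cannot certify real-data numbers, which is why experimental headline
values are covered only by the property-based recoveries.

## 8. Hydrodynamic theory

For a sphere of radius $R$ (from molecular mass via the partial
specific volume 0.73 cm³/g: $V = 0.73 \cdot 10^{21} M / 6.023\times10^{23}$ nm³,
$R = (3V/4\pi)^{1/3}$), the package computes the hopping (translation
only) limit $D = k_BT/6\pi\eta R$ and the sliding limit with rotational
coupling to the helix,

$$f = 6\pi\eta R + \left(\frac{2\pi}{3.4\,\mathrm{nm}}\right)^2
  \left[8\pi\eta R^3 + 6\pi\eta R R_{oc}^2\right],$$

bracketed by $R_{oc} = 0$ (center of mass on the helical axis) and
$R_{oc} = R$. Temperature is not stated with the constants; $k_BT =
4.1143$ pN·nm (298 K) back-solves all printed limits to within 0.6% and
is exposed in `hydrodynamic_model`. Scan time over a length $l$ uses
the 1D relation $l = \sqrt{2Dt}$, i.e. $t = l^2/2D$; the package also
emits $l^2/D$ because both conventions appear in the literature (the
two differ by exactly a factor 2 and reconcile the "46 ms" and "93 ms"
figures quoted for scanning a ~150 bp nucleosome-depleted region at
0.024 µm²/s).

## 9. Known limitations

* Single-particle tracking only: no linking of crossing tracks, no
  drift correction, no 2D imaging.
* The MSD estimator suite is the regression procedure described above;
  covariance-based or maximum-likelihood D estimators are out of scope.
* The TIFF codec is a minimal baseline implementation (16-bit
  grayscale, uncompressed) written because no TIFF package is available
  in the target environment; it is validated against an independent
  reader in the test suite but does not aim to read arbitrary TIFFs.
* Configuration files for the pipeline driver are JSON (no YAML parser
  in the target environment).
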