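---
title: "Smoothing-priors filtering of irregular tachograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothing-priors filtering of irregular tachograms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgphrv)
```

## The model

An HRV tachogram is a set of RR intervals $z_i$ observed at beat times
$x_i$, strictly increasing but irregular. We model the slow trend with a
Gaussian-process-flavoured smoothness prior expressed through a
second-difference penalty and estimate it by Tikhonov-regularized least
squares:

$$\hat y_\sigma = \arg\min_y \|y - z\|^2 + \sigma^2\|\hat D_2 y\|^2
               = (I + \sigma^2 \hat D_2^\top \hat D_2)^{-1} z .$$

The trend $\hat y$ is the low-pass output; $z - \hat y$ is the detrended
(high-pass) output; the decomposition is exact by construction. Because the
solution is a single linear map, the filter is zero-phase: on a uniform
grid the smoother matrix is symmetric, and on irregular grids each output
sample is a weighting function over the whole record whose width adapts to
the local sample spacing — a time-varying filter, with no resampling at any
point.

The assumptions worth keeping in mind: the penalty encodes an
integrated-Wiener-type prior whose spectral density falls as $1/f^4$, so
"trend" means "whatever a second-order smooth process would do"; the data
enter through an identity observation matrix (no measurement model beyond
additive error); and frequency semantics on an irregular axis are only
defined relative to a representative sampling rate (below).

## The nonuniform second-difference operator

Row $i$ of $\hat D_2$ estimates $f''(x_i)$ from the three samples at
$x_{i-1}, x_i, x_{i+1}$. We use the exact three-point divided-difference
stencil

$$\left[\frac{2}{(x_{i-1}-x_i)(x_{i-1}-x_{i+1})},\;
        \frac{-2}{(x_{i-1}-x_i)(x_i-x_{i+1})},\;
        \frac{2}{(x_{i+1}-x_{i-1})(x_{i+1}-x_i)}\right],$$

which satisfies two identities that the test suite enforces on thousands of
random grids: it annihilates affine samples exactly, and applied to samples
of $x^2$ it returns exactly 2. Published presentations of this stencil vary
in how the sign groupings are typeset, and the variants disagree on
asymmetric grids (on $x = (0,1,3)$ the two end coefficients must be
$2/3$ and $1/3$, in that order — swapping them yields 5 instead of 2 on
$x^2$). We therefore treat quadratic exactness, not any particular
typography, as the definition, and `d2hat()` is validated against it.

Two boundary rows are simply absent: the operator is $(T-2)\times T$ and
penalizes interior curvature only. No ghost points or one-sided stencils
are introduced; the endpoints are constrained only through their
neighbours.

All rows are rescaled by the first row's leading coefficient
(`norm_constant`, $1/h^2$ on a uniform grid of spacing $h$). This keeps the
normal-equations matrix well scaled, and it has a consequence worth
stating prominently: the normalization absorbs the grid scale, so a given
$\sigma^2$ corresponds to a cut-off expressed in units of the
representative sampling rate, not in absolute Hz. The bandwidth
calibration below is defined for this normalized operator; physical
cut-offs are converted via $\omega = 2f/f_{s,\mathrm{rep}}$ with
$f_{s,\mathrm{rep}} = 1/\mathrm{median}(\Delta x)$. On strongly non-uniform
grids that conversion is only representative — the method's one
approximation, inherited by every frequency-domain statement the package
makes.

## Numerics

$I + \sigma^2\hat D_2^\top\hat D_2$ is pentadiagonal, symmetric and
positive definite for every $\sigma^2 \ge 0$, so `sgp_smooth()` factors it
with a sparse Cholesky decomposition and applies two triangular solves.
Cost and memory grow linearly with $T$; a dense $T\times T$ matrix is never
materialized (the tests assert the stored systems stay $O(T)$). Identical
grids reuse one factorization across many right-hand sides (the Monte
Carlo below relies on this). $\sigma^2 = 0$ short-circuits to the
identity. Degenerate time axes (duplicates, non-monotone) are rejected,
never sorted: silently reordering an RR record would corrupt it.

Tolerances used by the test suite: trend + residual reproduces the input
to $10^{-10}$ (relative); the sparse solve matches a dense reference solve
to $10^{-8}$ for $T \le 200$; at $\sigma^2 = 10^{12}$ the residual matches
exact affine detrending to $10^{-4}$ of the data scale — the comparison is
made relative to $\max|z|$ because the affine fit of near-zero-mean noise
can itself be arbitrarily small, making a ratio against it ill-posed. At
such extreme $\sigma^2$ the condition number is $\sim\sigma^2$, and the
observed agreement ($\sim10^{-5}$) is the sum of the genuine
finite-$\sigma^2$ gap and solver round-off.

## Bandwidth calibration

In the large-$T$ limit the smoother's equivalent kernel has amplitude
response $h(f) = 1/(\sigma^2 4\pi^2 f^4 + 1)$ on the continuous axis;
mapping to the normalized digital axis by the bilinear transform gives

$$h(\omega) = \frac{1}{\sigma^2\,(2\tan(\omega\pi/2))^4 + 1},
\qquad \omega \in [0,1],\ \text{Nyquist} = 1 .$$

We read $h$ as an **amplitude** response, so the $-3$ dB point is where
$h^2 = 1/2$, i.e. $h(\omega_c) = 1/\sqrt2$. Solving gives the closed form

$$\sigma^2 = (\sqrt2 - 1)\,(2\tan(\omega_c\pi/2))^{-4},$$

implemented with its analytic inverse in `sigma2_from_cutoff()` /
`cutoff_from_sigma2()` (round-trip exact to $10^{-12}$). The leading factor
must be $\sqrt2 - 1$ for the half-power algebra to close; the Monte Carlo
validation below confirms this interpretation empirically.

The actual discrete filter on a uniform grid has asymptotic power response
$1/(16\sigma^2\sin^4(\pi\omega/2)+1)$ — the stencil's transfer function
involves $\sin$, while the calibration was derived through $\tan$. The two
agree as $\omega \to 0$ and diverge towards Nyquist, so the realized
$-3$ dB point solves $\sin(\pi\omega/2) = \tan(\pi\omega_c/2)$: slightly
above nominal, and increasingly so at high cut-offs (at $\omega_c = 0.3$
the realized point is $\approx 0.34$). For $\tan(\pi\omega_c/2) > 1$
(roughly $\omega_c > 0.5$) the discrete filter never reaches $-3$ dB at
all and behaves as a mild shelf; a "low-pass" requested near Nyquist is
effectively an all-pass. This is a property of the method, not a defect of
the implementation, and it bounds what the sequential band-pass can do on
sparsely sampled records (see below).

### Monte Carlo validation

`monte_carlo_cutoff()` measures the realized cut-off: white Gaussian noise
on a uniform grid is filtered through the smoother at the calibrated
$\sigma^2$, Welch periodograms are averaged across replications, and the
frequency where the averaged power first falls to half its low-frequency
plateau is located. Choices the procedure needed that are not forced by
the definition:

* **Welch parameters** — Hann window, 8 segments, 50% overlap, per-segment
  mean removal (configurable). Conventional defaults; the validation
  outcome is insensitive to them at these problem sizes.
* **Plateau** — mean power over the lowest 2% of the frequency axis,
  excluding the DC bin. At the lowest cut-off studied (0.05) the response
  at the plateau's upper edge is still above 0.98 in power, biasing the
  plateau by under 0.1 dB.
* **Crossing** — log-linear interpolation between the two bracketing grid
  frequencies (power decays roughly geometrically through the transition).
* **Problem sizes** — the acceptance script runs 5000 samples × 1000
  replications per cut-off (a few seconds each here, with the
  factorization shared across replications); the test suite uses 200
  replications with correspondingly widened tolerances, and the replicate
  spread at 200 replications sets the tolerance for the low/high cut-off
  rows at ±0.005/±0.02.
* **Seeding** — every stochastic routine takes an explicit integer seed;
  identical seeds give bit-identical results (base R Mersenne-Twister via
  `withr::local_seed()`, which restores RNG state on exit).

## The Lomb-Scargle periodogram

The filtered series stays on its irregular axis, so spectra are estimated
with the classical Lomb-Scargle form, with the $\tau$ shift that makes it
invariant to time-origin translation (asserted to $10^{-10}$). Decisions:

* **Normalization** — twice the sample variance (the classical choice).
  Only peak locations and relative band powers are consumed downstream;
  absolute levels can be recovered by multiplying by the series variance.
* **Evaluation** — direct $O(T\cdot N_f)$ vectorized computation, exact at
  every requested frequency; no FFT gridding approximations. Tachograms of
  minutes to an hour are well within this budget.
* **Default grid** — from $1/\text{duration}$ to the representative
  Nyquist $f_{s,\mathrm{rep}}/2$ in steps of
  $1/(\text{oversample}\cdot\text{duration})$, oversample 4. Arbitrary
  grids may be supplied, including frequencies below the fundamental or
  above the representative Nyquist (irregular sampling carries usable
  information there, with leakage limits set by record length).
* **Mean subtraction** — applied per call, as the estimator assumes
  zero-mean data; a constant series returns zero power rather than an
  error.
* Band powers are trapezoidal integrals with linear interpolation at band
  edges; the standard VLF/LF/HF bands are 0.01–0.04, 0.04–0.15 and
  0.15–0.4 Hz.

## Sequential band-pass

`sgp_bandpass()` fixes the order: detrend first (high-pass at $f_{lo}$,
giving `vt1`, `vt2`), then low-pass the detrended series at $f_{hi}$
(giving `vt3`). On finite data the two orders are not identical and only
this one is offered. The trend `vt1` is retained — inspecting what was
removed costs nothing and is often the point. Both passes share one
operator and time axis; `vt0 = vt1 + vt2` holds exactly and the whole
chain is linear (tested by superposition).

A consequence of the high-cut-off behaviour above: on a typical tachogram
($f_{s,\mathrm{rep}} \approx 1.16$ Hz, Nyquist $\approx 0.58$ Hz), a
low-pass at 0.5 Hz corresponds to $\omega \approx 0.86$ and is a
near-all-pass — `vt3` is then essentially `vt2`, and spectral content
between the nominal $f_{hi}$ and the record's true band limit is **not**
suppressed. The detrending side has no such limit (low normalized
frequencies are exactly where the calibration is accurate), and the
package's tests show $\ge 25$ dB suppression of sub-0.01 Hz power on the
synthetic fixture. Users wanting a true high-side cut on sparse records
should choose $f_{hi}$ well below the representative Nyquist.

## The synthetic generator

`synth_hrv()` emulates the fixture used throughout the tests: Gaussian RR
values (mean 0.85 s — about 75 bpm — sd 0.025 s) on a fine uniform grid,
low-pass filtered at 1 Hz, then projected onto an irregular axis with
increments of mean 0.86 s and variance 0.01 s², 30 s by default. Details
that had to be pinned down:

* **Fine grid** — 4 Hz. The band limit (1 Hz) must sit below the fine
  grid's Nyquist; 4 Hz is the field's conventional resampling rate and
  leaves the 1 Hz transition fully representable.
* **Filter** — 3rd-order Butterworth run forward and backward
  (`signal::filtfilt`), zero-phase by construction, with mean removal and
  reflection padding to suppress edge transients. The filter family is a
  choice; Butterworth is the unexceptional one.
* **"No significant power above 1 Hz"** — a forward-backward 3rd-order
  low-pass is only −6 dB in power at its own cut-off, so band-limitedness
  is asserted above the transition region: mean Welch power at
  $f \ge 1.5$ Hz must sit ≥ 20 dB below the pass-band plateau (measured on
  the pre-projection signal, which is attached to the output as an
  attribute for exactly this purpose).
* **Irregular increments** — normal with the stated mean and variance,
  truncated below at 0.1 s by redraw (a shorter RR interval is not
  physiological; at these parameters truncation is a $7\sigma$ event, so
  the realized mean and variance are unaffected in practice).
* **Projection** — cubic spline interpolation (linear available). The
  choice is visible only above the band limit, where the signal has little
  power either way.

Over 100 seeds the generated records hit mean RR 0.85 ± 0.01 s, mean
increment 0.86 ± 0.02 s and representative sampling frequency
1.15 ± 0.06 Hz.

What passing tests on this fixture do **not** show: the generator is
band-limited noise with a flat pass-band — it has no respiratory peak, no
LF/HF structure, no ectopy, no nonstationarity beyond what the smoother
itself removes. Results about band-power ratios on real tachograms do not
follow from it; only the filtering and spectral machinery is being
validated.

## Known limitations

* The Hz axis on irregular data is defined through the representative
  sampling frequency; records with heavy-tailed interval distributions
  stretch that interpretation.
* The calibration's accuracy degrades towards Nyquist (realized cut-off
  $\approx 0.34$ at nominal 0.3; no $-3$ dB point above $\omega_c \approx
  0.5$), as discussed above.
* Only the second-difference penalty is implemented; higher-order
  penalties and non-identity observation matrices are out of scope.
* No RR artifact/ectopy editing and no epoch-wise batch analysis; the
  package filters whole single records.
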