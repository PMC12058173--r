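---
title: "Morlet wavelet time-frequency analysis of epoched EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morlet wavelet time-frequency analysis of epoched EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegtf)
```

## The model

`eegtf` decomposes event-locked, epoched EEG into the time-frequency plane
with complex Morlet wavelets. A Morlet wavelet at centre frequency $f$ is a
complex sinusoid under a Gaussian envelope,

$$w(t, f) = A \, e^{-t^2 / 2\sigma_t^2} \, e^{2 i \pi f t},
\qquad \sigma_t = \frac{n_{\mathrm{cycles}}}{2 \pi f},$$

where $n_{\mathrm{cycles}}$ fixes the wavelet duration in periods of $f$ and
therefore the time-frequency resolution trade-off: the envelope FWHM is
$2\sqrt{2\ln 2}\,\sigma_t$, so temporal resolution sharpens and spectral
resolution broadens as $f$ grows, with $\mathrm{FWHM}(f) \cdot f$ constant
across the bank. The default is $n_{\mathrm{cycles}} = 7$, the convention of
the developmental EEG literature this package follows (older reports of 3.5
cycles describe the same wavelet under a definition of $\sigma_t$ that
differs by a factor of two). There is no deeper theoretical reason for 7;
`cycles` is a single scalar argument applied to all frequencies, and
frequency-dependent cycle ramps are deliberately out of scope.

Coefficients are the discrete convolution of each DC-removed trace with each
wavelet, centre-aligned so the output inherits the input time axis, and
scaled by $\Delta t = 1/f_s$ so that results are invariant to the sampling
rate. The convolution runs in the frequency domain; the test-suite holds it
against an independently coded direct time-domain convolution (interior
agreement below $10^{-8}$ relative).

### Normalization

The normalization factor $A$ is selectable:

* `none`: $A = 1$, kept for back-compatibility with unnormalized pipelines;
* `amplitude`: $A = \dfrac{1}{2\pi\sigma_t}$, used when the modulus
  (amplitude, in signal units) is the measure;
* `power`: $A = \dfrac{2}{\pi\sigma_t}$, used when the squared modulus is
  the measure.

Both non-trivial factors scale as $1/\sigma_t$. This is a deliberate design
choice, and the property that motivates normalizing at all: with
$A \propto 1/\sigma_t$ the transform responds *identically at every analysis
frequency* to a unit-amplitude sinusoid (flat to $\sim 10^{-5}$ relative in
practice, dominated only by envelope truncation), so frequency content can
be compared quantitatively across frequencies. Normalization constants of
the form $A \propto \sigma_t^{-1/2}$ (unit-energy conventions) do not have
this property — under them the response to a unit sinusoid falls off as
$f^{-1/2}$, a factor of 3 across a 10–90 Hz bank — so we use the $1/\sigma_t$
family and state it explicitly here because conventions differ between
published toolboxes and the constants are easy to mis-read.

### Discretization

Wavelets are discretized at the *signal* sampling rate (anything else would
make the convolution ill-defined) on a symmetric grid with a sample exactly
at $t = 0$, truncated at $\pm 5\sigma_t$ rounded outward to a whole sample.
The truncation point matters more than it looks: a wavelet must have
(near-)zero total area so that the transform does not tilt the signal's
power spectrum. At $\pm 4\sigma_t$ the truncated discrete sum retains a
residual of order $3\times10^{-3}$ of the centre sample; at $\pm 5\sigma_t$
it drops below $10^{-5}$, and the envelope at the edges is below
$4\times10^{-6}$. We therefore truncate at $\pm 5\sigma_t$ and test the
zero-mean property at a $10^{-3}$ relative tolerance, which holds for all
banks with `cycles >= 5` and intentionally fails for degenerate sub-cycle
wavelets.

## Total-induced versus evoked oscillations

`tf_transform()` supports both orders of operations:

* **induced** (default): transform each trial, take the measure
  (modulus/squared modulus), then average across trials
  $\mathrm{avWT}(c,f,t) = \sum_n^N X(c,f,t,n)/N$. Oscillatory activity that
  is *not* phase-locked to stimulus onset survives this average.
* **evoked**: average the trials first (the ERP), then transform the
  average. Non-phase-locked activity cancels in the ERP at a $1/\sqrt{N}$
  rate before the transform ever sees it.

For identical trials the two coincide exactly; for uniformly phase-jittered
bursts the evoked amplitude at the burst locus falls well below the induced
amplitude (the ratio at $N = 200$ is about $0.05$–$0.11$ across seeds,
comfortably below the $0.2$ bound asserted in the tests). DC removal uses
the full epoch extent, not only the pre-stimulus interval, and for evoked
mode it is applied to the ERP *after* trial averaging — the two orders give
identical results because both operations are linear, but the convention is
stated here for reproducibility. `measure = "complex"` retains the raw
coefficients so phase can be extracted; baseline correction and dB refuse
complex input rather than silently taking a modulus.

The per-trial standard error of the mean across trials can be stored
alongside the average (`keep_sem = TRUE`); `plot_tf(show_sem = TRUE)` draws
the contour where the (baseline-corrected) effect exceeds twice this SEM, a
purely descriptive effect-size aid. SEM across *subjects* is not computed
here — group-level display belongs to the statistics package consuming the
exported tables.

## Edge handling

Convolution assumes signal continuity; an epoch boundary is a hard
discontinuity, so coefficients within half a wavelet support of either edge
are distorted, the more so the lower the frequency. The package's rule of
thumb for how much extra signal each edge needs is
$t = 2000 / \min(f)$ milliseconds (e.g. 400 ms for a 5 Hz lower bound), via
`recommend_padding()`. Two remedies exist:

* cut wider segments and remove the contaminated rim after the transform
  with `chop_edges()` — the default analysis chops 300 ms per edge from
  $-500..1500$ ms epochs, leaving 1400 ms segments ($-200..1200$ ms);
* `pad_edges()` before the transform when no wider segment exists. The
  default fill is mirror reflection, which preserves continuity of value at
  the seam and, because the amplitude measure is phase-insensitive, keeps
  near-correct amplitude at the edge; zero filling is available for
  reproducing simpler schemes. Padding provenance is tracked so the same
  amount can be chopped after transformation, restoring the original axis
  exactly.

## Baseline correction

There is no common baseline across frequencies: for every channel and every
frequency, the baseline value $b$ is the mean over the baseline window of
that (channel, frequency) time course alone. Three corrections are offered:

| mode | formula | model |
|---|---|---|
| `subtractive` (default) | $x - b$ | additive signal + noise |
| `subtractive_normalized` | $(x - b)/b$ | relative change |
| `divisive` | $x / b$ | multiplicative (oscillations and 1/f scale together) |

The subtractive default makes spectrograms read like baseline-corrected
ERPs, which is the appropriate choice when signal and background contribute
additively — the common situation in developmental data. The
"subtractive with normalization" variant is implemented as relative change
$(x-b)/b$; this is a declared interpretation (the name alone does not pin
down a formula) and is documented as such. Window endpoints snap to the
nearest sample and are inclusive; the default window is the full
pre-stimulus portion of the (post-chop) axis, e.g. $-200..0$ ms in the
default analysis. Degenerate baselines ($b = 0$ under the two ratio modes)
are an error, not an NaN.

dB conversion uses $20\log_{10}$ on amplitude and $10\log_{10}$ on power so
both measures of the same signal map to the same dB value; it requires
strictly positive input and the error message points to divisive baseline
correction as the standard way to get a positive, reference-relative
surface first.

## Windows, export and plotting

`window_mean()` is the single definition of a time × frequency window
average (endpoints snapped to nearest grid point, inclusive, unweighted
"double average"), and everything else reuses it: `export_stats()` writes
one row per subject and one column per condition × channel (condition-major
— the format does not state an ordering, so ours is fixed and documented)
in full double precision (`%.17g`), and `plot_topo2d()` reduces the tensor
to per-channel scalars through the same function, so the scalar field under
any scalp map is exactly reproducible by `window_mean()`. Scalp maps
interpolate with a biharmonic spline (Green's function
$r^2(\log r - 1)$, augmented with a constant term so flat fields reproduce
exactly), masked outside the electrode convex hull (expanded 15% about its
centroid) intersected with the head disc. The interpolant and mask are
package choices — scalp-map pixels outside the electrodes are extrapolation
and should not be over-read.

## Containers

Results are stored in MAT-v5 containers with the tensor under the variable
name `WT` (channel × frequency × time), axes `Fa` (Hz) and `tim` (ms),
`Fs`, `chanlocs` and `nepochs`, the layout ERPWAVELAB-compatible tools
expect; provenance with no counterpart in that layout (measure, baseline,
chopping, cycles, normalization, subject, condition) lives in the
namespaced struct `eegtf` to avoid collisions. The MAT-v5 writer/reader is
part of the package; files are written uncompressed and the reader also
accepts zlib-compressed elements and integer/single storage, and is
cross-checked in the test-suite against an independent MAT implementation.
Epoched input is read either from EEGLAB `.set` datasets (embedded data or
sibling `.fdt`; the design must carry one single event per epoch) or from
the package's documented `plain_matrix` MAT layout (`data`
trials × channels × samples, `time_ms`, `fs`, `channels`, `condition`,
`subject`), which doubles as the fixture format.

## The synthetic generator

`simulate_epochs()` builds every trace as a sum of oscillatory bursts plus
broadband Gaussian noise. A burst has a frequency, a centre latency, a
width (Gaussian envelope by default, with `duration_ms` equal to the
envelope FWHM so burst width speaks the same vocabulary as wavelet
resolution), an amplitude, and a phase policy: `locked` (same phase every
trial — survives the ERP) or `jittered` (uniform random phase per trial —
cancels in the ERP at $1/\sqrt N$). Noise is white by default; a $1/f^\alpha$
option via spectral shaping exercises the additive-background scenario that
motivates the subtractive baseline. The seed fully determines the output
and the caller's RNG state is untouched.

The bundled `tutorial` fixture emulates the design of an infant gamma-band
experiment: four conditions (`DG`, `AG`, `IDS`, `ADS`), 12 trials per
condition (the trial counts such experiments typically retain after
artefact rejection), 19 channels at 500 Hz, epochs $-500..1500$ ms. `DG`
carries a phase-locked 35 Hz burst at 300 ms, FWHM 100 ms, on the frontal
channels Fp1/Fpz/Fp2, amplitude 3 over unit noise (SNR 3); `AG` lacks it,
so the `DG − AG` contrast through the default pipeline peaks inside the
250–350 ms × 30–40 Hz window; `IDS` carries a jittered 10 Hz burst that
separates induced from evoked measures. What the generator deliberately
does **not** emulate: volume conduction and realistic cross-channel
covariance, artefacts (blinks, motion), non-stationary background, or any
head-model forward projection. Passing tests on this data demonstrate the
*algorithmic* contracts — localization, linearity, attenuation rates, I/O
fidelity — not robustness to the full messiness of recorded infant EEG.

## Numerical and scale choices

Test and acceptance problem sizes are chosen so the full suite runs in
seconds while leaving no property under-sampled: oracle convolution checks
use 100 random 500-sample traces against 3 bank frequencies; flatness sweeps
all 81 frequencies of the default bank; jitter attenuation uses 200 trials;
burst localization uses 20 seeded replicates of 12-trial epochs at SNR 3
(amplitude 3, unit noise) with a 1 Hz step bank, asserting recovery within
±1 Hz and ±$\sigma_t(f_0)$; the end-to-end contrast uses the full 10–90 Hz
bank on the 19-channel tutorial fixture. Tolerances follow the quantity:
exact identities at $10^{-12}$–$10^{-15}$, oracle equivalence at $10^{-8}$,
stochastic properties at the bounds stated above.

## Known limitations

* Inter-trial phase coherence, phase-locking statistics and cross-frequency
  coupling are out of scope (the complex measure gives the raw material).
* Preprocessing (filtering, artefact rejection, re-referencing,
  interpolation of bad channels) is explicitly not included; epochs are
  expected clean.
* 3D scalp rendering and spline-file support are not provided; maps are 2D.
* Continuous (non-epoched) recordings and designs with more than one event
  per epoch are rejected rather than re-aligned.
* The EEGLAB `.set` reader covers epoched datasets with the standard
  `EEG` fields; exotic variants (e.g. multiple linked data files) are not
  supported.

## A minimal session

```{r example, eval = FALSE}
ep <- simulate_epochs(12, 19, fs = 500, window_ms = c(-500, 1500),
                      bursts = burst_spec(35, 300, amplitude = 3,
                                          channels = c("Fp1", "Fpz", "Fp2")),
                      noise_sd = 1, channels = eegtf:::fixture_channels_19(),
                      condition = "DG", seed = 1)
bank <- wavelet_bank(10:90, cycles = 7, fs = 500)
res <- tf_transform(ep, bank)                 # induced amplitude
res <- chop_edges(res, 300)                   # -200..1200 ms
res <- baseline_correct(res, "subtractive")   # per-frequency, -200..0 ms
window_mean(res, c(250, 350), c(30, 40), "Fp2")
plot_tf(res, c("Fp1", "Fpz", "Fp2"))
plot_topo2d(res, layout_1020(), time_window = c(250, 350),
            freq_window = c(30, 40))
```
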