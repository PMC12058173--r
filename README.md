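# eegtf — Morlet wavelet time-frequency analysis for epoched EEG

`eegtf` is an R toolkit for time-frequency decomposition of event-locked,
epoched EEG, written for cognitive-neuroscience workflows (and in
particular the conventions of developmental/infant EEG research): analyse a
multi-subject, multi-condition experiment from epoched input files to
ERPWAVELAB-compatible result containers, statistics-ready tables and
figures, with every step scriptable and testable on synthetic data.

## The method

The signal is convolved with a bank of complex Morlet wavelets

    w(t, f) = A * exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t),
    sigma_t = n_cycles / (2 * pi * f)

one wavelet per analysis frequency (default 10–90 Hz in 1 Hz steps, 7
cycles). The normalization factor `A` (amplitude mode: `1 / (2*pi*sigma_t)`;
power mode: `2 / (pi*sigma_t)`) scales as `1/sigma_t`, which makes the
response to a unit sinusoid identical at every frequency, so frequency
content can be compared quantitatively across the bank. Per trial and
channel, the DC-removed trace is convolved with each wavelet and the
modulus (amplitude, default), squared modulus (power) or raw complex
coefficient is kept; averaging across trials *after* taking the measure
gives **total-induced** oscillations (non-phase-locked activity preserved),
transforming the trial average (the ERP) instead gives **evoked**
oscillations. Convolution-distorted edges are chopped (default 300 ms per
edge; the minimum extra signal needed per edge is `2000 / min(f)` ms), and
each (channel, frequency) time course is baseline-corrected —
subtractive by default, ERP-style, with subtractive-normalized and divisive
options. Results live in a Channel × Frequency × Time tensor stored under
the MATLAB variable name `WT` for interoperability with
ERPWAVELAB-compatible tooling.

## A worked example

Simulate a 12-trial, 19-channel epoched recording carrying a phase-locked
35 Hz gamma burst at 300 ms on the frontal channels, then run the default
pipeline:

```r
library(eegtf)

ep <- simulate_epochs(12, 19, fs = 500, window_ms = c(-500, 1500),
                      bursts = burst_spec(35, 300, amplitude = 3,
                                          channels = c("Fp1", "Fpz", "Fp2")),
                      noise_sd = 1, channels = eegtf:::fixture_channels_19(),
                      condition = "DG", subject = "S01", seed = 1)
ep
#> <eeg_epochs> 12 trials x 19 channels x 1001 samples, fs = 500 Hz, -500..1500 ms (S01 / DG)

bank <- wavelet_bank(10:90, cycles = 7, fs = 500)
bank
#> <wavelet_bank> 81 complex Morlet wavelets, 10-90 Hz, 7 cycles, fs = 500 Hz, normalization = amplitude

head(bank_summary(bank), 3)
#>   frequency_hz  sigma_t_s  fwhm_ms length_samples
#> 1           10 0.11140846 262.3469            559
#> 2           11 0.10128042 238.4972            509
#> 3           12 0.09284038 218.6224            467

res <- tf_transform(ep, bank)                 # induced amplitude
res <- chop_edges(res, 300)                   # remove distorted edges
res <- baseline_correct(res, "subtractive")   # per-frequency, -200..0 ms
res
#> <tf_result> 19 channels x 81 frequencies x 701 samples (amplitude)
#>   10-90 Hz, -200..1200 ms, 12 trial(s) averaged, baseline subtractive, chopped 300 ms/edge
#>   S01 / DG

window_mean(res, c(250, 350), c(30, 40), "Fp2")
#> [1] 0.3290178
```

The `window_mean` value is the mean baseline-corrected amplitude (signal
units) on channel Fp2 over the 250–350 ms × 30–40 Hz window — the injected
burst rising ~0.33 units above the pre-stimulus background, while a
burst-free condition averages near 0 there. `plot_tf(res, "Fp2")` renders
the spectrogram, `plot_topo2d(res, layout_1020(), time_window = c(250, 350),
freq_window = c(30, 40))` the interpolated scalp map, and
`export_stats()` writes subjects × (condition × channel) window means as a
tab-separated table for any statistics package. Multi-subject batches run
via `project_config()` + `run_project()`, which lay out `Import/`, `WT/`
and `Statistics/` folders with a manifest and skip up-to-date outputs.

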