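# eggwave

Artifact rejection and slow-wave analysis for the cutaneous
electrogastrogram (EGG).

The EGG records the gastric slow wave — a ~3 cycles-per-minute (0.05 Hz)
myoelectric rhythm of 50–200 µV at the skin surface. It is attractive for
long-term, noninvasive monitoring of gastric motility, but ambulatory
recordings are riddled with motion artifacts: mV-scale bursts of a few
seconds or less whose broadband power overlaps the 0.02–0.20 Hz analysis
band, so neither band-pass filtering nor window deletion works well. This
package is for researchers processing multichannel EGG (optionally with
simultaneous antral manometry): it cleans the signal, extracts the
standard slow-wave features, selects electrode pairs, and validates the
cleaned EGG against manometric contractility.

## The method

The observed bipolar signal is modelled as `y = x + e` (artifact plus
gastric signal), with `E[e] = 0` and `Var(e) = σ²ₑ` over a window of one
slow-wave cycle. The artifact is estimated by a variant of the linear
minimum mean-squared error (LMMSE) estimator built from *local* moments:

    x̂ₜ = mₜ + max{0, vₜ − σ²ₑ} / max{vₜ, σ²ₑ} · (yₜ − mₜ)

where `mₜ`, `vₜ` are the mean and population variance of `y` in the
centered window around `t`, and `σ²ₑ` is the record-wide mean of the local
variance. The cleaned EGG is `e = y − x̂`, so the decomposition exactly
reconstructs the input. In quiet data the gain is 0 and cleaning reduces
to local detrending; inside a burst `vₜ ≫ σ²ₑ`, the gain approaches 1,
and the burst is subtracted.

Downstream features follow the standard EGG conventions: four-minute
Hamming-tapered spectral windows with 75% overlap; band power at
0.04–0.06 Hz; normalized power (band minus the 0.06–0.10 Hz background);
dominant frequency over 0.02–0.20 Hz; percent of windows with a normal
2–4 cpm dominant rhythm; slow-wave SNR; a manometry motility index
(log pressure area above 9 mmHg per window); and least-squares
EGG-vs-motility regression with Bonferroni adjustment over channels.
A seeded synthetic-data generator provides ground truth for every stage.

## Worked example

Simulate two hours of artifact-laden EGG with coupled manometry, clean
it, and compare features before and after:

```r
library(eggwave)

sim <- simulate_egg(duration_s = 7200, seed = 42)   # 0.05 Hz, 100 uV + bursts
fit <- remove_artifacts(sim, value = observed)
glance(fit)
#> # A tibble: 1 × 6
#>       n    fs window_n mode    sigma_e_sq artifact_burden
#>   <int> <dbl>    <int> <chr>        <dbl>           <dbl>
#> 1 36000     5      101 sliding    105550.          0.0687

spec_raw <- compute_spectrogram(sim, value = observed)
spec_cln <- compute_spectrogram(tidy(fit), value = egg, fs = 5)
percent_normal(spec_raw)   # 72.6  (% of windows with 2-4 cpm dominant rhythm)
percent_normal(spec_cln)   # 100.0
egg_snr(spec_raw)          # 10.6 dB
egg_snr(spec_cln)          # 16.5 dB
```

`sigma_e_sq` is the estimated EGG variance floor (µV²); an
`artifact_burden` of 0.069 means 6.9% of samples had shrinkage gain above
0.5, i.e. were treated as artifact-dominated. Cleaning recovers the
normal slow-wave percentage (72.6% → 100%, the bursts had pushed a
quarter of the windows off-rhythm) and raises the slow-wave SNR by ~6 dB.

The cleaned band power also tracks simulated antral contractility:

```r
pr <- simulate_coupled_manometry(sim, seed = 43)
mi <- motility_index(pr)                     # ln(area above 9 mmHg) / window
feats <- egg_features(spec_cln)
nw <- min(nrow(feats), nrow(mi))
correlate_egg_manometry(
  tibble::tibble(band_power_db = feats$band_power_db[seq_len(nw)],
                 mi = mi$mi[seq_len(nw)])
)
#> <egg_correlation> EGG band power vs motility index
#>   r = 0.527, slope = 0.07646, n = 117 windows
#>   p = 9.98e-10 (Bonferroni x1: 9.98e-10)
```

`autoplot()` methods exist for the decomposition, spectrograms,
event-aligned averages and correlations; `run_validation_pipeline()` and
`run_ambulatory_pipeline()` chain the whole workflow, and
`inst/cli/eggwave.R` exposes it as shell subcommands
(`simulate`, `clean`, `features`, `correlate`, `validate`, `ambulatory`).

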