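# eegfbp

Depth-based exploratory spectral analysis of epoched EEG recordings, for
analysts who work with multichannel recordings segmented into short
stationary epochs and want distribution-free answers to three questions:
what is the *typical* spectrum across epochs, which epochs are spectrally
*unusual* (artifact candidates), and did the spectral content *change*
between phases of the recording?

The observation unit is a whole curve or surface, so the package is built
on functional data depth rather than pointwise statistics:

* **Spectral estimation** — per-epoch periodogram
  `I(ω_k) = |Σ_t X(t) e^{-i2πω_k t}|² / T`, boxcar smoothing with the span
  `2p+1` selected automatically by minimizing the gamma generalized
  cross-validated deviance
  `GCV(p) = M⁻¹ Σ_j q_j {−log(I_j/f̂_j) + (I_j−f̂_j)/f̂_j} / (1−W_{p,0})²`,
  log transformation with the Euler–Mascheroni bias correction
  `Y(ω_k) = log f̂(ω_k) + 0.57721`, band power over the conventional
  delta/theta/alpha/beta/gamma bands, and 60 Hz line-noise repair.
* **Depth** — band depth (BD), modified band depth (MBD; exact fast
  rank-based path in `O(nK log n)` that matches brute-force pair
  enumeration exactly), and modified volume depth (MVD) for surfaces.
* **Functional and surface boxplots** — median curve/surface, 50% central
  region from the `⌈n/2⌉` deepest members, fences at 1.5× the central
  height, whole-curve outlier flags, plus the classical pointwise-boxplot
  comparator.
* **Inference** — the depth rank-sum test: both families' curves are placed
  on a reference sample's depth scale, pooled positions are ranked, and the
  second family's rank sum `T` is referred to the null of `m` ranks drawn
  without replacement from `1..n+m` (Monte Carlo, normal, or exact null);
  per-channel early-vs-late stationarity screens with Bonferroni
  correction; region averaging.
* **Synthetic data** — AR(1) mixtures with two spectrally distinct groups,
  band-concentrated AR(2) processes, the two-family curve model
  `Y(ω_k) = f(ω_k) + a_r + h_r(ω_k)` with three mean-deviation scenarios,
  and injected outlier curves, so the whole pipeline is testable and
  calibratable without any recording.

## Worked example

Twenty 1-s epochs of an AR(1) signal, one contaminated curve injected, then
the functional boxplot against its pointwise comparator:

```r
library(eegfbp)

ef <- epoch_family(t(sapply(1:20, function(i) simulate_ar1(0.7, 200, seed = i))),
                   fs = 200)
curves <- spectral_curves(ef, span = 3)          # log bias-corrected curves
fam <- inject_outlier_curve(curves, low_band_noise_sd = 2, seed = 99)

functional_boxplot(fam)
#> <functional_boxplot> 21 curves, factor = 1.5
#>  median curve: 7
#>  outliers: 21

pointwise_boxplot(fam)
#> <pointwise_boxplot> 21 curves, coef = 1.5
#>  curves flagged at >= 1 point: 18; at every point: 0
```

The functional boxplot identifies epoch 7's curve as the typical log
spectrum and flags exactly the injected curve (number 21) as a whole-curve
outlier. The pointwise comparator, working frequency by frequency, scatters
flags over 18 curves and never identifies any *curve* as outlying — the
contrast the depth ordering exists to fix.

Comparing two simulated families whose mean functions differ by `2k/3`:

```r
fams <- simulate_curve_families(curve_family_spec("appreciable", seed = 1))
rank_sum_test(fams$family1, fams$family2, seed = 2)
#>  Depth-based rank-sum test for equality of median curves
#>
#> T = 1297.5 (null mean 2525, sd 145.057), n = 50, m = 50
#> p-value = 2e-04  [montecarlo, 10000 null draws]
#> H0 rejected at alpha = 0.05
```

The second family's curves sit outside the reference family's envelope, so
their positions collect the low ranks and `T` falls far below its null mean
of `m(n+m+1)/2 = 2525`.

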