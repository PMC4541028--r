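---
title: "Exploratory spectral analysis of epoched EEG with functional boxplots"
author: "eegfbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploratory spectral analysis of epoched EEG with functional boxplots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(eegfbp)
```

## The problem

A resting-state EEG recording is typically segmented into short consecutive
epochs (here the working scale is 1-s epochs of $T = 1000$ samples at
1000 Hz), each treated as a realization of a zero-mean stationary process.
The scientific questions this package addresses are exploratory: what does a
*typical* spectrum look like across epochs, which epochs are spectrally
*unusual* (artifact candidates), and did the spectral content *evolve*
between an early and a late phase of the recording — i.e., is the process
stationary at the scale of minutes?

The observation unit throughout is a whole curve (a log spectrum over
frequency) or a whole surface (a band-power map over the scalp), not a
scalar. The package therefore combines per-epoch spectral estimation with
functional data depth, which orders curves from the center of a family
outwards and supports median curves, central regions, whole-curve outlier
flags, and a nonparametric two-sample test.

## Per-epoch spectral estimation

For an epoch $X(0), \dots, X(T-1)$ (mean-detrended), the periodogram at the
Fourier frequencies $\omega_k = k/T$ is
$$I(\omega_k) = \frac{1}{T}\Big|\sum_{t=0}^{T-1} X(t)\,
  e^{-i 2\pi \omega_k t}\Big|^2, \qquad k = 0, \dots, \lfloor T/2 \rfloor.$$
It is approximately unbiased for the spectrum $f(\omega)$ but inconsistent,
so `boxcar_smooth()` averages each ordinate over a span of $2p+1$ neighbors
with equal weights $W_{p,j} = 1/(2p+1)$. Indices beyond the grid ends are
filled by even reflection ($I(\omega_{-k}) = I(\omega_k)$ at DC and the
mirror-image rule at Nyquist), which is the symmetry the two-sided
periodogram actually possesses rather than an ad-hoc boundary fill.

The span is the tuning parameter that matters. `select_span()` chooses $p$
by minimizing the gamma generalized cross-validated deviance
$$\mathrm{GCV}(p) = \frac{M^{-1} \sum_{j=0}^{M-1} q_j
  \{-\log(I_j/\hat f_{p,j}) + (I_j - \hat f_{p,j})/\hat f_{p,j}\}}
  {(1 - W_{p,0})^2},$$
with $M = \lfloor T/2\rfloor + 1$, half weights $q_j$ at the DC and Nyquist
bins (one rather than two chi-squared degrees of freedom there), and
$\mathrm{tr}(H_p)/M$ replaced by the center weight $W_{p,0}$ of the boxcar.
The criterion exploits the asymptotic gamma distribution of the raw
periodogram, so the span is always selected on the *raw* scale. $p = 0$
makes the denominator vanish and scores $+\infty$, as does any span that
produces a zero smoothed ordinate; the default grid is
$1, \dots, \min(30, \lfloor T/4\rfloor)$, wide enough for flat spectra while
keeping the smoother well inside the half-spectrum.

Because $I(\omega_k)/f(\omega_k)$ is asymptotically a unit-mean exponential
at interior frequencies, $E\log I = \log f - \gamma$ with
$\gamma \approx 0.57721$ the Euler–Mascheroni constant, and
$\operatorname{Var}\log I = \pi^2/6$ independently of frequency.
`log_bias_correct()` therefore returns $\log(\cdot) + 0.57721$: an
approximately unbiased, variance-stabilized estimate of the log spectrum —
the right scale on which to compare whole curves across epochs and phases.

Two orderings of smoothing and log transformation are defensible, and both
are implemented in `spectral_curves()`. The default `smooth-then-log`
smooths the raw periodogram at the GCV-selected span and then takes the
bias-corrected log; the alternative `log-then-smooth` applies the same span
as a boxcar on the log-corrected raw curve. The default is preferred because
the GCV theory lives on the raw scale; the alternative is kept behind the
`log_mode` flag rather than guessed away. (In the alternative mode the DC
ordinate of a demeaned epoch is exactly zero and is floored to a configurable
small positive value before the log; flooring is a documented warning in
`log_bias_correct()` itself.)

Band power `band_power()` is a left Riemann sum of ordinates whose center
frequency falls in the half-open band $[\mathrm{lo}, \mathrm{hi})$, with bin
width $f_s/T$. Half-open bands mean the conventional delta/theta/alpha/beta
boundaries (4, 8, 16, 32 Hz) are never double-counted; a band whose upper
edge reaches Nyquist is closed there so one band can cover the whole axis.
Narrowband mains contamination is repaired by `repair_line_noise()`, which
replaces a one-bin neighborhood of the line frequency by the mean of its
nearest untouched neighbors.

```{r spectra-demo}
x <- simulate_ar2_band("alpha", fs = 1000, n_samples = 1000, seed = 1)
sel <- select_span(periodogram(x, fs = 1000))
sel
plot(sel$spectrum, main = "GCV-smoothed periodogram, alpha-band AR(2)")
```

## Depth, functional boxplots, and their comparator

For curves $Y_1, \dots, Y_n$ on a common grid, the band of a pair
$(Y_\alpha, Y_\beta)$ is the region between their pointwise min and max.
Band depth (`band_depth()`) counts the fraction of the $\binom{n}{2}$
unordered pairs whose band contains a curve entirely; modified band depth
(`modified_band_depth()`) replaces the all-or-nothing indicator by the
*proportion* of grid points inside the band, which de-degenerates the
ranking for noisy curves. Boundary ties count as inside, and the domain
measure is the counting measure on the grid — the computable discretization
of Lebesgue measure for sampled curves. The implementation note that
matters: the depth sums run over unordered distinct pairs, which is the
convention that makes the $\binom{n}{2}$ normalization exact.

The fast path computes, at each grid point, the number of covering pairs
from the curve's pointwise rank ($a$ values strictly below, $b$ strictly
above, so $\binom{n}{2} - \binom{a}{2} - \binom{b}{2}$ pairs cover), at
$O(nK\log n)$ total cost. It agrees *exactly* with brute-force pair
enumeration, including under pointwise ties, and that equivalence is a
standing property test rather than an assumption. Modified volume depth
(`modified_volume_depth()`) is the identical construction over a finite
2-D site set; on 1-D-degenerate site sets it coincides with MBD, which the
tests also pin down.

`functional_boxplot()` sorts curves by MBD and reports: the deepest curve as
the functional median (tied deepest curves are averaged — and unlike the
connected pointwise median, the functional median is anchored to actually
observed curves); the pointwise envelope of the $\lceil n/2\rceil$ deepest
curves as the 50% central region; and fences obtained by inflating that
envelope by `factor` (default 1.5, the classical boxplot convention) times
its pointwise height. A curve is a potential outlier if it crosses a fence
at *any* grid point — the stricter of the two readings of "outside the
fence region", chosen because a single large spectral excursion is exactly
what an artifact looks like; the choice is a documented parameter of the
design, not a claim about intent. Raising `factor` never adds outliers, and
spatio-temporally correlated families may warrant a larger value; no
automatic adjustment is attempted.

`pointwise_boxplot()` is the deliberate comparator: an independent
1.5-IQR boxplot per frequency. It flags *points*, not curves, so a globally
aberrant curve with locally plausible values escapes it — the package
reports per-curve summaries (`flagged_any`, `flagged_all`) to make this
contrast measurable.

`surface_boxplot()` repeats the construction for band-power scalp maps
ordered by MVD, with the inner envelope (border of the 50% central region),
fences by the same inflation rule, and the outer envelope as the border of
the maximum non-outlying region. Surfaces stay on the finite channel-site
set: interpolating to a smooth grid before computing depth would make the
ordering depend on the interpolant, so interpolation is treated strictly as
a display concern.

```{r fbp-demo}
ef <- epoch_family(t(sapply(1:10, function(i) simulate_ar1(0.7, 200,
                                                           seed = i))),
                   fs = 200)
curves <- spectral_curves(ef, span = 3)
fam <- inject_outlier_curve(curves, low_band_noise_sd = 2, seed = 99)
fb <- functional_boxplot(fam)
fb
plot(fb, xlab = "frequency (Hz)", ylab = "log power")
```

## The depth rank-sum test

To compare two families $\{y_1,\dots,y_n\}$ and $\{y'_1,\dots,y'_m\}$,
every curve is placed on the depth scale of a *reference sample* (the first
family by default): its position $R(\cdot)$ is the fraction of reference
curves with no larger depth. The pooled positions are ranked $1..n+m$ with
midranks for ties, and the statistic is the sum $T$ of the second family's
ranks. Under the null of equal median curves the families are exchangeable
and $T$ is distributed as the sum of $m$ ranks drawn without replacement
from $1..n+m$ — mean $m(n+m+1)/2$, variance $nm(n+m+1)/12$. The two-sided
p-value is computed by seeded Monte Carlo (default $10^4$ draws, add-one
corrected), by normal approximation, or exactly for $n+m \le 12$.

One design point deserves emphasis. Depths must be measured *with respect
to the reference sample*, with a curve's own delimiter pairs excluded, so
that member and non-member depths are the same functional of the reference.
The superficially attractive alternative — computing depths once within the
pooled sample — destroys the test: two families that differ by a large
shift each form an internally coherent cluster, receive similar pooled
depths, and become indistinguishable (in simulation the pooled variant has
essentially zero power under a large mean shift, and its size is far from
nominal). The pooled variant is retained behind `depth_scope = "pooled"`
only so that this comparison can be reproduced.

`stationarity_screen()` applies the test channel-wise to early-phase vs
late-phase log spectral curve families (default phases: first and last
$\min(60, \lfloor n/2\rfloor)$ epochs) and reports raw and
Bonferroni-corrected calls at level $\alpha/\#\text{channels}$;
`region_average()` optionally collapses channels to predefined scalp
regions *before* spectral estimation, which averages down independent
channel noise while preserving coherent signal.

## What the synthetic-data generators emulate

`simulate_mixture_groups()` regenerates a two-group epoch design: 220
epochs of $X_r(t) = a_{1r}U_{1r}(t) + a_{2r}U_{2r}(t)$, where the AR(1)
components have per-epoch coefficients $0.9 + \xi_r$ and $-0.5 + \eta_r$
with jitter variance 0.001 (small enough that causality is never at risk;
violating draws are redrawn), $a_{1r} \sim N(10,1)$ everywhere, and
$a_{2r} \sim N(5,1)$ in the first 120 epochs but $N(0, 0.001)$ in the rest.
The innovation variance is left free by the design and defaults to one; the
two components are driven by independent noise streams. The first group's
spectra show two elevated regions (the $\phi = 0.9$ component concentrates
power at low frequencies, the $\phi = -0.5$ component at high frequencies);
the second group's collapse to the single low-frequency region.

`simulate_ar2_band()` produces band-concentrated AR(2) processes by placing
the conjugate pole pair at the band-midpoint angle with modulus 0.95 by
default. A caveat the tests document: an AR(2) peak sits *below* its pole
angle, and collapses onto DC when $1-\rho$ is not small relative to the
angle — at 1000 Hz the delta and theta midpoints need $\rho \gtrsim 0.99$,
so the modulus is an explicit parameter rather than a constant.

`simulate_curve_families()` regenerates the two-family curve model
$Y_{\ell,r}(\omega_k) = f_\ell(\omega_k) + a_r + h_r(\omega_k)$ on
$\omega_k = k/100$, with $a_r \sim N(0, 5)$, $h_r \sim N(0, 2)$ (read as
variances; both are parameters so the standard-deviation reading can be run
too), and window-7 moving-average smoothing with boundary shrinkage. The
three mean-function cases are: identical ($f_2 = f_1$), "slight" deviation,
and "appreciable" deviation ($f_2 = f_1 + 2k/3$). The default means
implement the printed arithmetic $f_1 = 5\cdot 1000\,\omega$,
$f_2 = 5\cdot 900\,\omega$ literally, but note that this makes the
"slight" gap ($5k$ at index $k$) *dominate* the "appreciable" gap
($2k/3$) at every frequency, which inverts the intended ordering of the
scenarios; since depth is invariant to common shifts, only the difference
$f_2 - f_1$ matters at all. Both means are therefore injectable: a
log-scale reading $5\log(1000\omega)$ vs $5\log(900\omega)$ gives a
genuinely slight constant gap of $5\log(10/9) \approx 0.53$ and is the
alternative the tests also exercise. Under the literal reading the slight
case rejects essentially always; under the log reading it barely moves the
test. Neither reading lands between the two, so the "slight" scenario
should be treated as qualitative.

`inject_outlier_curve()` emulates a contaminated epoch: the family's
pointwise median plus high-variance noise over an initial fraction
(default 20%, e.g. 0–100 Hz of a 0–500 Hz axis) of the grid and smaller
noise elsewhere. The off-band noise defaults to one fifth of the low-band
scale. This is a considered choice: if the off-band noise is made much
smaller, the injected curve tracks the pointwise median so tightly that it
attains the *highest* depth in the family, joins the 50% central region,
inflates its own fences, and can never be flagged by any fence rule. At
one fifth — comparable to a typical family's own pointwise spread when the
low-band noise is a few times that spread — the curve is an ordinary member
off-band and its outlyingness is carried entirely by the contaminated band,
which is the phenomenon the functional boxplot is designed to catch and the
pointwise comparator provably misses.

## Calibration at the study scale

The packaged study harness `rank_sum_power()` runs the full
generate–smooth–depth–test cycle. At the design scale (two families of 50
curves on a 100-point grid, 1000 replicates, $\alpha = 0.05$) the suite
asserts: empirical size within $[0.03, 0.07]$; power under the appreciable
deviation $\ge 0.99$; and the slight-case behavior under both mean-function
readings as described above. The replicated harness uses the normal
approximation to the rank null — at $n = m = 50$ it agrees with $10^5$-draw
Monte Carlo to within 0.02, which the tests verify directly — while
single-test calls default to seeded Monte Carlo.

These are also the sizes used by `scripts/acceptance.R`; they run in tens
of seconds on one core. Other standing property tests: Parseval's identity
on every epoch (at $10^{-8}$ relative tolerance), weight normalization and
symmetry of the boxcar, exact fast-vs-brute depth agreement on hundreds of
randomized families including ties, depth invariance under common shifts
and positive scaling, rank conservation $T_1 + T_2 = (n+m)(n+m+1)/2$, and
nestedness of central regions in the coverage fraction.

## Numerical choices and degenerate inputs

* Natural logs throughout; the bias constant is the conventional
  five-decimal truncation 0.57721.
* Zero periodogram ordinates are floored at the smallest positive ordinate
  times `floor_frac` (default $10^{-6}$) with a warning; an all-zero
  spectrum is an error, and a constant epoch yields an all-zero periodogram
  with a warning flag rather than an error.
* Ties: pointwise ties count as inside bands; tied deepest curves are
  averaged into the median; tied positions receive midranks; tied GCV
  scores select the smallest span.
* Constant families produce a degenerate, zero-height boxplot with no
  outliers (fence crossing is strict).
* Burn-in for all AR simulators is 500 steps; seeded generators restore the
  caller's RNG state.

## What passing tests do and do not show

The generators produce Gaussian, perfectly epoch-stationary data with
independent epochs and (for the curve model) exchangeable curves. Real EEG
has heavier tails, autocorrelated artifacts, volume-conducted spatial
correlation between channels, and epoch-to-epoch dependence — none of which
are emulated, and no claim is made that the 256-channel geometry or any
published per-channel finding is reproduced here. Calibration results
therefore validate the *machinery* (depth kernels, boxplot construction,
null distribution, span selection) under the stated models, not the
behavior of the pipeline on any particular recording. Confidence bands for
the median curve are out of scope.
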