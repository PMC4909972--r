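---
title: "Pairwise-complex ICA: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise-complex ICA: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwcica)
```

## The problem

Blind source separation (BSS) for multichannel time series assumes that the
observed channels x(t) are an unknown linear mixture of unobserved sources,
x(t) = A s(t). Classical ICA estimates a demixing matrix W ≈ A⁻¹ by making
the recovered components as statistically independent as possible — but its
objectives look only at the empirical distribution of samples, not at their
order. For signals such as EEG, generated by coupled oscillatory processes,
the temporal ordering carries real information.

Pairwise-complex ICA exploits that ordering. If the mixing is stationary, the
rate of change v(t) = dx/dt obeys the *same* mixing: v(t) = A ds/dt. Stacking
(x, v) doubles the dimension, but demanding a block-diagonal
demixing diag(W, W) on the doubled space is exactly the constraint satisfied
by a *complex-linear* map on z(t) = x(t) + i·v(t). The package therefore:

1. forms lagged observation pairs (x(t), x(t + h)) within each epoch;
2. maps each pair to a base/velocity pair (phase-space transform);
3. complexifies, z = base + i·velocity;
4. whitens (Hermitian covariance → identity) and runs a complex fixed-point
   ICA whose contrast depends only on |w^H z|², so each estimated row is
   identified only up to a unit-modulus factor e^{iφ};
5. resolves each φ analytically by maximizing the variance of the real part
   cos(φ)R − sin(φ)I of the demixed time course over the original signal —
   the closed form is φ = ½·atan2(2·R·Iᵀ, I·Iᵀ − R·Rᵀ) plus a quarter-period,
   with the maximizing representative selected and reduced mod π;
6. assembles the real demixing W = C·ℜ(Φ) − S·ℑ(Φ), C = diag cos φ,
   S = diag sin φ.

The same phase simultaneously *minimizes* the variance of the orthogonal
(imaginary) branch; the gap `var_max − var_min` is reported per component as
a quality heuristic (near zero for circular, phase-ambiguous components).

## Phase-space variants and the lag

Two scalings of the pair transform are offered. Mode `"v"` uses the physical
time scale: base = (x(t) + x(t+h))/2, velocity = (x(t+h) − x(t))/(h·Δt) — the
signal and its average rate of change over h samples. Mode `"haar"` uses the
orthogonal sum/difference scaling 1/√2 for both halves and ignores the
sampling interval; it preserves Euclidean norms exactly, so white noise keeps
its distribution under the transform. For h = 1 and Δt = 1 the two differ
only by the blockwise diagonal factor diag(2, 1)/√2.

The velocity half of the lag-h map convolves each channel with the difference
filter [1, 0, …, 0, −1]/(h·Δt) of length h + 1, with magnitude response
2|sin(π f h / f_s)|. Its first local maximum lies at f_s/(2h) (at Nyquist for
h = 1), so the lag selects the band whose dynamics the imaginary part
emphasizes: `lag_filter_response(8, 250)` puts it at 15.625 Hz, in the upper
alpha/beta range. Larger h also partitions the spectrum into more alternating
bands routed to the real or imaginary part.

A comparator mode `"hilbert"` skips the pairwise stages and uses the analytic
signal (imaginary part = Hilbert transform of each channel, computed in the
frequency domain per epoch) as the complex embedding; it loses no samples
and carries no lag parameter.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lag_h` | 1 | pair separation in samples; sets the emphasized band f_s/(2h) |
| `mode` | `"haar"` | pair scaling (`"v"` physical, `"haar"` orthogonal) or `"hilbert"` |
| `contrast` | `"log"` | G(u) = log(a + u) on u = \|w^H z\|²; `"sqrt"`, `"square"` available |
| `a` | 0.1 | stabilizer of the log/sqrt contrasts |
| `tol` | 1e−7 | stop when 1 − min_j \|⟨w_j^{k+1}, w_j^k⟩\| falls below this (phase-blind) |
| `max_iter` | 1000 | iteration cap; non-convergence is flagged per run, never fatal |
| `fun` | `"symmetric"` | parallel update with symmetric decorrelation; `"deflation"` available |
| `saddle_test` | `FALSE` | optional post-hoc pairwise π/4-rotation check of the converged basis |

Numerical choices: whitening uses the inverse principal square root of the
Hermitian covariance E[zz^H] (eigendecomposition; a rank-deficient covariance
is an error naming the number of degenerate dimensions, never a silent
reduction). The pseudo-covariance norm ‖E[zz^T]‖_F is recorded as a
circularity diagnostic. Initialization is a seeded random complex Gaussian
basis, orthonormalized; fixed seed and input give bitwise-identical results.
Phase ties (both critical variances equal within 1e−12, i.e. circular
components) resolve to the representative in [0, π/2). Each W row is
sign-flipped so its largest-magnitude entry is positive, and rows are ordered
by descending quality score (the pre-ordering permutation is kept in
`$order`).

Centering happens once, per channel, over the whole recording, at embed time.
For the `"haar"` mode the transform is linear, so centering before or after
the pair transform is equivalent; doing it first also serves the `"v"` mode
and the Hilbert comparator uniformly. Pairs never span epoch boundaries
(each epoch of length L contributes L − h pairs), and the Hilbert transform
is likewise applied per epoch to avoid cross-epoch leakage.

The phase-resolution variances are computed over the **full-length** original
centered signal, not the pairwise-shortened base: W is meant to act on raw
signals, so the phase choice should be optimal for that use.

## The simulation testbed

`simulate_experiment()` generates three vector-autoregressive source models,
each 100 epochs × 500 samples at 200 Hz with unit-variance Gaussian
innovations, independent epoch restarts and a 1000-sample burn-in:

1. ten uncoupled AR(2) damped harmonic oscillators
   (s_t = 2r cos(2πf₀/f_s)s_{t−1} − r²s_{t−2} + w_t), pole radii r drawn
   uniformly in [0.95, 0.999] per source and repetition;
2. five oscillators (5, 8, 11, 15, 20 Hz) with constant first-order
   cross-couplings (0.05 on a directed ring);
3. ten oscillators in two clusters of five with static within-cluster
   first-order couplings (0.02) and second-order cross-cluster couplings
   oscillating sinusoidally at per-edge frequencies in [0.1, 1] Hz,
   amplitude 0.02 (weak enough to keep the near-unit-circle oscillator
   poles stable throughout the coupling cycle).

The oscillator fundamentals are fixed at 3, 5, 7, 9, 11, 13, 15, 18, 21 and
25 Hz — ten distinct values spanning the delta-to-beta range that EEG source
models typically occupy, spaced so that each source shows a single resolvable
spectral peak. Every coupled draw is screened for companion-matrix spectral
radius < 1 (over a grid of coupling phases for the time-varying model) and
redrawn when unstable.

Mixing matrices are i.i.d. standard normal, resampled until the 2-norm
condition number is ≤ 30 — the operational meaning of "well-conditioned"
here, exposed as `cond_max`. Observation noise (`mix_and_noise`) is Gaussian,
scaled per channel to a stated signal-to-noise power ratio (1:1 in the
benchmark experiments); `snr = Inf` disables it. The benchmark protocol used
by `scripts/acceptance.R` instead injects the 1:1 Gaussian noise *into the
generated sources* before noiseless mixing (`source_noise()`), treating the
noisy source as the ground truth; see "Benchmark protocol" below.

What the generator does *not* emulate: volume conduction/head-model mixing
(mixings are generic random matrices), non-stationary mixing, artifacts,
line noise, or heavy-tailed sensor noise. Passing the benchmark suite
therefore shows correct behavior under the stated VAR conditions, not
performance claims on real EEG.

## Benchmark protocol

The repetition protocol scored by the acceptance script is: generate the
Experiment-1 sources, add per-source Gaussian noise at 1:1 power, mix the
noisy sources through a fresh well-conditioned random 10×10 matrix, run each
algorithm, and score the scaled Amari index of W·A (and, for the
correlation benchmark, the number of noisy sources matched by some component
at |r| ≥ 0.7). Placing the 1:1 noise inside the generative model rather
than at the sensors keeps the linear ICA model exact and makes the
correlation benchmark informative: with sensor-level noise of equal power,
even a perfect demixing row cannot exceed |r| ≈ 1/√2 ≈ 0.707 against its
source, and a threshold of 0.7 would count nothing but estimator noise. The
per-channel sensor-noise model remains the default of `mix_and_noise()` for
general use.

Problem sizes: the package's own benchmark runs use 20 repetitions of the
full 10 × 50,000 Experiment-1 design for the Amari and matching comparisons,
1,000 random demixing draws per mixing matrix (20 matrices) for the random
baseline, and 10⁴-sample circular mixtures for the complex-ICA recovery
checks. The benchmark configuration caps the fixed-point iteration at 150:
on these near-Gaussian mixtures the search plateaus early (the Amari score
changes by less than 0.01 between 100 iterations and full convergence around
500) and the cap keeps a full benchmark sweep to roughly a quarter hour on
one CPU; non-convergence at the cap is flagged in the provenance, as always.

One benchmark behavior worth understanding rather than hiding: the
time-scaled lag-1 variant separates on a velocity-dominated embedding (the
1/Δt factor makes the imaginary part roughly f_s/(2π f) times larger than
the real part for a source at frequency f), so its component-to-source
matched counts depend strongly on where the oscillator bank sits relative to
Nyquist. With the 3–25 Hz bank at 200 Hz, most sources live far below the
difference filter's passband and the matched count is low (about 1–2 of 10),
while the Haar variants match 3–5.

## Known limitations and open choices

* The complex fixed-point search on near-Gaussian oscillator mixtures has a
  shallow objective; distinct seeds (or BLAS rounding) can land on slightly
  different local optima. The symmetric scheme with the log contrast was the
  most stable configuration tested; the optional saddle-point pass rarely
  changed results on these mixtures and stays off by default.
* Component order and sign are not identifiable; the conventions here
  (quality-sorted, largest-entry-positive) are deterministic but are package
  conventions, not claims about any other implementation.
* The entropy estimator behind `mutual_information_reduction()` is a Vasicek
  m-spacing estimator with m = ⌈√T⌉ (histogram variant available); it is
  consistent but biased at small T, so MIR values are comparable across
  transforms of the same data, not across sample sizes.
* Noncircular complex sources violate the whitening/contrast assumptions
  (the pseudo-covariance diagnostic flags this); the pairwise embedding of a
  real signal is generically noncircular to a degree, which is precisely why
  the phase-resolution step carries information.
```
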