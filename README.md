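# pwcica

Blind source separation for multichannel time series (EEG and similar
recordings) that uses the *temporal ordering* of the data. Classical ICA
treats samples as exchangeable draws; `pwcica` implements pairwise-complex
ICA, which maps consecutive observation pairs into a complex vector space
encoding the signal and its rate of change, solves a complex fixed-point ICA
there, and resolves the resulting per-component phase ambiguity analytically
to recover a real demixing matrix.

## The method in brief

For a stationary linear mixture x(t) = A s(t), the rate of change obeys the
same mixing, v(t) = A ṡ(t). A demixing of the stacked pair (x, v) that is
block-diagonal diag(W, W) is exactly a complex-linear map acting on
z(t) = x(t) + i·v(t). The pipeline is

1. **pairwise embedding** — lagged pairs (x(t), x(t+h)) within each epoch;
2. **phase-space transform** — base (x(t)+x(t+h))/2 and velocity
   (x(t+h)−x(t))/(hΔt) (mode `"v"`), or the orthogonal sum/difference
   scaling 1/√2 (mode `"haar"`);
3. **complexification** — z = base + i·velocity (or the Hilbert analytic
   signal, mode `"hilbert"`);
4. **complex whitening + complex FastICA** — contrast G(|wᴴz|²), symmetric
   decorrelation; the objective is phase-blind, so each row of the complex
   demixing Φ is known only up to e^{iφ};
5. **phase resolution** — φ_j = ½·atan2(2·R·Iᵀ, I·Iᵀ − R·Rᵀ) (+ kπ/2), the
   variance-maximizing representative chosen analytically; then
   **W = C·ℜ(Φ) − S·ℑ(Φ)** with C = diag cos φ, S = diag sin φ.

The gap between the maximized real-branch variance and the minimized
imaginary-branch variance is reported as a per-component quality score.

The package also ships the evaluation stack used to benchmark such methods:
the scaled Amari index (range [0, 1], 0 = perfect separation up to
permutation/scale), random-demixing baselines, best/greedy correlation
matching of components to known sources, mutual information reduction
(Vasicek m-spacing entropies), a real FastICA baseline, and a
vector-autoregressive damped-oscillator simulation testbed, so every result
is reproducible without any data download.

## Worked example

Simulate ten damped-oscillator sources, mix them through a random
well-conditioned matrix with 1:1 generative noise, decompose, and score:

```r
library(pwcica)

sim   <- simulate_experiment(1, seed = 11)          # 10 x 50,000 at 200 Hz
truth <- source_noise(sim$sources, snr = 1, seed = 11)
A     <- random_mixing(10, 10, cond_max = 30, seed = 11)
x     <- signal_matrix(A %*% truth, srate = 200, epoch_length = 500)

dec <- pwc_ica(x, lag_h = 2, mode = "haar", seed = 11, max_iter = 150)
#> Warning: 10 component(s) did not converge within 150 iterations
amari_index(dec$W %*% A)
#> [1] 0.2424924
```

(The warning is expected: on near-Gaussian oscillator mixtures the
fixed-point search plateaus rather than converging; the 150-iteration cap is
the benchmark configuration and the result is flagged, not rejected.)

An Amari index of 0.24 means the product W·A is much closer to a generalized
permutation than a random demixing would be (the random baseline for
10-dimensional mixings averages ≈ 0.37); 0 would be perfect separation.
Components can be matched back to the known sources:

```r
m <- correlation_match(truth, dec$components)
count_matches(m, threshold = 0.7)
#> [1] 7
```

and the lag can be chosen from the band its difference filter emphasizes:

```r
lag_filter_response(8, 250)$peak_freq
#> [1] 15.625
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/pwcica simulate  --experiment 1 --seed 7 --out sim/
Rscript inst/cli/pwcica decompose --input sim/X.csv --srate 200 \
        --epoch-length 500 --lag 2 --mode haar --seed 7 --out out/
Rscript inst/cli/pwcica filter-response --lag 8 --srate 250
```

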