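#' Pairwise-complex ICA decomposition
#'
#' End-to-end driver: pairwise embedding at lag h, phase-space transform
#' (time-scaled `"v"` or orthogonal `"haar"`), complexification, complex
#' whitening, complex fixed-point ICA, analytic phase resolution, and assembly
#' of the real demixing matrix. Mode `"hilbert"` replaces the pairwise stages
#' with the analytic-signal comparator (no samples lost, `lag_h` ignored).
#'
#' @param signal A [signal_matrix()].
#' @param lag_h Pair lag h (samples); ignored in mode `"hilbert"`.
#' @param mode `"haar"`, `"v"`, or `"hilbert"`.
#' @param contrast,a,tol,max_iter,fun,saddle_test Passed to
#'   [complex_fastica()].
#' @param seed Integer seed controlling the ICA initialization; two runs with
#'   the same signal, configuration and seed return identical results.
#' @param n_components Number of components (default: all channels).
#' @return A `pwc_decomposition` (see [assemble_demixing()]) with full
#'   provenance (`lag_h`, `mode`, `dt`, `seed`, `contrast`, convergence
#'   flags, whitening diagnostics).
#' @examples
#' sim <- simulate_experiment(1, seed = 3)
#' x <- mix_and_noise(sim$sources[, 1:5000], random_mixing(10, 10, seed = 3),
#'                    snr = 1, seed = 3, srate = sim$srate, epoch_length = 500)
#' dec <- pwc_ica(x, lag_h = 2, mode = "haar", seed = 3)
#' @export
pwc_ica <- function(signal, lag_h = 1L, mode = c("haar", "v", "hilbert"),
                    contrast = "log", a = 0.1, tol = 1e-7, max_iter = 1000L,
                    fun = "symmetric", saddle_test = FALSE, seed = 1L,
                    n_components = NULL) {
  mode <- match.arg(mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pwc_ica stage [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }
  z <- if (mode == "hilbert") {
    stage("hilbert_complexify", hilbert_complexify(signal))
  } else {
    pairs <- stage("pairwise_embed", pairwise_embed(signal, lag_h))
    ps <- stage("phase_space_transform", phase_space_transform(pairs, mode))
    stage("complexify", complexify(ps))
  }
  wh <- stage("complex_whiten", complex_whiten(z))
  demix <- stage("complex_fastica",
                 complex_fastica(wh$z_white, n_components = n_components,
                                 contrast = contrast, a = a, fun = fun,
                                 max_iter = max_iter, tol = tol, seed = seed,
                                 saddle_test = saddle_test))
  demix <- fold_whitening(demix, wh$model)
  sol <- stage("critical_phases", critical_phases(demix, signal))
  dec <- stage("assemble_demixing", assemble_demixing(demix, sol, signal))
  dec$provenance <- list(
    lag_h = if (mode == "hilbert") NA_integer_ else as.integer(lag_h),
    mode = mode, dt = 1 / signal$srate, seed = seed, contrast = contrast,
    fun = fun, converged = demix$converged, n_iters = demix$n_iters,
    pseudo_cov_norm = wh$model$pseudo_cov_norm)
  dec
}

#' Frequency response of the lag-h difference filter
#'
#' The imaginary (velocity) half of the lag-h pairwise mapping convolves each
#' channel with the two-point difference filter `[1, 0, ..., 0, -1]` of length
#' h + 1. Its magnitude response is `|H(f)| = 2 |sin(pi f h / srate)|`; the
#' first local maximum sits at `srate / (2 h)` (or at Nyquist when h = 1),
#' which indicates the frequency band a given lag emphasizes.
#'
#' @param lag_h Positive integer lag h.
#' @param srate Sampling rate in Hz.
#' @param n_grid Number of grid points over `[0, srate/2]` (default 10001).
#' @return A list with `freq` (Hz grid), `magnitude` (`|H(f)|` on the grid)
#'   and `peak_freq`, the frequency of the first local maximum of the
#'   magnitude response.
#' @examples
#' lag_filter_response(8, 250)$peak_freq  # 15.625 Hz
#' @export
lag_filter_response <- function(lag_h, srate, n_grid = 10001L) {
  lag_h <- as.integer(lag_h)
  if (lag_h < 1L) stop("`lag_h` must be >= 1")
  if (srate <= 0) stop("`srate` must be positive")
  freq <- seq(0, srate / 2, length.out = n_grid)
  # H(f) = 1 - exp(-2 pi i f h / srate)  for the filter [1, 0...0, -1]
  mag <- Mod(1 - exp(-2i * pi * freq * lag_h / srate))
  peak <- NA_real_
  for (k in 2:(n_grid - 1L)) {
    if (mag[k] >= mag[k - 1L] && mag[k] > mag[k + 1L]) { peak <- freq[k]; break }
  }
  if (is.na(peak)) peak <- freq[n_grid]   # monotone: maximum at Nyquist
  list(freq = freq, magnitude = mag, peak_freq = peak)
}
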