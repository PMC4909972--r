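#' One repetition of the uncoupled-oscillator benchmark
#'
#' Runs the full comparison protocol on a fresh draw of the ten-oscillator
#' experiment: generate the sources (100 epochs x 500 samples at 200 Hz),
#' inject 1:1 generative noise into the sources ([source_noise()]), mix them
#' through a fresh well-conditioned random 10 x 10 matrix, run each requested
#' algorithm, and score the scaled Amari index of W A (plus, for the
#' correlation variants, the number of noisy sources matched by some
#' component at |r| >= 0.7).
#'
#' @param rep_seed Integer seed for this repetition (sources, noise, mixing
#'   and algorithm initialization all derive from it).
#' @param algorithms Character vector from `"pwc_haar2"`, `"fastica"`,
#'   `"hilbert"`, `"pwc_v1"`.
#' @param max_iter Iteration cap handed to every algorithm (the benchmark
#'   configuration caps at 150; see the methods vignette).
#' @param snr Generative signal-to-noise power ratio (default 1, the 1:1
#'   benchmark condition).
#' @return A list with `amari` (named numeric), `matched` (named integer,
#'   correlation variants only), and `n` (sources x samples of the problem).
#' @export
benchmark_experiment1_rep <- function(rep_seed,
                                      algorithms = c("pwc_haar2", "fastica",
                                                     "hilbert", "pwc_v1"),
                                      max_iter = 150L, snr = 1) {
  sim <- simulate_experiment(1, seed = rep_seed)
  truth <- source_noise(sim$sources, snr = snr, seed = rep_seed + 10000L)
  A <- random_mixing(10, 10, seed = rep_seed + 20000L)
  x <- signal_matrix(A %*% truth, srate = sim$srate,
                     epoch_length = sim$epoch_length)
  amari <- c()
  matched <- c()
  for (alg in algorithms) {
    if (alg == "fastica") {
      fit <- suppressWarnings(fastica_real(x, max_iter = max_iter,
                                           seed = rep_seed))
      W <- fit$W
      comps <- fit$components
    } else {
      cfg <- switch(alg,
                    pwc_haar2 = list(lag_h = 2L, mode = "haar"),
                    pwc_v1 = list(lag_h = 1L, mode = "v"),
                    hilbert = list(lag_h = 1L, mode = "hilbert"),
                    stop("unknown algorithm: ", alg))
      fit <- suppressWarnings(pwc_ica(x, lag_h = cfg$lag_h, mode = cfg$mode,
                                      max_iter = max_iter, seed = rep_seed))
      W <- fit$W
      comps <- fit$components
    }
    amari[alg] <- amari_index(W %*% A)
    if (alg %in% c("pwc_v1", "pwc_haar2")) {
      matched[alg] <- count_matches(correlation_match(truth, comps))
    }
  }
  list(amari = amari, matched = matched,
       n = c(sources = nrow(truth), samples = ncol(truth)))
}
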