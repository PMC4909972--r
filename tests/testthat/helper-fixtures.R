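# Small deterministic fixtures built in code.

# Random continuous signal.
rand_signal <- function(n = 3, N = 100, srate = 100, seed = 1,
                        epoch_length = NULL) {
  set.seed(seed)
  signal_matrix(matrix(rnorm(n * N), n), srate = srate,
                epoch_length = epoch_length)
}

# Independent circular non-Gaussian complex sources (uniform phase,
# exponential modulus) mixed by a random complex matrix.
circular_mixture <- function(n = 3, Tn = 10000, seed = 1) {
  set.seed(seed)
  S <- matrix(rexp(n * Tn) * exp(2i * pi * runif(n * Tn)), n)
  A <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  z <- structure(list(data = A %*% S, origin = "pwc", lag_h = 1L,
                      mode = "haar", dt = 0.01),
                 class = "complex_signal")
  list(S = S, A = A, z = z)
}

# Wrap a complex matrix as a complex_signal.
as_complex_signal <- function(Z) {
  structure(list(data = Z, origin = "pwc", lag_h = 1L, mode = "haar",
                 dt = 0.01),
            class = "complex_signal")
}

# Dense-grid oracle for the variance-maximizing phase of one component:
# variance over columns of cos(phi) R - sin(phi) I on a 10^4-point grid.
grid_phase_oracle <- function(R, I, n_grid = 1e4) {
  N <- length(R)
  phis <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  v <- vapply(phis, function(p) sum((cos(p) * R - sin(p) * I)^2) / N,
              numeric(1))
  list(phi = phis[which.max(v)], var = max(v), all = v, grid = phis)
}
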