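#' Default fundamental frequencies of the oscillator bank
#'
#' Ten distinct frequencies spanning the delta-through-beta EEG range, used
#' for the damped-oscillator sources of the simulation experiments.
#' @return Numeric vector of 10 frequencies in Hz.
#' @export
oscillator_frequencies <- function() c(3, 5, 7, 9, 11, 13, 15, 18, 21, 25)

# AR(2) diagonal terms of a damped oscillator with pole radius r and
# fundamental frequency f0 at sampling rate fs:
#   s_t = 2 r cos(2 pi f0 / fs) s_{t-1} - r^2 s_{t-2} + w_t
osc_coefs <- function(r, f0, fs) c(2 * r * cos(2 * pi * f0 / fs), -r^2)

# Spectral radius of the companion matrix of a VAR(p) with coefficient
# matrices in a list A (each m x m).
companion_radius <- function(A) {
  m <- nrow(A[[1]])
  p <- length(A)
  Cm <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) Cm[seq_len(m), ((k - 1) * m + 1):(k * m)] <- A[[k]]
  if (p > 1) Cm[(m + 1):(m * p), seq_len(m * (p - 1))] <- diag(m * (p - 1))
  max(Mod(eigen(Cm, only.values = TRUE)$values))
}

#' Simulate a vector-autoregressive source experiment
#'
#' Three source models, each producing 100 epochs of 500 samples at 200 Hz
#' (50,000 samples total), generated as independent epoch restarts with a
#' 1000-sample burn-in and unit-variance Gaussian innovations:
#'
#' * Experiment 1: ten uncoupled AR(2) damped harmonic oscillators with
#'   fundamental frequencies [oscillator_frequencies()] and pole radii drawn
#'   uniformly in `[0.95, 0.999]` per source.
#' * Experiment 2: five AR(2) sources (oscillators at 5, 8, 11, 15, 20 Hz)
#'   linked by constant first-order cross couplings on a directed ring
#'   (coefficient 0.05).
#' * Experiment 3: ten oscillators as in Experiment 1 arranged in two
#'   clusters of five, with static first-order couplings (0.02) inside each
#'   cluster and second-order cross-cluster couplings whose coefficients
#'   oscillate sinusoidally at per-edge frequencies drawn in `[0.1, 1]` Hz
#'   with amplitude 0.02.
#'
#' Coupled parameter draws are redrawn (up to 20 times) if the companion
#' spectral radius reaches 1 anywhere in the coupling cycle.
#'
#' @param which Experiment number: 1, 2, or 3.
#' @param seed Integer seed; fixes damping draws, coupling phases and
#'   innovations.
#' @param n_epochs,epoch_length,srate Epoch structure (defaults 100 x 500 at
#'   200 Hz).
#' @return A list with `sources` (m x n_samples matrix), `srate`,
#'   `epoch_length`, and `model` (coefficients, pole radii, frequencies,
#'   coupling schedule).
#' @export
simulate_experiment <- function(which, seed,
                                n_epochs = 100L, epoch_length = 500L,
                                srate = 200) {
  if (!which %in% 1:3) stop("`which` must be 1, 2, or 3")
  set.seed(as.integer(seed))
  burn <- 1000L
  switch(as.character(which),
    "1" = {
      f0 <- oscillator_frequencies()
      m <- length(f0)
      r <- stats::runif(m, 0.95, 0.999)
      S <- matrix(0, m, n_epochs * epoch_length)
      for (j in seq_len(m)) {
        cf <- osc_coefs(r[j], f0[j], srate)
        for (e in seq_len(n_epochs)) {
          w <- stats::rnorm(burn + epoch_length)
          s <- stats::filter(w, cf, method = "recursive")
          S[j, ((e - 1) * epoch_length + 1):(e * epoch_length)] <-
            s[(burn + 1):(burn + epoch_length)]
        }
      }
      list(sources = S, srate = srate, epoch_length = epoch_length,
           model = list(type = "uncoupled_ar2", r = r, f0 = f0, order = 2L))
    },
    "2" = {
      m <- 5L
      f0 <- c(5, 8, 11, 15, 20)
      A1c <- A2c <- NULL
      r <- NULL
      for (try in 1:20) {
        r <- stats::runif(m, 0.95, 0.999)
        A1c <- matrix(0, m, m)
        A2c <- matrix(0, m, m)
        for (j in seq_len(m)) {
          cf <- osc_coefs(r[j], f0[j], srate)
          A1c[j, j] <- cf[1]
          A2c[j, j] <- cf[2]
        }
        # static couplings: directed ring, first order
        for (j in seq_len(m)) A1c[j, (j %% m) + 1L] <- 0.05
        if (companion_radius(list(A1c, A2c)) < 1) break
        if (try == 20) stop("could not draw a stable coupled model")
      }
      S <- var_generate(list(A1c, A2c), n_epochs, epoch_length, burn)
      list(sources = S, srate = srate, epoch_length = epoch_length,
           model = list(type = "static_coupled_ar2", r = r, f0 = f0,
                        A = list(A1c, A2c), order = 2L))
    },
    "3" = {
      f0 <- oscillator_frequencies()
      m <- length(f0)
      amp <- 0.02
      ok <- FALSE
      for (try in 1:20) {
        r <- stats::runif(m, 0.95, 0.999)
        A1c <- matrix(0, m, m)
        A2c <- matrix(0, m, m)
        for (j in seq_len(m)) {
          cf <- osc_coefs(r[j], f0[j], srate)
          A1c[j, j] <- cf[1]
          A2c[j, j] <- cf[2]
        }
        # static first-order couplings inside each cluster of five
        for (cl in list(1:5, 6:10)) {
          for (j in seq_along(cl)) {
            A1c[cl[j], cl[(j %% 5) + 1L]] <- 0.02
          }
        }
        # dynamic second-order cross-cluster edges (5 edges, paired sources)
        edges <- cbind(1:5, 6:10)
        fc <- stats::runif(nrow(edges), 0.1, 1)
        phc <- stats::runif(nrow(edges), 0, 2 * pi)
        # stability screen over one full coupling cycle at the extremes
        worst <- 0
        for (a in seq(-amp, amp, length.out = 9)) {
          A2t <- A2c
          A2t[edges] <- A2t[edges] + a
          A2t[edges[, 2:1]] <- A2t[edges[, 2:1]] + a
          worst <- max(worst, companion_radius(list(A1c, A2t)))
        }
        if (worst < 1) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw a stable dynamic coupled model")
      coupling <- function(t) {   # t in samples (absolute, epoch-continuous)
        A2t <- A2c
        mod <- amp * sin(2 * pi * fc * t / srate + phc)
        A2t[edges] <- A2t[edges] + mod
        A2t[edges[, 2:1]] <- A2t[edges[, 2:1]] + mod
        A2t
      }
      S <- var_generate(list(A1c, NULL), n_epochs, epoch_length, burn,
                        A2_of_t = coupling)
      list(sources = S, srate = srate, epoch_length = epoch_length,
           model = list(type = "dynamic_coupled_ar2", r = r, f0 = f0,
                        A1 = A1c, A2_static = A2c, edges = edges,
                        coupling_freq = fc, coupling_phase = phc,
                        amplitude = amp, order = 2L))
    }
  )
}

# Generate an order-2 VAR trajectory, independent restart per epoch with
# burn-in. `A[[2]]` may be NULL if `A2_of_t(t)` supplies the (possibly
# time-varying) second-order matrix; t counts samples continuously across
# epochs so slow coupling cycles span the recording.
var_generate <- function(A, n_epochs, epoch_length, burn, A2_of_t = NULL) {
  m <- nrow(A[[1]])
  S <- matrix(0, m, n_epochs * epoch_length)
  A1 <- A[[1]]
  for (e in seq_len(n_epochs)) {
    s1 <- s2 <- numeric(m)
    for (k in seq_len(burn + epoch_length)) {
      t_abs <- (e - 1L) * epoch_length + max(k - burn, 0L)
      A2 <- if (is.null(A2_of_t)) A[[2]] else A2_of_t(t_abs)
      s <- A1 %*% s1 + A2 %*% s2 + stats::rnorm(m)
      s2 <- s1
      s1 <- as.numeric(s)
      if (k > burn) S[, (e - 1L) * epoch_length + (k - burn)] <- s1
    }
  }
  if (max(abs(S)) > 1e6) stop("generated trajectory is unbounded")
  S
}

#' Draw a random well-conditioned mixing matrix
#'
#' Entries are i.i.d. standard normal; the draw is repeated until the 2-norm
#' condition number is at most `cond_max`.
#'
#' @param n_channels,m_sources Output dimensions (`n_channels >= m_sources`).
#' @param cond_max Condition-number bound (default 30).
#' @param seed Integer seed.
#' @param max_tries Retry budget before giving up.
#' @return An `n_channels x m_sources` matrix of full column rank.
#' @export
random_mixing <- function(n_channels, m_sources, cond_max = 30, seed = 1L,
                          max_tries = 1000L) {
  if (n_channels < m_sources) stop("`n_channels` must be >= `m_sources`")
  set.seed(as.integer(seed))
  for (k in seq_len(max_tries)) {
    A <- matrix(stats::rnorm(n_channels * m_sources), n_channels, m_sources)
    sv <- svd(A, nu = 0, nv = 0)$d
    if (sv[length(sv)] > 0 && sv[1] / sv[length(sv)] <= cond_max) return(A)
  }
  stop("no mixing matrix with condition number <= ", cond_max, " after ",
       max_tries, " draws")
}

#' Add generative (source-level) noise
#'
#' Adds i.i.d. Gaussian noise to each source time course, scaled so the
#' per-source noise power equals (source power) / snr. In the benchmark
#' protocol the noisy sources are the ground truth and are mixed without
#' further sensor noise, keeping the linear ICA model exact; see the methods
#' vignette for the rationale.
#'
#' @param sources m x N source matrix.
#' @param snr Signal-to-noise power ratio per source (> 0); `Inf` returns the
#'   input unchanged.
#' @param seed Integer seed.
#' @return The noisy m x N source matrix.
#' @export
source_noise <- function(sources, snr = 1, seed = 1L) {
  if (!is.numeric(snr) || snr <= 0) stop("`snr` must be positive")
  if (!is.finite(snr)) return(sources)
  set.seed(as.integer(seed))
  pow <- rowMeans(sources^2)
  sources + matrix(stats::rnorm(length(sources)), nrow(sources)) *
    sqrt(pow / snr)
}

#' Mix sources and add channel noise
#'
#' Forms X = A S + e with e i.i.d. Gaussian per channel, scaled so that the
#' per-channel noise power equals (mixed signal power) / snr. `snr = 1` is
#' the 1:1 signal-to-noise condition of the simulation experiments;
#' `snr = Inf` disables noise.
#'
#' @param sources m x N source matrix.
#' @param A n x m mixing matrix.
#' @param snr Signal-to-noise power ratio (> 0).
#' @param seed Integer seed for the noise.
#' @param srate,epoch_length Carried into the returned [signal_matrix()].
#' @return A [signal_matrix()] of the noisy observations.
#' @export
mix_and_noise <- function(sources, A, snr = 1, seed = 1L, srate = 200,
                          epoch_length = NULL) {
  if (ncol(A) != nrow(sources)) stop("`A` and `sources` shapes do not conform")
  if (!is.numeric(snr) || snr <= 0) stop("`snr` must be positive")
  X <- A %*% sources
  if (is.finite(snr)) {
    set.seed(as.integer(seed))
    pow <- rowMeans(X^2)
    E <- matrix(stats::rnorm(nrow(X) * ncol(X)), nrow(X)) * sqrt(pow / snr)
    X <- X + E
  }
  signal_matrix(X, srate = srate, epoch_length = epoch_length)
}
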