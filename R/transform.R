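#' Pairwise (delay) embedding of a multichannel signal
#'
#' Forms the sequence of lagged observation pairs (x(t), x(t + h)), the delay
#' embedding underlying the pairwise-complex decomposition. Channel means are
#' removed here, once, over the whole recording. Within each epoch of length L
#' exactly L - h pairs are produced; no pair spans an epoch boundary.
#'
#' @param signal A [signal_matrix()].
#' @param lag_h Positive integer lag h between the two members of a pair.
#' @return An object of class `pwc_pairs` with fields `left` and `right`
#'   (n x T' matrices holding x(t) and x(t + h) column-wise), `lag_h`, `dt`
#'   (sampling interval in seconds), `epoch_sizes` (pairs contributed per
#'   epoch) and `n_channels`.
#' @examples
#' s <- signal_matrix(matrix(rnorm(50), nrow = 5), srate = 100)
#' p <- pairwise_embed(s, lag_h = 2)
#' ncol(p$left)  # 10 - 2 = 8 pairs
#' @export
pairwise_embed <- function(signal, lag_h = 1L) {
  stopifnot(inherits(signal, "signal_matrix"))
  lag_h <- as.integer(lag_h)
  if (length(lag_h) != 1L || is.na(lag_h) || lag_h < 1L) {
    stop("`lag_h` must be a positive integer")
  }
  L <- if (is.null(signal$epoch_length)) ncol(signal$data) else signal$epoch_length
  if (lag_h >= L) stop("lag exceeds epoch: lag_h = ", lag_h,
                       " but epochs have ", L, " samples")
  signal <- center_signal(signal)
  bounds <- epoch_bounds(signal)
  lefts <- vector("list", length(bounds))
  rights <- vector("list", length(bounds))
  for (e in seq_along(bounds)) {
    idx <- bounds[[e]]
    keep <- idx[seq_len(length(idx) - lag_h)]
    lefts[[e]] <- signal$data[, keep, drop = FALSE]
    rights[[e]] <- signal$data[, keep + lag_h, drop = FALSE]
  }
  n <- nrow(signal$data)
  Tp <- sum(vapply(lefts, ncol, integer(1)))
  if (Tp < n) stop("too few pairs (", Tp, ") for ", n, " channels")
  if (Tp < 10L * n) {
    warning("only ", Tp, " pairs for ", n,
            " channels; estimates may be unstable")
  }
  structure(
    list(left = do.call(cbind, lefts), right = do.call(cbind, rights),
         lag_h = lag_h, dt = 1 / signal$srate,
         epoch_sizes = vapply(lefts, ncol, integer(1)), n_channels = n),
    class = "pwc_pairs"
  )
}

#' Map observation pairs into the dynamic phase space
#'
#' Transforms each pair (x(t), x(t + h)) into a base/velocity pair. In mode
#' `"v"` the base is the two-point average (x(t) + x(t+h))/2 and the velocity
#' the time-scaled difference (x(t+h) - x(t))/(h dt): the physical signal and
#' its average rate of change on time scale h. In mode `"haar"` the orthogonal
#' sum/difference scaling 1/sqrt(2) is used for both halves and the sampling
#' interval is ignored.
#'
#' @param pairs A `pwc_pairs` object from [pairwise_embed()].
#' @param mode `"v"` (time-scaled) or `"haar"` (orthogonal).
#' @param dt Sampling interval in seconds; defaults to the interval recorded in
#'   `pairs`. Ignored in mode `"haar"`.
#' @return An object of class `phase_space` with `base` and `velocity`
#'   matrices of identical shape, plus `mode`, `lag_h` and `dt`.
#' @export
phase_space_transform <- function(pairs, mode = c("haar", "v"), dt = NULL) {
  stopifnot(inherits(pairs, "pwc_pairs"))
  mode <- match.arg(mode)
  if (ncol(pairs$left) == 0L) stop("`pairs` is empty")
  if (mode == "v") {
    if (is.null(dt)) dt <- pairs$dt
    if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
      stop("`dt` must be a positive scalar in mode \"v\"")
    }
    base <- (pairs$left + pairs$right) / 2
    velocity <- (pairs$right - pairs$left) / (pairs$lag_h * dt)
  } else {
    dt <- pairs$dt
    base <- (pairs$left + pairs$right) / sqrt(2)
    velocity <- (pairs$right - pairs$left) / sqrt(2)
  }
  structure(
    list(base = base, velocity = velocity, mode = mode,
         lag_h = pairs$lag_h, dt = dt, epoch_sizes = pairs$epoch_sizes),
    class = "phase_space"
  )
}

#' Complexify a phase space
#'
#' Associates each base/velocity pair with the complex vector
#' z = base + i velocity. The mapping is lossless: `Re(z)` and `Im(z)`
#' recover base and velocity exactly.
#'
#' @param phase_space A `phase_space` from [phase_space_transform()].
#' @return An object of class `complex_signal` with complex matrix `data`
#'   (n x T'), `origin = "pwc"`, and the `lag_h`, `mode`, `dt` of its
#'   phase space.
#' @export
complexify <- function(phase_space) {
  stopifnot(inherits(phase_space, "phase_space"))
  structure(
    list(data = phase_space$base + 1i * phase_space$velocity, origin = "pwc",
         lag_h = phase_space$lag_h, mode = phase_space$mode,
         dt = phase_space$dt),
    class = "complex_signal"
  )
}

#' Analytic-signal (Hilbert) complexification
#'
#' Comparator mapping: each (centered) channel becomes the real part of a
#' complex channel whose imaginary part is its Hilbert transform, i.e. the
#' analytic signal. Computed in the frequency domain independently per epoch,
#' so no samples are lost and no energy leaks across epoch boundaries.
#'
#' @param signal A [signal_matrix()].
#' @return A `complex_signal` with `origin = "hilbert"` and as many columns as
#'   the input has samples.
#' @export
hilbert_complexify <- function(signal) {
  stopifnot(inherits(signal, "signal_matrix"))
  signal <- center_signal(signal)
  out <- matrix(0i, nrow = nrow(signal$data), ncol = ncol(signal$data))
  for (idx in epoch_bounds(signal)) {
    seg <- signal$data[, idx, drop = FALSE]
    for (ch in seq_len(nrow(seg))) {
      out[ch, idx] <- analytic_signal(seg[ch, ])
    }
  }
  structure(
    list(data = out, origin = "hilbert", lag_h = NULL, mode = "hilbert",
         dt = 1 / signal$srate),
    class = "complex_signal"
  )
}

# Analytic signal of a real vector via the one-sided spectrum:
# double positive frequencies, zero negative ones, keep DC/Nyquist.
analytic_signal <- function(x) {
  N <- length(x)
  X <- stats::fft(x)
  w <- numeric(N)
  if (N %% 2 == 0) {
    w[1] <- 1; w[N / 2 + 1] <- 1
    if (N > 2) w[2:(N / 2)] <- 2
  } else {
    w[1] <- 1
    if (N > 1) w[2:((N + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / N
}
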