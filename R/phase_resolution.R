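#' Resolve the per-component phase ambiguity
#'
#' A complex demixing row is identified only up to a unit-modulus scalar
#' e^{i phi}. For each row j this chooses the phase whose real part
#' cos(phi) R_j - sin(phi) I_j has maximal variance over the full-length
#' centered real signal, where R_j and I_j are the row time courses of the
#' real and imaginary parts of the complex demixing applied to the signal.
#' The critical phase has the closed form
#' phi = (1/2) atan2(2 R I^T, I I^T - R R^T) (+ k pi/2); the variance is
#' evaluated at the two critical values in a half-period and the maximizer is
#' selected. The same phase simultaneously minimizes the variance of the
#' orthogonal (imaginary-part) counterpart, and the gap between the two
#' variances is a per-component quality heuristic.
#'
#' @param phi A `complex_demixing` with the whitening folded in
#'   ([fold_whitening()]), so that `phi$phi` acts on raw complex channels
#'   matching the rows of `signal`.
#' @param signal The original [signal_matrix()] (it is centered internally).
#' @return A `phase_solution`: `phases` (in `[0, pi)`), `var_max`, `var_min`,
#'   `quality = var_max - var_min`, all per component.
#' @export
critical_phases <- function(phi, signal) {
  stopifnot(inherits(phi, "complex_demixing"))
  if (is.null(phi$phi)) stop("whitening not folded in; see fold_whitening()")
  stopifnot(inherits(signal, "signal_matrix"))
  X <- center_signal(signal)$data
  if (ncol(phi$phi) != nrow(X)) {
    stop("demixing has ", ncol(phi$phi), " columns but the signal has ",
         nrow(X), " channels")
  }
  R <- Re(phi$phi) %*% X
  I <- Im(phi$phi) %*% X
  N <- ncol(X)
  m <- nrow(R)
  phases <- var_max <- var_min <- numeric(m)
  for (j in seq_len(m)) {
    rr <- sum(R[j, ]^2)
    ii <- sum(I[j, ]^2)
    ri <- sum(R[j, ] * I[j, ])
    if (rr == 0 && ii == 0) {
      warning("component ", j, " has zero variance; phase set to 0")
      next
    }
    ph0 <- 0.5 * atan2(2 * ri, ii - rr)
    cand <- c(ph0, ph0 + pi / 2)
    v <- vapply(cand, function(p) {
      (cos(p)^2 * rr + sin(p)^2 * ii - sin(2 * p) * ri) / N
    }, numeric(1))
    sel <- if (abs(v[1] - v[2]) < 1e-12) {
      # tie (circular component): prefer the representative in [0, pi/2)
      cm <- cand %% pi
      if (any(cm < pi / 2)) which(cm < pi / 2)[1] else 1L
    } else which.max(v)
    phases[j] <- cand[sel] %% pi
    var_max[j] <- v[sel]
    var_min[j] <- v[3L - sel]
  }
  structure(
    list(phases = phases, var_max = var_max, var_min = var_min,
         quality = var_max - var_min),
    class = "phase_solution"
  )
}

#' Per-component quality-of-fit heuristic
#'
#' The gap between the variance captured by the selected (real-part) phase and
#' the variance of its orthogonal counterpart. Components whose complex time
#' course is far from circular score high; circular components score near 0.
#'
#' @param phases A `phase_solution` from [critical_phases()].
#' @return Nonnegative numeric vector of per-component scores.
#' @export
quality_heuristic <- function(phases) {
  stopifnot(inherits(phases, "phase_solution"))
  phases$quality
}

#' Assemble the real demixing matrix
#'
#' Builds W = C Re(Phi) - S Im(Phi), where C and S are diagonal matrices of
#' cos(phi_j) and sin(phi_j) at the selected critical phases, applies it to
#' the full centered signal, and computes the mixing estimate as the
#' Moore-Penrose pseudoinverse of W. Rows are sign-flipped so the
#' largest-magnitude entry of each row is positive, and ordered by descending
#' quality score (the original complex-ICA order is kept in `order`).
#'
#' @param phi A `complex_demixing` with whitening folded in.
#' @param phases The `phase_solution` computed from the same `phi` and signal.
#' @param signal The original [signal_matrix()].
#' @return A `pwc_decomposition`: `W` (m x n_channels), `A_est`
#'   (pseudoinverse of `W`), `components` (m x n_samples, W applied to the
#'   centered signal), `phase_solution`, `order`, `provenance`.
#' @export
assemble_demixing <- function(phi, phases, signal) {
  stopifnot(inherits(phi, "complex_demixing"),
            inherits(phases, "phase_solution"),
            inherits(signal, "signal_matrix"))
  C <- cos(phases$phases)
  S <- sin(phases$phases)
  W <- C * Re(phi$phi) - S * Im(phi$phi)
  # deterministic sign: largest-|entry| of each row made positive
  for (j in seq_len(nrow(W))) {
    k <- which.max(abs(W[j, ]))
    if (W[j, k] < 0) W[j, ] <- -W[j, ]
  }
  ord <- order(phases$quality, decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  sol <- phases
  sol$phases <- sol$phases[ord]
  sol$var_max <- sol$var_max[ord]
  sol$var_min <- sol$var_min[ord]
  sol$quality <- sol$quality[ord]
  Xc <- center_signal(signal)$data
  comps <- W %*% Xc
  sv <- svd(W, nu = 0, nv = 0)$d
  if (sv[length(sv)] < 1e-12 * sv[1]) {
    warning("assembled demixing matrix is close to singular")
  }
  A_est <- MASS::ginv(W)
  structure(
    list(W = W, A_est = A_est, components = comps, phase_solution = sol,
         order = ord,
         provenance = list(lag_h = phi$lag_h, mode = phi$mode,
                           contrast = phi$contrast_name, seed = phi$seed,
                           converged = phi$converged, n_iters = phi$n_iters)),
    class = "pwc_decomposition"
  )
}

#' @export
print.pwc_decomposition <- function(x, ...) {
  cat("<pwc_decomposition> ", nrow(x$W), " components x ", ncol(x$W),
      " channels\n", sep = "")
  cat("  quality (var_max - var_min): ",
      paste(signif(x$phase_solution$quality, 3), collapse = " "), "\n")
  invisible(x)
}
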