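#' Real-valued FastICA baseline
#'
#' Standard real fixed-point ICA (symmetric decorrelation) used as the
#' reference algorithm in the simulation comparisons. Data are centered and
#' whitened internally; the returned demixing matrix acts on the raw
#' channels.
#'
#' @param signal A [signal_matrix()] or a plain channels-by-samples matrix.
#' @param n_components Number of components (default: all channels).
#' @param contrast `"tanh"` (default) or `"cube"` (kurtosis-style).
#' @param alpha Gain of the `"tanh"` nonlinearity.
#' @param max_iter,tol Iteration cap and tolerance on the direction change
#'   1 - min_j |<w_j^(k+1), w_j^(k)>|.
#' @param seed Integer seed for the random orthonormal initialization.
#' @return A list with `W` (n_components x n_channels demixing, whitening
#'   folded in), `components`, `n_iters`, `converged`.
#' @export
fastica_real <- function(signal, n_components = NULL,
                         contrast = c("tanh", "cube"), alpha = 1,
                         max_iter = 1000L, tol = 1e-7, seed = 1L) {
  contrast <- match.arg(contrast)
  X <- if (inherits(signal, "signal_matrix")) signal$data else signal
  X <- X - rowMeans(X)
  n <- nrow(X)
  Tn <- ncol(X)
  if (is.null(n_components)) n_components <- n
  if (n_components > n) stop("n_components exceeds the number of channels")
  C <- tcrossprod(X) / Tn
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (any(eg$values <= 1e-12 * max(eg$values))) {
    stop("signal covariance is rank deficient")
  }
  S <- eg$vectors %*% ((1 / sqrt(eg$values)) * t(eg$vectors))
  Z <- S %*% X

  g <- switch(contrast,
              tanh = function(u) tanh(alpha * u),
              cube = function(u) u^3)
  dg <- switch(contrast,
               tanh = function(u) alpha * (1 - tanh(alpha * u)^2),
               cube = function(u) 3 * u^2)

  sym_decor <- function(W) {
    eg <- eigen(tcrossprod(W), symmetric = TRUE)
    (eg$vectors %*% ((1 / sqrt(pmax(eg$values, .Machine$double.eps))) *
                       t(eg$vectors))) %*% W
  }

  set.seed(as.integer(seed))
  W <- sym_decor(matrix(stats::rnorm(n_components * n), n_components))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Y <- W %*% Z
    GY <- g(Y)
    Wn <- tcrossprod(GY, Z) / Tn - rowMeans(dg(Y)) * W
    Wn <- sym_decor(Wn)
    dirchg <- 1 - min(abs(rowSums(Wn * W)))
    W <- Wn
    if (dirchg < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("fastica_real did not converge in ", max_iter,
                          " iterations")
  Wfull <- W %*% S
  list(W = Wfull, components = Wfull %*% X, n_iters = iter,
       converged = converged)
}
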