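#' Whiten a complex signal
#'
#' Removes the complex mean and applies the inverse principal square root of
#' the Hermitian covariance E[z z^H], so that the whitened data satisfies
#' (1/T) Z Z^H = I. This is the required preprocessing for the complex
#' fixed-point ICA, whose source model assumes unit-variance uncorrelated
#' components. No dimensionality reduction is performed; a rank-deficient
#' covariance is an error.
#'
#' @param z A `complex_signal` (see [complexify()], [hilbert_complexify()]).
#' @param tol Relative eigenvalue threshold below which a dimension is
#'   declared deficient.
#' @return A list with `z_white` (the whitened `complex_signal`) and `model`,
#'   a `whitening_model` holding `matrix_S` (the applied transform), `mean`,
#'   `eigenvalues`, and `pseudo_cov_norm` (Frobenius norm of the empirical
#'   pseudo-covariance E[z z^T], a circularity diagnostic).
#' @export
complex_whiten <- function(z, tol = 1e-12) {
  stopifnot(inherits(z, "complex_signal"))
  Z <- z$data
  n <- nrow(Z)
  Tn <- ncol(Z)
  if (Tn < n) stop("fewer samples (", Tn, ") than channels (", n, ")")
  mu <- rowMeans(Z)
  Zc <- Z - mu
  C <- tcrossprod(Zc, Conj(Zc)) / Tn          # Hermitian covariance E[zz^H]
  C <- (C + Conj(t(C))) / 2
  eg <- eigen(C, symmetric = TRUE)
  ev <- eg$values
  bad <- sum(ev <= tol * max(ev))
  if (bad > 0L) {
    stop("covariance is rank deficient: ", bad, " of ", n,
         " dimensions are degenerate")
  }
  S <- eg$vectors %*% ((1 / sqrt(ev)) * Conj(t(eg$vectors)))
  Zw <- S %*% Zc
  pseudo <- tcrossprod(Zc, Zc) / Tn           # E[zz^T], zero for circular data
  zw <- z
  zw$data <- Zw
  model <- structure(
    list(matrix_S = S, mean = mu, eigenvalues = ev,
         pseudo_cov_norm = sqrt(sum(Mod(pseudo)^2))),
    class = "whitening_model"
  )
  list(z_white = zw, model = model)
}

# Contrast families G(u), g = G', g' for the complex fixed-point update,
# evaluated at u = |w^H z|^2. "log" is G(u) = log(a + u).
contrast_funs <- function(contrast = c("log", "sqrt", "square"), a = 0.1) {
  contrast <- match.arg(contrast)
  switch(contrast,
    log = list(G = function(u) log(a + u),
               g = function(u) 1 / (a + u),
               dg = function(u) -1 / (a + u)^2),
    sqrt = list(G = function(u) sqrt(a + u),
                g = function(u) 0.5 / sqrt(a + u),
                dg = function(u) -0.25 / (a + u)^1.5),
    square = list(G = function(u) u^2,
                  g = function(u) u,
                  dg = function(u) rep(1, length(u)))
  )
}

# Inverse principal square root of a Hermitian matrix.
herm_inv_sqrt <- function(M) {
  M <- (M + Conj(t(M))) / 2
  eg <- eigen(M, symmetric = TRUE)
  eg$vectors %*% ((1 / sqrt(pmax(eg$values, .Machine$double.eps))) *
                    Conj(t(eg$vectors)))
}

#' Complex fixed-point ICA
#'
#' Estimates a complex demixing matrix for whitened, (approximately) circular
#' complex data by the fixed-point iteration of the complex FastICA family.
#' The contrast is a smooth function G of the squared modulus of the
#' projections, so the objective is invariant to per-component phase shifts;
#' the returned rows are therefore identified only up to a unit-modulus
#' scalar (resolved downstream by [critical_phases()]).
#'
#' @param z_white A whitened `complex_signal` (from [complex_whiten()]).
#' @param n_components Number of components to extract (default: all).
#' @param contrast One of `"log"` (default, G(u) = log(a + u)), `"sqrt"`,
#'   `"square"`.
#' @param a Stabilizing constant of the `"log"`/`"sqrt"` contrasts.
#' @param fun Estimation scheme: `"symmetric"` (parallel update plus symmetric
#'   decorrelation, default) or `"deflation"`.
#' @param max_iter,tol Iteration cap and convergence tolerance on
#'   1 - min_j |<w_j^(k+1), w_j^(k)>| (phase-blind direction change).
#' @param seed Integer seed for the random orthonormal initialization.
#' @param w_init Optional complex matrix (n_components x n) of initial rows;
#'   overrides `seed`-based initialization.
#' @param saddle_test If `TRUE`, after convergence every component pair is
#'   tested for a pi/4 rotation in its 2-plane that increases the contrast,
#'   and the rotation is kept when it does.
#' @return A `complex_demixing` object: `phi_white` (rows orthonormal under
#'   the Hermitian inner product, acting on whitened data), `n_iters`,
#'   `converged` (per run / per component for deflation), `contrast_name`,
#'   `seed`. Fold in a whitening model with [fold_whitening()].
#' @references Bingham & Hyvarinen (2000); Koldovsky & Tichavsky's
#'   saddle-point refinement.
#' @export
complex_fastica <- function(z_white, n_components = NULL,
                            contrast = "log", a = 0.1,
                            fun = c("symmetric", "deflation"),
                            max_iter = 1000L, tol = 1e-7, seed = 1L,
                            w_init = NULL, saddle_test = FALSE) {
  stopifnot(inherits(z_white, "complex_signal"))
  fun <- match.arg(fun)
  Z <- z_white$data
  n <- nrow(Z)
  Tn <- ncol(Z)
  if (is.null(n_components)) n_components <- n
  if (n_components > n) stop("n_components (", n_components,
                             ") exceeds the number of channels (", n, ")")
  cf <- contrast_funs(contrast, a)

  if (is.null(w_init)) {
    set.seed(as.integer(seed))
    w_init <- matrix(complex(real = stats::rnorm(n_components * n),
                             imaginary = stats::rnorm(n_components * n)),
                     nrow = n_components)
  } else {
    if (!is.matrix(w_init) || nrow(w_init) != n_components ||
        ncol(w_init) != n) stop("`w_init` must be ", n_components, " x ", n)
    w_init <- w_init * (1 + 0i)
  }

  # One fixed-point update of all rows of W (m x n, rows act as w^H on Z).
  # Column convention: w+ = E[z (w^H z)^* g] - E[g + |y|^2 g'] w; rows store
  # w^H, so the data term becomes E[y g z^H], one zgemm for all rows.
  ZH <- Conj(t(Z))
  update_rows <- function(W) {
    Y <- W %*% Z                       # m x T projections w_j^H z
    U <- Mod(Y)^2
    Gu <- cf$g(U)
    beta <- rowMeans(Gu + U * cf$dg(U))
    ((Y * Gu) %*% ZH) / Tn - beta * W
  }

  if (fun == "symmetric") {
    W <- herm_inv_sqrt(tcrossprod(w_init, Conj(w_init))) %*% w_init
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      Wn <- update_rows(W)
      Wn <- herm_inv_sqrt(tcrossprod(Wn, Conj(Wn))) %*% Wn
      dirchg <- 1 - min(Mod(rowSums(Wn * Conj(W))))
      W <- Wn
      if (dirchg < tol) { converged <- TRUE; break }
    }
    n_iters <- iter
    conv <- rep(converged, n_components)
  } else {
    W <- matrix(0i, n_components, n)
    n_iters <- integer(n_components)
    conv <- logical(n_components)
    for (j in seq_len(n_components)) {
      w <- w_init[j, , drop = FALSE]
      if (j > 1L) {
        P <- Conj(t(W[seq_len(j - 1L), , drop = FALSE])) %*%
          W[seq_len(j - 1L), , drop = FALSE]
        w <- w - w %*% P
      }
      w <- w / sqrt(Re(sum(w * Conj(w))))
      for (it in seq_len(max_iter)) {
        wn <- update_rows(w)
        if (j > 1L) wn <- wn - wn %*% P
        wn <- wn / sqrt(Re(sum(wn * Conj(wn))))
        chg <- 1 - Mod(sum(wn * Conj(w)))
        w <- wn
        n_iters[j] <- it
        if (chg < tol) { conv[j] <- TRUE; break }
      }
      W[j, ] <- w
    }
  }

  if (saddle_test && n_components > 1L) {
    W <- saddle_point_pass(W, Z, cf)
  }

  if (any(!conv)) {
    warning(sum(!conv), " component(s) did not converge within ",
            max_iter, " iterations")
  }

  structure(
    list(phi_white = W, phi = NULL, whitening = NULL,
         n_iters = n_iters, converged = conv,
         contrast_name = contrast, seed = seed, fun = fun),
    class = "complex_demixing"
  )
}

# Pairwise pi/4-rotation check. The per-component criterion is the squared
# deviation of the empirical contrast mean from its value under a circular
# complex Gaussian (|y|^2 ~ Exp(1)); a mixture of two sources sits at a
# saddle where this deviation drops, so if the rotated pair scores higher
# the rotation is kept.
saddle_point_pass <- function(W, Z, cf) {
  m <- nrow(W)
  e0 <- stats::integrate(function(u) cf$G(u) * exp(-u), 0, Inf,
                         rel.tol = 1e-10)$value
  score <- function(w) (mean(cf$G(Mod(w %*% Z)^2)) - e0)^2
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      s0 <- score(W[i, , drop = FALSE]) + score(W[j, , drop = FALSE])
      r1 <- (W[i, ] + W[j, ]) / sqrt(2)
      r2 <- (W[i, ] - W[j, ]) / sqrt(2)
      s1 <- score(matrix(r1, 1)) + score(matrix(r2, 1))
      if (s1 > s0 + 1e-10) {
        W[i, ] <- r1
        W[j, ] <- r2
      }
    }
  }
  W
}

#' Fold a whitening transform into a complex demixing
#'
#' Combines the demixing estimated on whitened data with the whitening matrix
#' so that `phi` acts directly on raw (mean-centered) complex signals.
#'
#' @param demix A `complex_demixing` from [complex_fastica()].
#' @param model A `whitening_model` from [complex_whiten()].
#' @return The `complex_demixing` with `phi = phi_white %*% matrix_S` filled
#'   in and the model attached.
#' @export
fold_whitening <- function(demix, model) {
  stopifnot(inherits(demix, "complex_demixing"),
            inherits(model, "whitening_model"))
  demix$phi <- demix$phi_white %*% model$matrix_S
  demix$whitening <- model
  demix
}
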