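#' Scaled Amari index
#'
#' Permutation- and scale-invariant measure of how far a square matrix P
#' (typically the product of a demixing and a mixing matrix) is from a
#' generalized permutation matrix:
#' \deqn{\frac{1}{2n(n-1)}\Big[\sum_i\big(\sum_j \frac{|P_{ij}|}{\max_k |P_{ik}|} - 1\big)
#'   + \sum_j\big(\sum_i \frac{|P_{ij}|}{\max_k |P_{kj}|} - 1\big)\Big]}
#' The 1/(2n(n-1)) scaling puts the index in [0, 1] for every dimension:
#' 0 exactly when P is a permutation of a diagonal matrix, 1 when all entries
#' are equal.
#'
#' @param P Square numeric matrix, n >= 2, no all-zero row or column.
#' @return The index, a scalar in [0, 1].
#' @examples
#' amari_index(diag(3))                  # 0
#' amari_index(matrix(1, 4, 4))          # 1
#' @export
amari_index <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop("`P` must be square")
  n <- nrow(P)
  if (n < 2L) stop("`P` must be at least 2 x 2")
  Q <- abs(P)
  rmax <- apply(Q, 1, max)
  cmax <- apply(Q, 2, max)
  if (any(rmax == 0) || any(cmax == 0)) {
    stop("`P` has an all-zero row or column")
  }
  (sum(rowSums(Q / rmax) - 1) + sum(colSums(t(t(Q) / cmax)) - 1)) /
    (2 * n * (n - 1))
}

#' Random-demixing Amari baseline
#'
#' Expected Amari index when the demixing matrix is chosen at random: for
#' each mixing matrix, i.i.d. standard-normal demixing matrices are drawn
#' (redrawn when numerically singular) and the index of each product W A is
#' computed.
#'
#' @param A_list List of square nonsingular mixing matrices.
#' @param draws_per_A Random demixing draws per mixing matrix (default 1000).
#' @param seed Integer seed.
#' @return A list with `mean`, `sd`, and `values` (all indices pooled).
#' @export
random_baseline_amari <- function(A_list, draws_per_A = 1000L, seed = 1L) {
  stopifnot(is.list(A_list), length(A_list) >= 1L, draws_per_A >= 1L)
  set.seed(as.integer(seed))
  vals <- numeric(0)
  for (A in A_list) {
    n <- nrow(A)
    v <- numeric(draws_per_A)
    for (k in seq_len(draws_per_A)) {
      repeat {
        W <- matrix(stats::rnorm(n * n), n, n)
        if (abs(det(W)) > 1e-12) break
      }
      v[k] <- amari_index(W %*% A)
    }
    vals <- c(vals, v)
  }
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

#' Match estimated components to true sources by correlation
#'
#' Non-greedy: for each source, the component with the highest absolute
#' Pearson correlation (a component may serve several sources). Greedy: the
#' globally best |r| pair is fixed and both series removed, repeated until
#' every source is matched, giving a one-to-one assignment. Ties within
#' 1e-12 resolve to the lowest source index, then lowest component index.
#'
#' @param S_true m x N matrix of true source time courses.
#' @param S_comp k x N matrix of component time courses (k >= m for greedy).
#' @param greedy Use the one-to-one greedy assignment? Default `FALSE`.
#' @return A data frame with columns `source`, `component`, `r` (absolute
#'   correlation), one row per source.
#' @export
correlation_match <- function(S_true, S_comp, greedy = FALSE) {
  if (ncol(S_true) != ncol(S_comp)) {
    N <- min(ncol(S_true), ncol(S_comp))
    S_true <- S_true[, seq_len(N), drop = FALSE]
    S_comp <- S_comp[, seq_len(N), drop = FALSE]
  }
  m <- nrow(S_true)
  k <- nrow(S_comp)
  sd_t <- apply(S_true, 1, stats::sd)
  sd_c <- apply(S_comp, 1, stats::sd)
  if (any(sd_t == 0) || any(sd_c == 0)) {
    warning("zero-variance series; their correlations are set to 0")
  }
  R <- matrix(0, m, k)
  ok_t <- sd_t > 0
  ok_c <- sd_c > 0
  if (any(ok_t) && any(ok_c)) {
    R[ok_t, ok_c] <- abs(stats::cor(t(S_true[ok_t, , drop = FALSE]),
                                    t(S_comp[ok_c, , drop = FALSE])))
  }
  if (!greedy) {
    comp <- apply(R, 1, which.max)
    return(data.frame(source = seq_len(m), component = comp,
                      r = R[cbind(seq_len(m), comp)]))
  }
  if (k < m) stop("greedy matching needs at least as many components as sources")
  src_left <- rep(TRUE, m)
  cmp_left <- rep(TRUE, k)
  out <- data.frame(source = integer(m), component = integer(m),
                    r = numeric(m))
  for (step in seq_len(m)) {
    sub <- R
    sub[!src_left, ] <- -Inf
    sub[, !cmp_left] <- -Inf
    best <- max(sub)
    hits <- which(sub >= best - 1e-12, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    out[step, ] <- list(i, j, R[i, j])
    src_left[i] <- FALSE
    cmp_left[j] <- FALSE
  }
  out[order(out$source), , drop = FALSE]
}

#' Count sources matched above a correlation threshold
#'
#' @param matches Data frame from [correlation_match()].
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @return Integer count of sources with `r >= threshold`.
#' @export
count_matches <- function(matches, threshold = 0.7) {
  sum(matches$r >= threshold)
}

# Vasicek m-spacing estimator of differential entropy (nats),
# m = ceiling(sqrt(T)); spacings beyond the sample range are clamped.
entropy_vasicek <- function(x) {
  n <- length(x)
  m <- ceiling(sqrt(n))
  xs <- sort(x)
  hi <- xs[pmin(seq_len(n) + m, n)]
  lo <- xs[pmax(seq_len(n) - m, 1L)]
  d <- hi - lo
  d[d <= 0] <- .Machine$double.eps
  mean(log(n / (2 * m) * d))
}

# Histogram (plug-in) entropy estimator, Freedman-Diaconis-ish binning.
entropy_hist <- function(x, bins = ceiling(sqrt(length(x)))) {
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  w <- diff(h$breaks)
  keep <- p > 0
  -sum(p[keep] * log(p[keep] / w[keep]))
}

#' Mutual information reduction of a linear transform
#'
#' The drop in total mutual information achieved by applying W to a
#' multichannel signal: \eqn{MIR(W) = \sum_i h(x_i) - \sum_i h((Wx)_i) +
#' \log|\det W|}, with h a one-dimensional differential-entropy estimator.
#' Positive values mean the transformed channels are more independent.
#' Units are nats.
#'
#' @param X n x N numeric matrix (or a [signal_matrix()]).
#' @param W Square full-rank n x n matrix.
#' @param estimator `"vasicek"` (m-spacing, default) or `"hist"`.
#' @return MIR in nats.
#' @export
mutual_information_reduction <- function(X, W, estimator = c("vasicek", "hist")) {
  estimator <- match.arg(estimator)
  if (inherits(X, "signal_matrix")) X <- X$data
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("`W` must be square")
  dW <- det(W)
  if (abs(dW) < 1e-12) stop("`W` is singular")
  ent <- if (estimator == "vasicek") entropy_vasicek else entropy_hist
  Y <- W %*% X
  sum(apply(X, 1, ent)) - sum(apply(Y, 1, ent)) + log(abs(dW))
}

#' Compare two paired Amari-index samples
#'
#' Paired t-test on per-repetition differences (each repetition shares its
#' mixing matrix and sources across algorithms), as used to declare one
#' algorithm's Amari distribution significantly lower than another's.
#'
#' @param x,y Equal-length numeric vectors of Amari indices, paired by
#'   repetition.
#' @param alternative Passed to [stats::t.test()]; `"less"` tests whether
#'   `x` is significantly lower than `y`.
#' @return The `htest` object.
#' @export
compare_amari <- function(x, y, alternative = "less") {
  stats::t.test(x, y, paired = TRUE, alternative = alternative)
}
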