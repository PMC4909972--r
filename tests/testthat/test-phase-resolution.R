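# Phase resolution is exercised through small synthetic complex demixings
# wrapped as complex_demixing objects with the whitening already folded in.
fake_phi <- function(M) {
  structure(list(phi = M, phi_white = M, n_iters = 0L,
                 converged = TRUE, contrast_name = "log", seed = 0L),
            class = "complex_demixing")
}

test_that("an already-real component gets phase 0 mod pi and zero var_min", {
  set.seed(21)
  sig <- rand_signal(n = 2, N = 500, seed = 21)
  M <- matrix(c(1 + 0i, 2 + 0i, -1 + 0i, 0.5 + 0i), 2, byrow = TRUE)
  sol <- critical_phases(fake_phi(M), sig)
  expect_true(all(pmin(sol$phases, pi - sol$phases) < 1e-10))
  expect_equal(sol$var_min, c(0, 0), tolerance = 1e-12)
  dec <- assemble_demixing(fake_phi(M), sol, sig)
  # W rows equal +/- the real part, up to quality ordering
  expect_equal(abs(dec$W[order(dec$order), ]), abs(Re(M)), tolerance = 1e-10)
})

test_that("identical real and imaginary time courses give the pi/4 family", {
  sig <- rand_signal(n = 1, N = 1000, seed = 22)
  M <- matrix(1 + 1i, 1, 1)    # R and I both equal the (centered) channel
  sol <- critical_phases(fake_phi(M), sig)
  xc <- sig$data - rowMeans(sig$data)
  vs <- sum(xc^2) / ncol(xc)
  # var((cos - sin) phi applied) = (1 - sin 2 phi) var(s): max 2 var(s) at 3pi/4
  expect_equal(sol$var_max, 2 * vs, tolerance = 1e-10)
  expect_equal(sol$var_min, 0, tolerance = 1e-10)
  expect_equal(sol$phases %% (pi / 2), pi / 4, tolerance = 1e-10)
})

test_that("the analytic phase matches a dense grid search on random instances", {
  set.seed(23)
  for (k in 1:100) {
    n <- sample(2:4, 1)
    sig <- rand_signal(n = n, N = 200, seed = 1000 + k)
    M <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
    sol <- critical_phases(fake_phi(M), sig)
    xc <- sig$data - rowMeans(sig$data)
    R <- Re(M) %*% xc
    I <- Im(M) %*% xc
    for (j in 1:n) {
      or <- grid_phase_oracle(R[j, ], I[j, ])
      expect_gte(sol$var_max[j], or$var - 1e-10)
      # selected phase within grid resolution of the grid argmax (mod pi)
      dphi <- abs(sol$phases[j] - (or$phi %% pi))
      expect_lt(min(dphi, pi - dphi), 2 * pi / 1e4 + 1e-12)
    }
  }
})

test_that("the variance-max phase minimizes the imaginary-branch variance", {
  set.seed(24)
  for (k in 1:20) {
    sig <- rand_signal(n = 3, N = 300, seed = 2000 + k)
    M <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3)
    sol <- critical_phases(fake_phi(M), sig)
    xc <- sig$data - rowMeans(sig$data)
    R <- Re(M) %*% xc
    I <- Im(M) %*% xc
    for (j in 1:3) {
      p <- sol$phases[j]
      v_imag <- sum((sin(p) * R[j, ] + cos(p) * I[j, ])^2) / ncol(xc)
      expect_equal(v_imag, sol$var_min[j], tolerance = 1e-10)
    }
  }
})

test_that("phases are pi-periodic: both representatives flip only the sign", {
  sig <- rand_signal(n = 2, N = 400, seed = 25)
  M <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2)
  sol <- critical_phases(fake_phi(M), sig)
  sol2 <- sol
  sol2$phases <- sol$phases + pi
  d1 <- assemble_demixing(fake_phi(M), sol, sig)
  d2 <- assemble_demixing(fake_phi(M), sol2, sig)
  # the deterministic row-sign convention makes both identical
  expect_equal(d1$W, d2$W, tolerance = 1e-12)
  expect_equal(d1$components, d2$components, tolerance = 1e-12)
})

test_that("scaling the signal scales variances by c^2 and keeps phases", {
  sig <- rand_signal(n = 2, N = 300, seed = 26)
  M <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2)
  sol1 <- critical_phases(fake_phi(M), sig)
  sig3 <- sig
  sig3$data <- 3 * sig$data
  sol3 <- critical_phases(fake_phi(M), sig3)
  expect_equal(sol3$phases, sol1$phases, tolerance = 1e-10)
  expect_equal(sol3$var_max, 9 * sol1$var_max, tolerance = 1e-9)
  expect_equal(sol3$var_min, 9 * sol1$var_min, tolerance = 1e-9)
})

test_that("quality heuristic is nonnegative and near zero for circular rows", {
  set.seed(27)
  N <- 1e5
  # R and I i.i.d. equal-variance: the complex row course is circular
  X <- rbind(rnorm(N), rnorm(N))
  sig <- signal_matrix(X, srate = 100)
  M <- matrix(c(1 + 0i, 0 + 1i), 1, 2)   # row course = x1 + i x2
  sol <- critical_phases(fake_phi(M), sig)
  expect_gte(min(quality_heuristic(sol)), 0)
  expect_lt(quality_heuristic(sol)[1], 0.02)
  # purely real component scores its full variance
  M2 <- matrix(c(1 + 0i, 0 + 0i), 1, 2)
  sol2 <- critical_phases(fake_phi(M2), sig)
  xc <- X - rowMeans(X)
  expect_equal(quality_heuristic(sol2)[1], sum(xc[1, ]^2) / N,
               tolerance = 1e-10)
})

test_that("assembly honours the phase algebra and the pseudoinverse contract", {
  sig <- rand_signal(n = 3, N = 200, seed = 28)
  M <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3)
  sol <- critical_phases(fake_phi(M), sig)
  sol0 <- sol
  sol0$phases <- rep(0, 3)
  d0 <- assemble_demixing(fake_phi(M), sol0, sig)
  expect_equal(abs(d0$W[order(d0$order), ]), abs(Re(M)), tolerance = 1e-12)
  solq <- sol
  solq$phases <- rep(pi / 2, 3)
  dq <- assemble_demixing(fake_phi(M), solq, sig)
  expect_equal(abs(dq$W[order(dq$order), ]), abs(Im(M)), tolerance = 1e-12)
  d <- assemble_demixing(fake_phi(M), sol, sig)
  expect_equal(d$W %*% d$A_est, diag(3), tolerance = 1e-6)
})

test_that("a zero-variance component is flagged, not fatal", {
  sig <- rand_signal(n = 2, N = 100, seed = 29)
  M <- matrix(c(0 + 0i, 0 + 0i, 1 + 2i, 3 - 1i), 2, byrow = TRUE)
  expect_warning(sol <- critical_phases(fake_phi(M), sig), "zero variance")
  expect_equal(sol$phases[1], 0)
  expect_equal(sol$quality[1], 0)
})
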