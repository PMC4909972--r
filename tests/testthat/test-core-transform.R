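test_that("pairwise embedding produces L - h pairs per epoch, none crossing epochs", {
  s <- rand_signal(n = 1, N = 5)
  expect_equal(ncol(suppressWarnings(pairwise_embed(s, 1))$left), 4L)
  expect_equal(ncol(suppressWarnings(pairwise_embed(s, 4))$left), 1L)
  expect_error(pairwise_embed(s, 5), "lag exceeds epoch")
  expect_error(pairwise_embed(s, 0), "positive")

  # epoched: 4 epochs x 10 samples, h = 2 -> 4 * 8 pairs
  se <- rand_signal(n = 2, N = 40, epoch_length = 10, seed = 2)
  p <- suppressWarnings(pairwise_embed(se, 2))
  expect_equal(ncol(p$left), 4L * 8L)
  expect_equal(p$epoch_sizes, rep(8L, 4))
  # pair members really are h apart within the same epoch
  xc <- se$data - rowMeans(se$data)
  expect_equal(p$left[, 1:8], xc[, 1:8])
  expect_equal(p$right[, 1:8], xc[, 3:10])
  expect_equal(p$left[, 9:16], xc[, 11:18])   # second epoch starts fresh
})

test_that("pairwise embedding centers channels over the whole recording", {
  s <- rand_signal(n = 3, N = 50, seed = 3)
  s$data <- s$data + c(10, -4, 2)
  p <- pairwise_embed(s, 1)
  grand <- cbind(p$left, s$data[, 50] - rowMeans(s$data))
  expect_equal(rowMeans(grand), rep(0, 3), tolerance = 1e-12)
})

test_that("phase-space arithmetic matches the V and Haar definitions", {
  p <- structure(list(left = matrix(1), right = matrix(3), lag_h = 1L,
                      dt = 1 / 200, epoch_sizes = 1L, n_channels = 1L),
                 class = "pwc_pairs")
  v <- phase_space_transform(p, "v")
  expect_equal(v$base[1, 1], 2)
  expect_equal(v$velocity[1, 1], 400)
  h <- phase_space_transform(p, "haar")
  expect_equal(h$base[1, 1], 2 * sqrt(2))
  expect_equal(h$velocity[1, 1], sqrt(2))
  # identical pair -> zero velocity in V mode
  p$right <- matrix(1)
  expect_equal(phase_space_transform(p, "v")$velocity[1, 1], 0)
})

test_that("the Haar transform is orthogonal and V relates to it by diag(2,1)/sqrt(2)", {
  set.seed(7)
  p <- structure(list(left = matrix(rnorm(40), 4), right = matrix(rnorm(40), 4),
                      lag_h = 1L, dt = 1, epoch_sizes = 10L, n_channels = 4L),
                 class = "pwc_pairs")
  h <- phase_space_transform(p, "haar")
  norms_in <- sqrt(colSums(p$left^2) + colSums(p$right^2))
  norms_out <- sqrt(colSums(h$base^2) + colSums(h$velocity^2))
  expect_equal(norms_out, norms_in, tolerance = 1e-12)

  v <- phase_space_transform(p, "v", dt = 1)
  expect_equal(h$base, v$base * 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(h$velocity, v$velocity * 1 / sqrt(2), tolerance = 1e-12)
})

test_that("embed + transform is linear in the signal", {
  s1 <- rand_signal(n = 3, N = 30, seed = 4)
  s2 <- rand_signal(n = 3, N = 30, seed = 5)
  mix <- s1
  mix$data <- 2 * s1$data + 3 * s2$data
  for (mode in c("v", "haar")) {
    t1 <- phase_space_transform(suppressWarnings(pairwise_embed(s1, 2)), mode)
    t2 <- phase_space_transform(suppressWarnings(pairwise_embed(s2, 2)), mode)
    tm <- phase_space_transform(suppressWarnings(pairwise_embed(mix, 2)), mode)
    expect_equal(tm$base, 2 * t1$base + 3 * t2$base, tolerance = 1e-12)
    expect_equal(tm$velocity, 2 * t1$velocity + 3 * t2$velocity,
                 tolerance = 1e-12)
  }
})

test_that("permuting epochs permutes phase-space columns without changing values", {
  s <- rand_signal(n = 2, N = 30, epoch_length = 10, seed = 6)
  sp <- s
  sp$data <- s$data[, c(11:20, 21:30, 1:10)]   # epoch order 2,3,1
  a <- phase_space_transform(suppressWarnings(pairwise_embed(s, 1)), "haar")
  b <- phase_space_transform(suppressWarnings(pairwise_embed(sp, 1)), "haar")
  perm <- c(10:18, 19:27, 1:9)
  expect_equal(b$base, a$base[, perm])
  expect_equal(b$velocity, a$velocity[, perm])
})

test_that("complexify is lossless", {
  s <- rand_signal(seed = 8)
  ps <- phase_space_transform(pairwise_embed(s, 1), "v")
  z <- complexify(ps)
  expect_identical(Re(z$data), ps$base)
  expect_identical(Im(z$data), ps$velocity)
  ps0 <- ps
  ps0$velocity[] <- 0
  expect_true(all(Im(complexify(ps0)$data) == 0))
})

test_that("hilbert complexification yields the analytic signal", {
  srate <- 200
  N <- 4000
  t <- (0:(N - 1)) / srate
  f <- 10
  x <- signal_matrix(rbind(cos(2 * pi * f * t), rep(1, N)), srate = srate)
  z <- hilbert_complexify(x)
  expect_equal(ncol(z$data), N)                       # no samples lost
  mid <- 500:3500
  # imaginary part of the analytic cosine is the sine, away from edges
  expect_lt(max(abs(Im(z$data[1, mid]) - sin(2 * pi * f * t[mid]))), 1e-3)
  # constant channel centers to zero; its Hilbert transform vanishes
  expect_lt(max(abs(Im(z$data[2, ]))), 1e-10)
  # real part equals the centered input
  expect_equal(Re(z$data[1, ]), cos(2 * pi * f * t) - mean(cos(2 * pi * f * t)),
               tolerance = 1e-10)
})

test_that("analytic-signal modulus tracks a slow amplitude envelope", {
  srate <- 200
  N <- 6000
  t <- (0:(N - 1)) / srate
  a <- 1 + 0.5 * sin(2 * pi * 0.3 * t)
  x <- signal_matrix(matrix(a * cos(2 * pi * 20 * t), 1), srate = srate)
  z <- hilbert_complexify(x)
  mid <- 1000:5000
  expect_lt(max(abs(Mod(z$data[1, mid]) - a[mid])), 0.05)
})

test_that("hilbert transform respects epoch boundaries", {
  s <- rand_signal(n = 1, N = 64, epoch_length = 32, seed = 9)
  z <- hilbert_complexify(s)
  # each epoch equals the transform of that epoch in isolation
  xc <- s$data - rowMeans(s$data)
  e1 <- signal_matrix(xc[, 1:32, drop = FALSE], srate = s$srate)
  z1 <- hilbert_complexify(e1)
  # isolated-call re-centering shifts only the real (DC) part, never Im
  expect_equal(Im(z$data[1, 1:32]), Im(z1$data[1, ]), tolerance = 1e-10)
})
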