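test_that("L1 loss matches hand arithmetic", {
  x <- matrix(0, 2, 2)
  expect_equal(l1_loss(x, x), 0)
  expect_equal(l1_loss(x, x + 0.3), 0.3)
  expect_equal(l1_loss(matrix(c(0.1, -0.2, 0, 0.3), 2), matrix(0, 2, 2)), 0.15)
  expect_error(l1_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("ms_ssim is 1 at identity, symmetric, and matches the brute-force oracle", {
  set.seed(3)
  x <- matrix(runif(16 * 16, -1, 1), 16)
  y <- x + matrix(rnorm(256, 0, 0.25), 16)
  expect_equal(ms_ssim(x, x, n_scales = 1), 1, tolerance = 1e-9)
  expect_equal(ms_ssim(x, y, n_scales = 1), ms_ssim(y, x, n_scales = 1),
               tolerance = 1e-12)
  expect_lt(abs(ms_ssim(x, y, n_scales = 1) - brute_ssim_windowed(x, y)), 1e-6)
  expect_error(ms_ssim(x, y, n_scales = 3), "too small")
})

test_that("ms_ssim decreases monotonically with added noise", {
  set.seed(4)
  x <- matrix(runif(64 * 64, -1, 1), 64)
  vals <- sapply(c(0.05, 0.15, 0.3, 0.6), function(s) {
    set.seed(99)
    ms_ssim(x, x + matrix(rnorm(64^2, 0, s), 64))
  })
  expect_true(all(diff(vals) < 0))
})

test_that("single-scale ms_ssim agrees with the metrics module's windowed ssim", {
  set.seed(5)
  x <- matrix(runif(20 * 20, -1, 1), 20)
  y <- x + matrix(rnorm(400, 0, 0.1), 20)
  expect_lt(abs(ms_ssim(x, y, n_scales = 1) - ssim(x, y, windowed = TRUE)), 1e-6)
})

test_that("the weighted reconstruction loss combines its parts exactly", {
  set.seed(6)
  x <- matrix(runif(48 * 48, -1, 1), 48)
  y <- x + matrix(rnorm(48^2, 0, 0.2), 48)
  expect_equal(recon_loss(x, x), 0, tolerance = 1e-9)
  w0 <- loss_weights(omega = 0)
  expect_equal(recon_loss(x, y, w0), l1_loss(x, y))
  a <- l1_loss(x, y)
  b <- ms_ssim(x, y)
  expect_equal(recon_loss(x, y, loss_weights(omega = 0.84)),
               0.84 * (1 - b) + 0.16 * a, tolerance = 1e-9)
})

test_that("ms-ssim and reconstruction gradients agree with finite differences", {
  set.seed(7)
  x <- array(runif(48 * 48, -1, 1), c(48, 48, 1, 1))
  y <- x + array(rnorm(48^2, 0, 0.15), c(48, 48, 1, 1))
  r <- mrcgan:::ms_ssim_internal(x, y, 2, 11, 1.5, 2, want_grad = TRUE)
  f <- function(yy) ms_ssim(x, yy, n_scales = 2)
  for (i in sample(length(y), 4)) {
    fd <- fd_dir(f, y, i, eps = 1e-6)
    expect_lt(abs(fd - r$grad[i]) / max(abs(fd), 1e-6), 1e-3)
  }
  w <- loss_weights()
  rg <- mrcgan:::recon_grad(x, y, w, n_scales = 2)
  f2 <- function(yy) recon_loss(x, yy, w, n_scales = 2)
  for (i in sample(length(y), 3)) {
    fd <- fd_dir(f2, y, i, eps = 1e-6)
    expect_lt(abs(fd - rg$grad[i]) / max(abs(fd), 1e-6), 1e-3)
  }
})

test_that("non-saturating adversarial losses take their closed-form values", {
  z <- nonsat_gan_losses(0, 0)
  expect_equal(z$d_loss, 2 * log(2), tolerance = 1e-12)
  expect_equal(z$g_loss, log(2), tolerance = 1e-12)
  lim <- nonsat_gan_losses(50, -50)
  expect_lt(lim$d_loss, 1e-20)
  z2 <- nonsat_gan_losses(1, -1)
  sp <- function(v) log1p(exp(-abs(v))) + max(v, 0)
  expect_equal(z2$d_loss, 2 * sp(-1), tolerance = 1e-12)
  expect_equal(z2$g_loss, sp(1), tolerance = 1e-12)
})

test_that("the R1 penalty of a linear discriminator is (gamma/2) ||w||^2", {
  set.seed(8)
  wvec <- array(rnorm(8 * 8), c(8, 8, 1, 1))
  lin <- list(input_grad = function(x) {
    n <- dim(x)[4]
    list(value = apply(x, 4, function(im) sum(im * c(wvec))),
         grad = array(rep(wvec, n), c(dim(wvec)[1:3], n)))
  })
  batch <- array(rnorm(8 * 8 * 1 * 4), c(8, 8, 1, 4))
  expect_lt(abs(r1_penalty(lin, batch, loss_weights(gamma_r1 = 1)) -
                  0.5 * sum(wvec^2)), 1e-6)
  # doubling gamma doubles the penalty; constant discriminators pay nothing
  expect_equal(r1_penalty(lin, batch, loss_weights(gamma_r1 = 2)),
               2 * r1_penalty(lin, batch, loss_weights(gamma_r1 = 1)))
  flat <- list(input_grad = function(x)
    list(value = rep(1, dim(x)[4]), grad = array(0, dim(x))))
  expect_equal(r1_penalty(flat, batch), 0)
})

test_that("cycle loss expands per its two-term definition", {
  set.seed(9)
  g <- array(runif(6 * 6, -1, 1), c(6, 6, 1, 2))
  t <- array(runif(6 * 6, -1, 1), c(6, 6, 1, 2))
  idb <- list(G = identity, F = identity)
  expect_equal(cycle_loss(idb, g, t), 0)
  plus <- list(G = function(x) x + 0.25, F = identity)
  expect_equal(cycle_loss(plus, g, t), 0.5, tolerance = 1e-12)
  # symmetric under swapping (G, g) <-> (F, t)
  b1 <- list(G = function(x) x + 0.1, F = function(x) x - 0.3)
  b2 <- list(G = function(x) x - 0.3, F = function(x) x + 0.1)
  expect_equal(cycle_loss(b1, g, t), cycle_loss(b2, t, g), tolerance = 1e-12)
  expect_error(cycle_loss(list(G = identity), g, t), "both generator")
})

test_that("the conditioning loss sums averaged MSE and FS cross-entropy", {
  expect_equal(conditioning_loss(c(0.5, 0.5, 100), c(0.5, 0.5, 1)), 0,
               tolerance = 1e-9)
  expect_equal(conditioning_loss(c(0.6, 0.7, 100), c(0.5, 0.5, 1)),
               (0.01 + 0.04) / 2, tolerance = 1e-9)
  expect_equal(conditioning_loss(c(0.5, 0.5, 0), c(0.5, 0.5, 1)), log(2),
               tolerance = 1e-12)
  expect_equal(conditioning_loss(c(0.5, 0.5, 0), c(0.5, 0.5, 0)), log(2),
               tolerance = 1e-12)
  # gradient against finite differences
  set.seed(10)
  p <- matrix(runif(6), 2, 3)
  y <- matrix(c(0.3, 0.6, 0.2, 0.8, 1, 0), 2, 3)
  g <- mrcgan:::conditioning_grad(p, y)
  for (i in 1:6) {
    fd <- fd_dir(function(pp) conditioning_loss(pp, y), p, i)
    expect_lt(abs(fd - g[i]), 1e-7)
  }
})

test_that("losses are nonnegative and recon vanishes only at identity", {
  set.seed(11)
  x <- matrix(runif(48 * 48, -1, 1), 48)
  y <- x + matrix(rnorm(48^2, 0, 0.1), 48)
  expect_gt(recon_loss(x, y), 0)
  expect_gte(l1_loss(x, y), 0)
  expect_gte(1 - ms_ssim(x, y), 0)
})
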