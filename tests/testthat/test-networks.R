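small_gen_cfg <- function(...) generator_config(filters = c(4, 8),
                                                base_size = 32, ...)

test_that("the generator preserves shape, bounds its output and starts as the identity", {
  g <- build_generator(small_gen_cfg(), seed = 1)
  x <- array(runif(32 * 32 * 1 * 3, -0.9, 0.9), c(32, 32, 1, 3))
  y <- translate(g, x, c(0.5, 0.5, 0), c(0.8, 0.6, 1))
  expect_equal(dim(y), dim(x))
  expect_true(all(abs(y) <= 1))
  # identity-initialized: output reproduces the input
  expect_lt(max(abs(y - x)), 1e-12)
  g64 <- build_generator(generator_config(filters = c(4, 8, 8), base_size = 64),
                         seed = 2)
  x64 <- matrix(runif(64 * 64, -1, 1), 64)
  expect_equal(dim(translate(g64, x64, c(0.5, 0.5, 0), c(0.5, 0.5, 1))),
               c(64, 64))
  expect_error(build_generator(generator_config(filters = c(4, 8), base_size = 30)),
               "divisible")
})

test_that("identity-initialized style projections make the output label-independent", {
  g <- build_generator(small_gen_cfg(), seed = 3)
  x <- array(runif(32 * 32, -0.9, 0.9), c(32, 32, 1, 1))
  y1 <- g$forward(x, rbind(c(0.1, 0.9, 0)), rbind(c(0.9, 0.1, 1)))$out$val
  y2 <- g$forward(x, rbind(c(0.7, 0.2, 1)), rbind(c(0.3, 0.8, 0)))$out$val
  expect_identical(y1, y2)
})

test_that("parameter count is invariant to which labels are injected", {
  n <- sapply(list(c(FALSE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE)), function(fl)
    n_parameters(build_generator(small_gen_cfg(
      inject_source_labels = fl[1], inject_target_labels = fl[2]), seed = 4)))
  expect_equal(n[1], n[2])
  expect_equal(n[2], n[3])
})

test_that("translate is deterministic, batch-consistent and validates labels", {
  g <- build_generator(small_gen_cfg(), seed = 5)
  # perturb so the network is nontrivial
  for (L in g$layers) for (p in L$param_names) {
    d <- dim(L[[p]])
    v <- L[[p]] + rnorm(length(L[[p]]), 0, 0.05)
    if (!is.null(d)) dim(v) <- d
    L[[p]] <- v
  }
  x <- array(runif(32 * 32 * 1 * 3, -0.9, 0.9), c(32, 32, 1, 3))
  ys <- matrix(runif(9), 3)
  yt <- matrix(runif(9), 3)
  y1 <- translate(g, x, ys, yt)
  expect_identical(y1, translate(g, x, ys, yt))
  # single-image calls agree with the batch per sample (convolutions run
  # in single precision, so agreement is to float accuracy)
  for (i in 1:3) {
    yi <- translate(g, matrix(x[, , 1, i], 32), ys[i, ], yt[i, ])
    expect_lt(max(abs(yi - y1[, , 1, i])), 1e-5)
  }
  expect_error(translate(g, x, c(30, 3000, 0), c(40, 4000, 1)), "scaled")
})

test_that("generator parameter gradients agree with finite differences", {
  set.seed(6)
  g <- build_generator(small_gen_cfg(), seed = 6)
  for (L in g$layers) for (p in L$param_names) {
    d <- dim(L[[p]])
    v <- L[[p]] + rnorm(length(L[[p]]), 0, 0.1)
    if (!is.null(d)) dim(v) <- d
    L[[p]] <- v
  }
  x <- array(runif(32 * 32 * 1 * 2, -0.9, 0.9), c(32, 32, 1, 2))
  ys <- matrix(runif(6), 2)
  yt <- matrix(runif(6), 2)
  gy <- array(rnorm(length(x)), dim(x))
  tape <- mrcgan:::ad_tape()
  rf <- mrcgan:::gen_forward(g, x, ys, yt, tape)
  mrcgan:::zero_grads(g$layers)
  mrcgan:::ad_backward(tape, rf$out, gy)
  proj <- function() sum(mrcgan:::gen_forward(g, x, ys, yt,
                                              mrcgan:::ad_tape())$out$val * gy)
  # directional derivatives over whole parameter tensors: robust to the
  # single-precision convolution arithmetic
  for (nm in c("stem", "enc1.conv1", "enc1.ad1", "bott.conv2", "dec1.short",
               "final", "out")) {
    L <- g$layers[[nm]]
    p <- L$param_names[1]
    grad <- L[[mrcgan:::grad_name(p)]]
    gn <- sqrt(sum(grad^2))
    expect_gt(gn, 1e-3)  # gradient actually flows to this layer
    dir <- grad / gn  # derivative along the gradient: maximal signal
    orig <- L[[p]]
    eps <- 1e-3
    L[[p]] <- orig + eps * dir; fp <- proj()
    L[[p]] <- orig - eps * dir; fm <- proj()
    L[[p]] <- orig
    fd <- (fp - fm) / (2 * eps)
    expect_lt(abs(fd - gn) / gn, 2e-2)
  }
})


test_that("the discriminator scores batches and is differentiable in its input", {
  d <- build_discriminator(discriminator_config(filters = c(4, 8), base_size = 32),
                           seed = 7)
  x <- array(runif(32 * 32 * 1 * 5, -1, 1), c(32, 32, 1, 5))
  s <- d$forward(x)
  expect_length(s, 5)
  ig <- d$input_grad(x)
  expect_true(all(is.finite(ig$grad)))
  expect_equal(dim(ig$grad), dim(x))
  # directional central-difference check of the score gradient
  xs <- array(runif(32 * 32, -1, 1), c(32, 32, 1, 1))
  gg <- d$input_grad(xs)$grad
  dir <- array(rnorm(length(xs)), dim(xs))
  dir <- dir / sqrt(sum(dir^2))
  eps <- 1e-3
  fd <- (sum(d$forward(xs + eps * dir)) - sum(d$forward(xs - eps * dir))) / (2 * eps)
  an <- sum(dir * gg)
  expect_lt(abs(fd - an) / max(abs(an), 1e-3), 2e-2)
})

test_that("the auxiliary classifier maps images to scaled-label triplets", {
  ac <- build_aux_classifier(input_size = 32, filters = c(4, 8, 8, 8), seed = 8)
  x <- array(runif(32 * 32 * 1 * 4, -1, 1), c(32, 32, 1, 4))
  p <- ac$predict(x)
  expect_equal(dim(p), c(4, 3))
  expect_true(all(is.finite(p)))
  # FS decision convention: logit > 0
  expect_type(p[, 3] > 0, "logical")
  expect_error(build_aux_classifier("efficientnet_b3"), "not available")
  expect_error(build_aux_classifier("resnet50"), "unknown backbone")
})

test_that("contrast_grid orders and shapes its output and degenerates to translate", {
  g <- build_generator(small_gen_cfg(), seed = 9)
  img <- matrix(runif(32 * 32, -0.9, 0.9), 32)
  ys <- c(0.6, 0.6, 0)
  gr <- contrast_grid(g, img, ys, te_list = c(45, 15, 30),
                      tr_list = c(4000, 2000), fs = 0)
  expect_equal(dim(gr), c(32, 32, 3, 2))
  expect_equal(dimnames(gr)$te, c("15", "30", "45"))
  one <- contrast_grid(g, img, ys, te_list = 30, tr_list = 3000, fs = 1)
  expect_equal(matrix(one[, , 1, 1], 32),
               translate(g, img, ys, scale_labels(30, 3000, 1)))
})

test_that("checkpoints round-trip weights, EMA and config", {
  g <- build_generator(small_gen_cfg(), seed = 10)
  g$ema <- mrcgan:::get_params(g$layers)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(g, f)
  g2 <- load_checkpoint(f)
  x <- matrix(runif(32 * 32, -0.9, 0.9), 32)
  expect_identical(translate(g, x, c(0.5, 0.5, 0), c(0.5, 0.5, 1)),
                   translate(g2, x, c(0.5, 0.5, 0), c(0.5, 0.5, 1)))
  ac <- build_aux_classifier(input_size = 32, filters = c(4, 8, 8, 8), seed = 11)
  ac$trained <- TRUE
  f2 <- tempfile(fileext = ".rds")
  save_checkpoint(ac, f2)
  ac2 <- load_checkpoint(f2)
  expect_true(ac2$trained)
  xb <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(ac$predict(xb), ac2$predict(xb))
})

test_that("forward passes stay finite at initialization", {
  g <- build_generator(small_gen_cfg(), seed = 12)
  d <- build_discriminator(discriminator_config(filters = c(4, 8), base_size = 32),
                           seed = 12)
  x <- array(runif(32 * 32 * 1 * 4, -1, 1), c(32, 32, 1, 4))
  expect_true(all(is.finite(translate(g, x, c(1, 1, 1), c(0, 0, 0)))))
  expect_true(all(is.finite(d$forward(x))))
})
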