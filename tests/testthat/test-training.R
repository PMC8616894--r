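# compact configs so training-loop tests stay fast
fast_variant <- function(variant, iterations = 6, seed = 1, ...) {
  variant_config(variant, iterations = iterations, batch_size = 4,
                 ac_iterations = 20, ac_batch_size = 16,
                 gen_filters = c(4, 8), disc_filters = c(4, 8),
                 ac_filters = c(4, 8, 8, 8), seed = seed, ...)
}

small_ds <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_synthetic_dataset(seed = 31, n_subjects = 20,
                                       slices_per_subject = 2,
                                       pair_fraction = 0.7, noise_sd = 0.01)
    cache
  }
})

test_that("ema_update follows its closed forms", {
  cur <- list(a = c(1, 2), b = matrix(3, 2, 2))
  sh <- list(a = c(0, 0), b = matrix(0, 2, 2))
  # decay 0: shadow jumps to current
  expect_equal(ema_update(cur, sh, 0), cur)
  # fixed point
  expect_equal(ema_update(cur, cur, 0.999), cur)
  # geometric series over k steps with constant current
  s <- 5
  for (k in 1:7) s <- ema_update(2, s, 0.9)
  expect_equal(s, 5 * 0.9^7 + 2 * (1 - 0.9^7), tolerance = 1e-12)
  expect_error(ema_update(cur, list(a = c(0, 0)), 0.5), "match")
  expect_error(ema_update(cur, sh, 1), "decay")
})

test_that("variant switches form a cumulative ladder differing by one feature", {
  cfgs <- lapply(1:6, variant_config)
  expect_true(!any(unlist(cfgs[[1]]$switches)))
  for (k in 2:6) {
    d <- mapply(function(a, b) a != b, cfgs[[k]]$switches, cfgs[[k - 1]]$switches)
    expect_equal(sum(d), 1)
    expect_true(unlist(cfgs[[k]]$switches)[d])  # the new switch turns on
  }
  expect_error(variant_config(7), "variant")
})

test_that("batch sampling respects variant pools and is deterministic", {
  ds <- small_ds()
  v1 <- fast_variant(1)
  b1 <- sample_batch(ds, v1, rng_state = 77)
  expect_identical(b1, sample_batch(ds, v1, rng_state = 77))
  expect_false(identical(b1, sample_batch(ds, v1, rng_state = 78)))
  # variants 1-4 never draw a non-FS target
  for (s in c(1, 5, 9, 13))
    expect_true(all(ds$meta$fs[sample_batch(ds, fast_variant(2), s)$tgt] == 1))
  # variant 5 eventually draws non-FS targets too
  fs5 <- unlist(lapply(1:20, function(s)
    ds$meta$fs[sample_batch(ds, fast_variant(5), s)$tgt]))
  expect_true(any(fs5 == 0))
  expect_true(all(ds$meta$role[sample_batch(ds, fast_variant(5), 3)$src] == "source"))
})

test_that("variant-6 unpaired draws match the dataset share", {
  ds <- small_ds()
  v6 <- fast_variant(6)
  pools <- mrcgan:::variant_pools(ds, v6)
  expect_gt(pools$unpaired_share, 0)
  types <- vapply(1:800, function(s)
    sample_batch(ds, v6, s, pools)$type, character(1))
  expect_lt(abs(mean(types == "unpaired") - pools$unpaired_share), 0.05)
  b <- sample_batch(ds, v6, 5, pools)
  if (b$type == "unpaired") {
    expect_true(all(ds$meta$fs[b$idx] == 0))
    expect_true(all(b$yr >= 0 & b$yr <= 1))
  }
})

test_that("AC pretraining learns, reports and reproduces bit-identically", {
  ds <- small_ds()
  r1 <- pretrain_ac(ds, fast_variant(6, seed = 5))
  expect_true(r1$ac$trained)
  expect_true(all(is.finite(r1$history$loss)))
  expect_true(all(c("te_mae_scaled", "tr_mae_scaled", "fs_accuracy") %in%
                    names(r1$report)))
  r2 <- pretrain_ac(ds, fast_variant(6, seed = 5))
  expect_identical(r1$report, r2$report)
  bad <- ds
  bad$meta$te_ms[1] <- NA
  expect_error(pretrain_ac(bad, fast_variant(6)), "labels")
})

test_that("GAN training runs all paired variants with finite losses, deterministically", {
  ds <- small_ds()
  for (v in c(1, 4)) {
    m <- train_gan(ds, fast_variant(v, iterations = 4, seed = 9))
    expect_true(all(is.finite(m$history$d_loss)))
    expect_true(all(is.finite(m$history$g_adv)))
    expect_true(all(is.finite(m$history$g_recon)))
    expect_true(all(is.finite(m$history$r1)))
  }
  m1 <- train_gan(ds, fast_variant(5, iterations = 4, seed = 9))
  m2 <- train_gan(ds, fast_variant(5, iterations = 4, seed = 9))
  expect_identical(m1$history, m2$history)
})

test_that("variant 1 is blind to acquisition labels", {
  ds <- small_ds()
  perm <- ds
  set.seed(123)
  # shuffle TE/TR among samples; FS stays so the sampling pools are unchanged
  p <- sample(nrow(perm$meta))
  perm$meta$te_ms <- perm$meta$te_ms[p]
  perm$meta$tr_ms <- perm$meta$tr_ms[p]
  h1 <- train_gan(ds, fast_variant(1, iterations = 4, seed = 11))$history
  h2 <- train_gan(perm, fast_variant(1, iterations = 4, seed = 11))$history
  expect_identical(h1, h2)
  # variants with injection are not label-blind
  h3 <- train_gan(ds, fast_variant(2, iterations = 4, seed = 11))$history
  h4 <- train_gan(perm, fast_variant(2, iterations = 4, seed = 11))$history
  expect_false(identical(h3, h4))
})

test_that("variant 6 requires a pretrained AC and exercises cycle and conditioning", {
  ds <- small_ds()
  expect_error(train_gan(ds, fast_variant(6)), "pretrained auxiliary classifier")
  untrained <- build_aux_classifier(input_size = ds$height,
                                    filters = c(4, 8, 8, 8), seed = 1)
  expect_error(train_gan(ds, fast_variant(6), untrained), "pretrained")
  # mostly-unpaired dataset so the unpaired branch is certainly exercised
  ds_u <- make_synthetic_dataset(seed = 32, n_subjects = 20,
                                 slices_per_subject = 2, pair_fraction = 0.2,
                                 noise_sd = 0.01)
  ac <- pretrain_ac(ds_u, fast_variant(6, seed = 2))$ac
  m <- train_gan(ds_u, fast_variant(6, iterations = 8, seed = 2), ac)
  unp <- m$history[m$history$type == "unpaired", ]
  expect_gt(nrow(unp), 0)
  expect_true(all(is.finite(unp$g_cycle)))
  expect_true(all(is.finite(unp$g_cond)))
})

test_that("EMA shadow weights power the trained translator", {
  ds <- small_ds()
  m <- train_gan(ds, fast_variant(5, iterations = 4, seed = 13))
  expect_false(is.null(m$G$ema))
  img <- matrix(runif(64 * 64, -1, 1), 64)
  y_ema <- translate(m$G, img, c(0.5, 0.5, 0), c(0.7, 0.7, 1), use_ema = TRUE)
  y_cur <- translate(m$G, img, c(0.5, 0.5, 0), c(0.7, 0.7, 1), use_ema = FALSE)
  expect_false(identical(y_ema, y_cur))
})

test_that("every active generator loss term produces gradient flow", {
  ds <- small_ds()
  v <- fast_variant(5, iterations = 1, seed = 17)
  gen <- build_generator(generator_config(filters = v$gen_filters, base_size = 64),
                         seed = 17)
  b <- sample_batch(ds, v, 3)
  xs <- ds$images[, , , b$src, drop = FALSE]
  xt <- ds$images[, , , b$tgt, drop = FALSE]
  ys <- mrcgan:::meta_labels(ds, b$src)
  yt <- mrcgan:::meta_labels(ds, b$tgt)
  tape <- mrcgan:::ad_tape()
  gf <- mrcgan:::gen_forward(gen, xs, ys, yt, tape)
  rg <- mrcgan:::recon_grad(xt, gf$out$val, loss_weights())
  mrcgan:::zero_grads(gen$layers)
  mrcgan:::ad_backward(tape, gf$out, rg$grad)
  gnorm <- sum(vapply(gen$layers, function(L)
    sum(vapply(L$param_names, function(p)
      sum(L[[mrcgan:::grad_name(p)]]^2), numeric(1))), numeric(1)))
  expect_gt(gnorm, 0)
})
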