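#' Experiment variant configuration
#'
#' The six model variants form a cumulative ladder; each enables exactly one
#' feature on top of the previous one:
#' \describe{
#'   \item{1}{pix2pix baseline: non-FS to FS pairs, L1 reconstruction +
#'     non-saturating adversarial loss with R1; labels ignored.}
#'   \item{2}{target labels injected into the decoder via AdaIN.}
#'   \item{3}{source labels additionally injected into the encoder.}
#'   \item{4}{reconstruction loss becomes the weighted L1/MS-SSIM mix.}
#'   \item{5}{pairs with non-fat-saturated targets join the training data.}
#'   \item{6}{unpaired non-FS images join, trained under cycle-consistency
#'     and the AC conditioning loss with random target labels.}
#' }
#'
#' Optimizer settings follow the full-scale recipe (Adam, beta1 = 0,
#' beta2 = 0.99, batch 8 for the GAN and 64 for the AC; learning rate 1e-4
#' and EMA decay 0.999 at the full 200K-iteration schedule). The desk-scale
#' defaults shorten training about a hundredfold (2000 iterations at
#' 64 px), and the schedule-dependent settings are rescaled accordingly:
#' learning rates 3e-4 (GAN) and 2e-3 with cosine decay (AC), EMA decay
#' 0.995 so the shadow window stays a fraction of the run. Pass `lr = 1e-4`,
#' `ema_decay = 0.999`, `ac_lr = 1e-4` to reproduce the full-scale
#' settings.
#'
#' @param variant integer 1-6.
#' @param iterations GAN training iterations.
#' @param batch_size GAN batch size.
#' @param ac_iterations,ac_batch_size,ac_lr AC pretraining schedule.
#' @param lr,beta1,beta2 Adam settings for generator and discriminator.
#' @param ema_decay generator EMA decay.
#' @param weights a [loss_weights()].
#' @param image_size training resolution (images are assumed preprocessed).
#' @param gen_filters,disc_filters,ac_filters network widths.
#' @param augment_prob probability an iteration's batch is augmented.
#' @param max_shift,zoom_range augmentation ranges.
#' @param val_fraction held-out subject fraction for validation reports.
#' @param seed experiment seed (fans out to named substreams).
#' @return a `variant_config` list; the derived `switches` field holds the
#'   cumulative feature flags.
#' @export
variant_config <- function(variant, iterations = 2000, batch_size = 8,
                           ac_iterations = 2000, ac_batch_size = 64,
                           ac_lr = 2e-3,
                           lr = 3e-4, beta1 = 0, beta2 = 0.99,
                           ema_decay = 0.995, weights = loss_weights(),
                           image_size = 64,
                           gen_filters = c(8, 16, 32),
                           disc_filters = c(8, 16, 32, 64),
                           ac_filters = c(8, 16, 32, 64),
                           augment_prob = 0.5, max_shift = 0.05,
                           zoom_range = c(0.9, 1.1),
                           val_fraction = 0.1, seed = 1) {
  if (!variant %in% 1:6) stop_arg("variant must be an integer in 1..6")
  switches <- list(
    inject_target_labels = variant >= 2,
    inject_source_labels = variant >= 3,
    use_msssim = variant >= 4,
    nonfs_targets = variant >= 5,
    use_unpaired = variant >= 6)
  structure(list(variant = variant, switches = switches,
                 iterations = iterations, batch_size = batch_size,
                 ac_iterations = ac_iterations, ac_batch_size = ac_batch_size,
                 ac_lr = ac_lr, lr = lr, beta1 = beta1, beta2 = beta2,
                 ema_decay = ema_decay, weights = weights,
                 image_size = image_size, gen_filters = gen_filters,
                 disc_filters = disc_filters, ac_filters = ac_filters,
                 augment_prob = augment_prob, max_shift = max_shift,
                 zoom_range = zoom_range, val_fraction = val_fraction,
                 seed = seed),
            class = "variant_config")
}

#' @export
print.variant_config <- function(x, ...) {
  on <- names(Filter(isTRUE, x$switches))
  cat(sprintf("<variant_config> model %d: %s\n  %d iters, batch %d, lr %g, seed %d\n",
              x$variant,
              if (length(on)) paste(on, collapse = ", ") else "pix2pix baseline",
              x$iterations, x$batch_size, x$lr, x$seed))
  invisible(x)
}

# ---- Adam -------------------------------------------------------------------

adam_new <- function(layers, lr, beta1 = 0, beta2 = 0.99, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$layers <- layers
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(get_params(layers), function(p) p * 0)
  st$v <- st$m
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  c1 <- 1 - st$b1^st$t
  c2 <- 1 - st$b2^st$t
  for (nm in names(st$layers)) {
    L <- st$layers[[nm]]
    for (p in L$param_names) {
      key <- paste0(nm, ".", p)
      g <- L[[grad_name(p)]]
      st$m[[key]] <- st$b1 * st$m[[key]] + (1 - st$b1) * g
      st$v[[key]] <- st$b2 * st$v[[key]] + (1 - st$b2) * g * g
      L[[p]] <- L[[p]] - st$lr * (st$m[[key]] / c1) /
        (sqrt(st$v[[key]] / c2) + st$eps)
    }
  }
  zero_grads(st$layers)
  invisible(NULL)
}

#' Exponential-moving-average update of a parameter set
#'
#' `shadow <- decay * shadow + (1 - decay) * current`, elementwise.
#' Translation and evaluation use the shadow parameters.
#'
#' @param current,shadow parameter sets: numeric vectors/arrays or
#'   (nested) lists thereof with identical structure.
#' @param decay EMA decay in `[0, 1)`.
#' @return the updated shadow parameter set.
#' @export
ema_update <- function(current, shadow, decay) {
  if (decay < 0 || decay >= 1) stop_arg("decay must be in [0, 1)")
  if (is.list(current)) {
    if (!is.list(shadow) || length(shadow) != length(current) ||
        !identical(names(shadow), names(current)))
      stop_arg("parameter sets do not match")
    return(mapply(ema_update, current, shadow,
                  MoreArgs = list(decay = decay), SIMPLIFY = FALSE))
  }
  if (length(current) != length(shadow))
    stop_arg("parameter sets do not match")
  decay * shadow + (1 - decay) * current
}

# ---- batch sampling ---------------------------------------------------------

# index pools a variant may draw from
variant_pools <- function(dataset, variant) {
  m <- dataset$meta
  src <- which(m$role == "source")
  tgt_of <- function(s) which(m$pair_id == m$pair_id[s] & m$role == "target")
  tgt <- vapply(src, tgt_of, integer(1))
  keep <- if (variant$switches$nonfs_targets) rep(TRUE, length(src))
          else m$fs[tgt] == 1
  unpaired <- which(m$role == "unpaired" & m$fs == 0)
  n_paired_samples <- 2 * sum(keep)
  share <- if (variant$switches$use_unpaired && length(unpaired) > 0)
    length(unpaired) / (length(unpaired) + n_paired_samples) else 0
  list(src = src[keep], tgt = tgt[keep], unpaired = unpaired,
       unpaired_share = share)
}

#' Draw one training batch
#'
#' Variants 1-4 draw non-FS to FS pairs only; variant 5 includes pairs with
#' non-FS targets; variant 6 draws an unpaired batch with probability equal
#' to the unpaired share of the dataset, attaching random target labels from
#' the dataset's label sampler.
#'
#' @param dataset an `mr_dataset`.
#' @param variant a [variant_config()].
#' @param rng_state integer seed making the draw deterministic.
#' @param pools precomputed index pools (internal use by the training loop);
#'   recomputed from the dataset when `NULL`.
#' @return list with `type` (`"paired"`/`"unpaired"`) and sample indices;
#'   paired batches carry `src`/`tgt`, unpaired ones `idx` and random
#'   target labels `yr` (`n x 3`, scaled).
#' @export
sample_batch <- function(dataset, variant, rng_state, pools = NULL) {
  if (is.null(pools)) pools <- variant_pools(dataset, variant)
  if (length(pools$src) == 0 && length(pools$unpaired) == 0)
    stop_arg("dataset has no samples usable by variant ", variant$variant)
  n <- variant$batch_size
  with_seed(substream_seed(rng_state, "batch"), {
    if (pools$unpaired_share > 0 && runif(1) < pools$unpaired_share) {
      idx <- sample(pools$unpaired, n, replace = length(pools$unpaired) < n)
      lab <- sample_acquisition_labels(n, substream_seed(rng_state, "randlab"),
                                       dataset$label_sampler)
      list(type = "unpaired", idx = idx,
           yr = scale_labels(lab$te_ms, lab$tr_ms, lab$fs))
    } else {
      j <- sample(seq_along(pools$src), n, replace = length(pools$src) < n)
      list(type = "paired", src = pools$src[j], tgt = pools$tgt[j])
    }
  })
}

meta_labels <- function(dataset, idx) {
  m <- dataset$meta
  scale_labels(m$te_ms[idx], m$tr_ms[idx], m$fs[idx])
}

# ---- AC pretraining ---------------------------------------------------------

#' Pretrain the auxiliary classifier on labelled images
#'
#' Trains the AC to regress scaled TE and TR (mean squared error) and
#' classify fat saturation (binary cross-entropy) from single images, with
#' the shared shift/zoom augmentation, Adam, and a subject-wise held-out
#' validation split. Deterministic given `config$seed`.
#'
#' @param dataset an `mr_dataset` with labels in its manifest.
#' @param config a [variant_config()] (uses the `ac_*` fields and `seed`).
#' @return list with `ac` (the trained classifier), `report` (held-out MAE
#'   in scaled units and ms, FS accuracy), and `history` (per-iteration
#'   loss).
#' @export
pretrain_ac <- function(dataset, config = variant_config(6)) {
  m <- dataset$meta
  if (any(is.na(m$te_ms)) || any(is.na(m$fs)))
    stop_arg("dataset samples must carry acquisition labels")
  seed <- config$seed
  subjects <- unique(m$subject_id)
  n_val <- max(1L, round(length(subjects) * config$val_fraction))
  val_sub <- with_seed(substream_seed(seed, "ac_val_split"),
                       sample(subjects, n_val))
  val_idx <- which(m$subject_id %in% val_sub)
  train_idx <- setdiff(seq_len(nrow(m)), val_idx)

  ac <- build_aux_classifier(input_size = dataset$height,
                             filters = config$ac_filters, seed = seed)
  opt <- adam_new(ac$layers, config$ac_lr, config$beta1, config$beta2)
  labels <- meta_labels(dataset, seq_len(nrow(m)))
  hist <- numeric(config$ac_iterations)
  for (it in seq_len(config$ac_iterations)) {
    # cosine-decayed learning rate over the pretraining schedule
    opt$lr <- config$ac_lr * 0.5 * (1 + cos(pi * (it - 1) / config$ac_iterations))
    sit <- substream_seed(seed, paste0("ac_it", it))
    idx <- with_seed(sit, sample(train_idx, config$ac_batch_size,
                                 replace = length(train_idx) < config$ac_batch_size))
    x <- dataset$images[, , , idx, drop = FALSE]
    if (with_seed(substream_seed(sit, "augp"), runif(1)) < config$augment_prob)
      x <- augment_batch(x, sit, max_shift = config$max_shift,
                         zoom_range = config$zoom_range)
    y <- labels[idx, , drop = FALSE]
    tape <- ad_tape()
    out <- ac_forward(ac, x, tape)
    hist[it] <- conditioning_loss(out$out$val, y)
    ad_backward(tape, out$out, conditioning_grad(out$out$val, y))
    adam_step(opt)
  }
  ac$trained <- TRUE
  pred <- ac$predict(dataset$images[, , , val_idx, drop = FALSE])
  yv <- labels[val_idx, , drop = FALSE]
  report <- list(
    n_val = length(val_idx),
    te_mae_scaled = mean(abs(pred[, 1] - yv[, 1])),
    tr_mae_scaled = mean(abs(pred[, 2] - yv[, 2])),
    te_mae_ms = mean(abs(pred[, 1] - yv[, 1])) * 50,
    tr_mae_ms = mean(abs(pred[, 2] - yv[, 2])) * 5000,
    fs_accuracy = mean((pred[, 3] > 0) == (yv[, 3] == 1)))
  list(ac = ac, report = report,
       history = data.frame(iteration = seq_along(hist), loss = hist))
}

# ---- GAN training -----------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the image-to-image GAN
#'
#' Alternating discriminator/generator updates with the non-saturating
#' adversarial loss, R1 regularization on real batches, the variant's
#' reconstruction loss on paired batches and, for variant 6, cycle
#' consistency plus the weighted AC conditioning loss on unpaired batches
#' with random target labels. The generator maintains an EMA shadow used by
#' [translate()]. Fully deterministic given `variant$seed`.
#'
#' @param dataset an `mr_dataset`.
#' @param variant a [variant_config()].
#' @param ac a pretrained [build_aux_classifier()]; required for variant 6.
#' @return an object of class `gan_model`: list with `G`, `D`, `AC`,
#'   `variant`, `history` (per-iteration losses) and `translator`, a
#'   function `(image, y_source, y_target) -> image` using the EMA weights.
#' @export
train_gan <- function(dataset, variant, ac = NULL) {
  if (variant$switches$use_unpaired && (is.null(ac) || !isTRUE(ac$trained)))
    stop_arg("variant 6 requires a pretrained auxiliary classifier")
  seed <- variant$seed
  w <- variant$weights
  gen <- build_generator(generator_config(
    filters = variant$gen_filters, base_size = variant$image_size,
    inject_source_labels = variant$switches$inject_source_labels,
    inject_target_labels = variant$switches$inject_target_labels), seed = seed)
  disc <- build_discriminator(discriminator_config(
    filters = variant$disc_filters, base_size = variant$image_size),
    seed = seed)
  g_opt <- adam_new(gen$layers, variant$lr, variant$beta1, variant$beta2)
  d_opt <- adam_new(disc$layers, variant$lr, variant$beta1, variant$beta2)
  shadow <- get_params(gen$layers)
  omega_eff <- if (variant$switches$use_msssim) w$omega else 0
  wts_recon <- loss_weights(omega = omega_eff, gamma_r1 = w$gamma_r1,
                            lambda_c = w$lambda_c,
                            lambda_recon = w$lambda_recon)
  hist <- vector("list", variant$iterations)
  eps_fd <- 1e-3
  pools <- variant_pools(dataset, variant)
  if (!is.null(ac)) for (L in ac$layers) L$frozen <- TRUE
  on.exit(if (!is.null(ac)) for (L in ac$layers) L$frozen <- FALSE)

  for (it in seq_len(variant$iterations)) {
    sit <- substream_seed(seed, paste0("gan_it", it))
    b <- sample_batch(dataset, variant, sit, pools)
    if (b$type == "paired") {
      xs <- dataset$images[, , , b$src, drop = FALSE]
      xt <- dataset$images[, , , b$tgt, drop = FALSE]
      if (with_seed(substream_seed(sit, "augp"), runif(1)) < variant$augment_prob) {
        n <- length(b$src)
        both <- augment_batch(abind4(xs, xt), sit, group = rep(seq_len(n), 2),
                              max_shift = variant$max_shift,
                              zoom_range = variant$zoom_range)
        xs <- both[, , , seq_len(n), drop = FALSE]
        xt <- both[, , , n + seq_len(n), drop = FALSE]
      }
      ys <- meta_labels(dataset, b$src)
      yt <- meta_labels(dataset, b$tgt)
    } else {
      xs <- dataset$images[, , , b$idx, drop = FALSE]
      xt <- xs  # unpaired images are the real examples for D
      ys <- meta_labels(dataset, b$idx)
      yt <- b$yr
    }
    n <- dim(xs)[4]

    # generator forward (kept on tape for the G step)
    tg <- ad_tape()
    gf <- gen_forward(gen, xs, ys, yt, tg)
    fake <- gf$out$val

    # ---- discriminator step ----
    zero_grads(disc$layers)
    # R1: input gradient of the real scores, then a symmetric secant pass
    # along it so the penalty shapes the weight gradient
    tp <- ad_tape()
    tp$no_param_grads <- TRUE
    xtn <- ad_input(tp, xt)
    xtn$want_grad <- TRUE
    rp <- disc_forward(disc, xtn, tp)
    ad_backward(tp, rp$out, matrix(1, n, 1))
    gin <- xtn$grad
    gnorm <- sqrt(apply(gin^2, 4, sum))
    r1_val <- w$gamma_r1 / 2 * mean(gnorm^2)
    if (w$gamma_r1 > 0 && any(gnorm > 0)) {
      u <- gin
      for (i in seq_len(n)) if (gnorm[i] > 0)
        u[, , , i] <- u[, , , i] / gnorm[i]
      coef <- w$gamma_r1 * gnorm / (2 * eps_fd * n)
      tfd <- ad_tape()
      rfd <- disc_forward(disc, abind4(xt + eps_fd * u, xt - eps_fd * u), tfd)
      ad_backward(tfd, rfd$out, matrix(c(coef, -coef), 2 * n, 1))
    }
    td <- ad_tape()
    rrf <- disc_forward(disc, abind4(xt, fake), td)
    s_real <- rrf$out$val[seq_len(n), 1]
    s_fake <- rrf$out$val[n + seq_len(n), 1]
    adv <- nonsat_gan_losses(s_real, s_fake)
    ad_backward(td, rrf$out,
                matrix(c(-sigmoid(-s_real), sigmoid(s_fake)) / n, 2 * n, 1))
    adam_step(d_opt)

    # ---- generator step ----
    zero_grads(gen$layers)
    for (L in disc$layers) L$frozen <- TRUE
    rf2 <- disc_forward(disc, gf$out, tg)
    g_adv <- mean(softplus(-rf2$out$val))
    ad_acc(rf2$out, matrix(-sigmoid(-rf2$out$val) / n, n, 1))
    rec <- cyc <- cond <- NA_real_
    if (b$type == "paired") {
      rg <- recon_grad(xt, fake, wts_recon)
      rec <- rg$value
      ad_acc(gf$out, w$lambda_recon * rg$grad)
    } else {
      # forward cycle back to the original labels (shared generator as F)
      back <- gen_forward(gen, gf$out, yt, ys, tg)
      cyc <- l1_loss(back$out$val, xs)
      ad_acc(back$out, l1_grad(xs, back$out$val))
      acf <- ac_forward(ac, gf$out, tg)
      cond <- conditioning_loss(acf$out$val, yt)
      ad_acc(acf$out, w$lambda_c * conditioning_grad(acf$out$val, yt))
    }
    ad_backward(tg, rf2$out, matrix(0, n, 1))
    for (L in disc$layers) L$frozen <- FALSE
    adam_step(g_opt)
    shadow <- ema_update(get_params(gen$layers), shadow, variant$ema_decay)

    hist[[it]] <- data.frame(iteration = it, type = b$type,
                             d_loss = adv$d_loss, r1 = r1_val,
                             g_adv = g_adv, g_recon = rec,
                             g_cycle = cyc, g_cond = cond)
  }
  gen$ema <- shadow
  history <- do.call(rbind, hist)
  structure(list(G = gen, D = disc, AC = ac, variant = variant,
                 history = history,
                 translator = function(image, y_source, y_target)
                   translate(gen, image, y_source, y_target)),
            class = "gan_model")
}

#' @export
print.gan_model <- function(x, ...) {
  cat(sprintf("<gan_model> variant %d, %d iterations; final d_loss %.3f, g_adv %.3f\n",
              x$variant$variant, nrow(x$history),
              utils::tail(x$history$d_loss, 1), utils::tail(x$history$g_adv, 1)))
  invisible(x)
}

abind4 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3], d[4] + dim(b)[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}
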